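test_that("Delta-R2* conversion is exact, scale-invariant, and validated", {
  tms <- dscTimes()
  expect_equal(curveValues(toDeltaR2star(rep(700, 80), 20, 46, 2)), rep(0, 80))
  # a drop to exp(-0.046) of baseline at TE 46 ms is exactly 1.0 1/s
  sig <- rep(1000, 80); sig[30] <- 1000 * exp(-0.046)
  cc <- toDeltaR2star(sig, 20, 46, 2)
  expect_equal(curveValues(cc)[30], 1.0, tolerance = 1e-12)
  expect_equal(curveValues(toDeltaR2star(sig * 3.3, 20, 46, 2)),
               curveValues(cc))
  bad <- sig; bad[17] <- 0
  expect_error(toDeltaR2star(bad, 20, 46, 2), "frame 17")
  expect_error(toDeltaR2star(sig, 20, 0, 2), "echo time")
})

test_that("rBV is the tracer-dilution integral ratio", {
  tms <- dscTimes()
  ca <- aifConcentration(gammaVariateAif(), tms, 40)
  aif <- concentrationCurve(tms, ca, 20L)
  half <- concentrationCurve(tms, 0.5 * ca, 20L)
  expect_equal(computeRBV(half, aif), 0.5, tolerance = 1e-12)
  expect_error(computeRBV(half, aif, window = c(10, 10)), "window")
  expect_error(computeRBV(half, aif, window = c(1, 200)), "window")
  expect_error(computeRBV(half, concentrationCurve(tms, rep(0, 80), 20L)),
               "not positive")
})

test_that("impulse-input deconvolution returns the constructed residue exactly", {
  n <- 60; dt <- 2
  tms <- (seq_len(n) - 0.5) * dt
  FR <- 1.2 * exp(-(seq_len(n) - 1) * dt / 6)
  imp <- rep(0, n); imp[1] <- 1 / dt
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j:n, j] <- imp[seq_len(n - j + 1)]
  ct <- dt * (A %*% FR)[, 1]
  dec <- deconvolveTSVD(concentrationCurve(tms, ct, 2L),
                        concentrationCurve(tms, imp, 2L), threshold = 0)
  expect_equal(dec$scaled_residue, FR, tolerance = 1e-10)
  expect_equal(dec$rbf, 1.2, tolerance = 1e-10)
})

test_that("threshold-0 tSVD equals forward substitution on a well-conditioned system", {
  n <- 60; dt <- 2
  tms <- (seq_len(n) - 0.5) * dt
  ca <- 6 * exp(-tms / 20)  # bolus peak at the first sample: strong diagonal
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j:n, j] <- ca[seq_len(n - j + 1)]
  FR <- 1.2 * exp(-(seq_len(n) - 1) * dt / 6)
  ct <- dt * (A %*% FR)[, 1]
  dec <- deconvolveTSVD(concentrationCurve(tms, ct, 2L),
                        concentrationCurve(tms, ca, 2L), threshold = 0)
  fs <- forwardsolve(dt * A, ct)
  expect_lt(max(abs(dec$scaled_residue - fs)) / max(abs(fs)), 0.01)
  expect_error(deconvolveTSVD(concentrationCurve(tms, ct, 2L),
                              concentrationCurve(tms, rep(0, n), 2L), 0.2),
               "all-zero")
  expect_error(deconvolveTSVD(concentrationCurve(tms, ct, 2L),
                              concentrationCurve(tms, ca, 2L), 1), "threshold")
})

test_that("deconvolution is linear in the tissue curve and MTT-consistent", {
  tms <- dscTimes()
  gv <- gammaVariateAif()
  ca <- concentrationCurve(tms, aifConcentration(gv, tms, 40), 20L)
  ct <- residueConvolve(1.5, 6, gv, tms, "boxcar", refine = 10L,
                        bolusTime = 40)
  d1 <- deconvolveTSVD(ct, ca, 0.2)
  d3 <- deconvolveTSVD(concentrationCurve(tms, 3 * curveValues(ct), 20L),
                       ca, 0.2)
  expect_equal(d3$rbf, 3 * d1$rbf, tolerance = 1e-10)
  expect_equal(d3$rbv, 3 * d1$rbv, tolerance = 1e-10)
  expect_equal(d3$mtt, d1$mtt, tolerance = 1e-10)
  expect_equal(d1$mtt, d1$rbv / d1$rbf)
  # truncated-SVD tolerances at the protocol's conditions
  expect_lt(abs(d1$rbv / 9 - 1), 0.01)
  expect_lt(abs(d1$rbf / 1.5 - 1), 0.15)
  expect_lt(abs(d1$mtt / 6 - 1), 0.20)
})

test_that("deconvolution followed by re-convolution reproduces the tissue curve", {
  tms <- dscTimes()
  gv <- gammaVariateAif()
  ca <- aifConcentration(gv, tms, 40)
  ct <- curveValues(residueConvolve(1.5, 6, gv, tms, "boxcar", refine = 10L,
                                    bolusTime = 40))
  dec <- deconvolveTSVD(concentrationCurve(tms, ct, 20L),
                        concentrationCurve(tms, ca, 20L), 0.2)
  n <- length(tms)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j:n, j] <- ca[seq_len(n - j + 1)]
  recon <- 2 * (A %*% dec$scaled_residue)[, 1]
  # residual bounded by the truncation level of the regularization
  expect_lt(sqrt(sum((recon - ct)^2) / sum(ct^2)), 0.25)
})
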