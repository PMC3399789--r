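test_that("relative concentration conversion is exact and scale-invariant", {
  flat <- toRelativeConcentration(rep(200, 80), 20, 3.7)
  expect_equal(curveValues(flat), rep(0, 80))
  sig <- rep(200, 80); sig[40] <- 300
  expect_equal(curveValues(toRelativeConcentration(sig, 20, 3.7))[40], 0.5)
  expect_equal(curveValues(toRelativeConcentration(sig * 3, 20, 3.7)),
               curveValues(toRelativeConcentration(sig, 20, 3.7)))
  expect_equal(curveTimes(flat), dceTimes())
  expect_error(toRelativeConcentration(rep(0, 80), 20, 3.7), "positive")
})

test_that("AIF extraction recovers generator parameters from a noiseless aorta", {
  truthAif <- aifModel()
  times <- dceTimes()
  cp <- aifConcentration(truthAif, times, 74)
  # aorta signal under linearized enhancement; measured mode returns it
  curve <- toRelativeConcentration(1000 * (1 + cp), 20, 3.7)
  expect_equal(curveValues(extractAIF(curve, "measured")), cp)
  fit <- extractAIF(curve, "biexp_fit")
  expect_lt(abs(fit@a1 / truthAif@a1 - 1), 0.01)
  expect_lt(abs(fit@a2 / truthAif@a2 - 1), 0.01)
  expect_lt(abs(fit@m1 / truthAif@m1 - 1), 0.01)
  expect_lt(abs(fit@m2 / truthAif@m2 - 1), 0.01)
  expect_true(attr(fit, "converged"))
  # flat curve: no detectable bolus
  expect_error(extractAIF(toRelativeConcentration(rep(500, 80), 20, 3.7)),
               "no detectable bolus")
})

test_that("Tofts forward model honours its analytic limits", {
  times <- dceTimes()
  aif <- aifModel()
  cp <- aifConcentration(aif, times, 74)
  # zero transfer: identically zero curve
  expect_equal(curveValues(toftsForward(0, 0.35, cp, times)), rep(0, 80))
  expect_error(toftsForward(0.2, 0, cp, times), "ve")
  # impulse AIF of unit area (on the minute scale of the kinetic
  # integral): the response is the exponential kernel
  dtMin <- 3.7 / 60
  imp <- rep(0, 80); imp[30] <- 1 / dtMin
  ct <- curveValues(toftsForward(0.25, 0.35, imp, times))
  kep <- 0.25 / 0.35
  late <- 35:60
  expected <- 0.25 * exp(-kep * (times[late] - times[30]) / 60)
  expect_equal(ct[late], expected, tolerance = 0.01)
  # near-unity ve with ktrans t << ve: linear in the integrated AIF
  small <- curveValues(toftsForward(0.002, 1, cp, times))
  integ <- 0.002 * pracma::cumtrapz(times / 60, cp)[, 1]
  expect_lt(max(abs(small - integ)) / max(integ), 0.01)
})

test_that("frame-grid convolution matches dt/10 refined quadrature", {
  times <- dceTimes()
  cp <- aifConcentration(aifModel(), times, 74)
  for (k in c(0.05, 1.0)) for (v in c(0.1, 0.6)) {
    c1 <- curveValues(toftsForward(k, v, cp, times, refine = 1L))
    c10 <- curveValues(toftsForward(k, v, cp, times, refine = 10L))
    expect_lt(max(abs(c1 - c10)) / max(c10), 0.005)
  }
})

test_that("noiseless ROI curves return the generating (ktrans, ve)", {
  times <- dceTimes()
  aif <- aifModel()
  for (k in c(0.05, 0.5)) for (v in c(0.15, 0.5)) {
    ct <- toftsForward(k, v, aif, times, refine = 10L, bolusTime = 74)
    fit <- fitTofts(ct, aif, bolusTime = 74)
    expect_true(fit$converged)
    expect_lt(abs(fit$ktrans / k - 1), 0.01)
    expect_lt(abs(fit$ve / v - 1), 0.01)
  }
  # all-zero tissue: zero transfer with zero residual, no exception
  zero <- concentrationCurve(times, rep(0, 80), 20L)
  fz <- fitTofts(zero, aif, bolusTime = 74)
  expect_equal(fz$ktrans, 0)
  expect_equal(fz$residual_norm, 0)
})

test_that("fitted parameters are invariant to joint curve scaling", {
  times <- dceTimes()
  aif <- aifModel()
  cp <- aifConcentration(aif, times, 74)
  ct <- toftsForward(0.3, 0.4, cp, times)
  f1 <- fitTofts(ct, cp)
  f2 <- fitTofts(concentrationCurve(times, curveValues(ct) * 4.2, 20L),
                 cp * 4.2)
  expect_equal(f1$ktrans, f2$ktrans, tolerance = 1e-4)
  expect_equal(f1$ve, f2$ve, tolerance = 1e-4)
})

test_that("parameter recovery under noise tightens with SNR", {
  times <- dceTimes()
  aif <- aifModel()
  ct <- curveValues(toftsForward(0.25, 0.35, aif, times, refine = 8L,
                                 bolusTime = 74))
  errAt <- function(snr, reps = 40) {
    e <- replicate(reps, {
      y <- ct + rnorm(80, 0, max(ct) / snr)
      f <- fitTofts(concentrationCurve(times, y, 20L), aif, bolusTime = 74)
      abs(f$ktrans / 0.25 - 1)
    })
    median(e)
  }
  set.seed(21)
  e20 <- errAt(20)
  e80 <- errAt(80)
  expect_lt(e20, 0.10)
  expect_lt(e80, e20)
})
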