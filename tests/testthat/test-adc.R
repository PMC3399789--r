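test_that("noiseless mono-exponential signals are recovered to machine precision", {
  b <- paperBValues()
  for (s0 in c(200, 800, 2000)) {
    for (adc in c(0.6, 1.2, 2.2) * 1e-3) {
      sig <- s0 * exp(-b * adc)
      for (method in c("loglinear", "nonlinear")) {
        f <- fitADC(sig, b, method = method)
        expect_lt(abs(f$adc / adc - 1), 1e-9)
        expect_lt(abs(f$s0 / s0 - 1), 1e-9)
      }
    }
  }
})

test_that("loglinear and nonlinear agree on noiseless data and degenerate cases", {
  b <- paperBValues()
  for (s0 in c(300, 1500)) for (adc in c(0.8, 1.8) * 1e-3) {
    ll <- fitADC(s0 * exp(-b * adc), b, "loglinear")
    nl <- fitADC(s0 * exp(-b * adc), b, "nonlinear")
    expect_lt(abs(ll$adc / nl$adc - 1), 1e-3)
  }
  # constant signal: zero decay
  expect_equal(fitADC(rep(500, 10), b)$adc, 0)
  expect_equal(fitADC(rep(500, 10), b, "loglinear")$adc, 0)
})

test_that("ADC estimate is invariant to uniform signal scaling", {
  b <- paperBValues()
  set.seed(5)
  sig <- 800 * exp(-b * 1.1e-3) + rnorm(10, 0, 10)
  sig <- pmax(sig, 1)
  for (method in c("loglinear", "nonlinear")) {
    f1 <- fitADC(sig, b, method)
    f2 <- fitADC(sig * 7.5, b, method)
    expect_equal(f1$adc, f2$adc, tolerance = 1e-8)
    expect_equal(f2$s0 / f1$s0, 7.5, tolerance = 1e-6)
  }
})

test_that("input validation: too few positive samples and non-finite input", {
  b <- paperBValues()
  expect_error(fitADC(c(100, 50, rep(0, 8)), b), "fewer than 3")
  expect_error(fitADC(c(rep(100, 9), NA), b), "finite")
})

test_that("under Rician noise the nonlinear fit resists the log-domain bias", {
  b <- paperBValues()
  set.seed(11)
  nvox <- 4000
  adc <- 1.0e-3
  clean <- matrix(rep(1000 * exp(-b * adc), each = nvox), nrow = nvox)
  corrupt <- function(sigma) {
    n <- length(clean)
    matrix(sqrt((clean + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2),
           nrow = nvox)
  }
  biasAt <- function(noisy, method) {
    est <- mpMRIquant:::.fitAdcMatrix(noisy, b, method)$adc
    median(est) / adc - 1
  }
  n10 <- corrupt(100)   # SNR 10 at b = 0
  n50 <- corrupt(20)    # SNR 50
  # log-domain bias grows with sigma; signal-scale median error stays < 5%
  expect_gt(abs(biasAt(n10, "loglinear")), abs(biasAt(n50, "loglinear")))
  expect_lt(abs(biasAt(n10, "nonlinear")), 0.05)
  expect_lt(abs(biasAt(n50, "nonlinear")), 0.02)
})

test_that("adcMap fits voxel-wise with NA outside the mask and flags failures", {
  m <- smallGeometry()
  tr <- smallTruth(m)
  dwi <- simulateDWI(m, tr, smallMeta())
  map <- adcMap(dwi, m, region = "tumor")
  vals <- mapValues(map)
  tumor <- regionMask(m, "tumor")
  expect_true(all(is.na(vals[!tumor])))
  expect_true(all(is.finite(vals[tumor])))
  # uniform region reproduces the single-voxel fit
  rim <- regionMask(m, "viable_rim")
  one <- fitADC(1000 * exp(-paperBValues() * 0.9e-3), paperBValues())
  expect_equal(unname(vals[rim][1]), one$adc, tolerance = 1e-9)
  expect_error(adcMap(simulateDCE(m, tr, smallMeta())), "dwi")
})

test_that("region means are count-weighted and gated by the ROI size floor", {
  m <- smallGeometry()
  tr <- smallTruth(m)
  map <- adcMap(simulateDWI(m, tr, smallMeta()), m)
  counts <- attr(m, "voxelCounts")
  expected <- (counts[["viable_rim"]] * 0.9e-3 +
                 counts[["necrotic_core"]] * 2.2e-3) / counts[["tumor"]]
  expect_equal(regionMean(map, m, "tumor"), expected, tolerance = 1e-9)
  expect_equal(regionMean(map, m, "liver"), 1.0e-3, tolerance = 1e-9)
  # a tiny region is refused
  lab <- maskLabels(m)
  lab[lab == maskLegend(m)[["aorta"]]] <- 0L
  lab[1:3, 1, 1] <- maskLegend(m)[["aorta"]]
  m2 <- roiMaskSet(lab, maskLegend(m), maskSpacing(m))
  expect_error(regionMean(map, m2, "aorta"), "10-voxel")
})

test_that("relative ADC and percent change implement the endpoint transforms", {
  expect_equal(relativeADC(1.2e-3, 1.0e-3), 1.2)
  expect_equal(relativeADC(1.0e-3, 1.0e-3), 1.0)
  expect_equal(relativeADC(0, 1.0e-3), 0)
  expect_error(relativeADC(1e-3, 0), "positive")
  expect_equal(percentChange(1.0, 1.0), 0)
  expect_equal(percentChange(1.0, 1.5), 50)
  expect_equal(percentChange(2.0, 1.0), -50)
  expect_equal(percentChange(100, 40), -60)
  expect_error(percentChange(0, 1), "non-zero")
})
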