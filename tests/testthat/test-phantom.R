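test_that("phantom geometry digitizes the anatomy with exact set identities", {
  m <- smallGeometry()
  counts <- attr(m, "voxelCounts")
  rim <- regionMask(m, "viable_rim")
  core <- regionMask(m, "necrotic_core")
  tumor <- regionMask(m, "tumor")
  expect_identical(tumor, rim | core)
  expect_false(any(rim & core))
  expect_true(all(counts >= 10))
  expect_error(smallGeometry(rim = 8), "rim thickness")
  expect_error(smallGeometry(rim = 10), "rim thickness")
  expect_error(makeGeometry(shape = c(20, 20, 6), spacing = c(1, 1, 2.2),
                            tumorRadii = c(15, 15, 15), rimThickness = 2),
               "does not fit")
})

test_that("digitized ellipsoid volume matches the analytic value within 5%", {
  m <- makeGeometry(shape = c(48, 48, 48), spacing = c(0.5, 0.5, 0.5),
                    tumorRadii = c(8, 8, 8), rimThickness = 2)
  expect_lt(abs(tumorVolume(m) / (4 / 3 * pi * 8^3) - 1), 0.05)
})

test_that("DWI forward model is exact mono-exponential decay when noiseless", {
  m <- smallGeometry()
  tr <- smallTruth(m)
  dwi <- simulateDWI(m, tr, smallMeta())
  dat <- seriesData(dwi)
  liver <- regionMask(m, "liver")
  # b = 0 plane equals S0 exactly
  expect_equal(dat[, , , 1][liver], rep(1000, sum(liver)))
  # closed form at b = 1000 for liver ADC 1.0e-3: 1000 * exp(-1)
  expect_equal(dat[, , , 10][liver], rep(1000 * exp(-1), sum(liver)),
               tolerance = 1e-12)
})

test_that("simulators are bit-reproducible under a fixed seed", {
  m <- smallGeometry()
  tr <- smallTruth(m, noiseSigma = 20, seed = 7L)
  meta <- smallMeta()
  expect_identical(seriesData(simulateDWI(m, tr, meta)),
                   seriesData(simulateDWI(m, tr, meta)))
  expect_identical(seriesData(simulateDSC(m, tr, meta)),
                   seriesData(simulateDSC(m, tr, meta)))
  tr2 <- smallTruth(m, noiseSigma = 20, seed = 8L)
  expect_false(identical(seriesData(simulateDWI(m, tr, meta)),
                         seriesData(simulateDWI(m, tr2, meta))))
})

test_that("Rician noise scale is calibrated: sample sd within 5% of sigma", {
  m <- smallGeometry()
  tr <- smallTruth(m, noiseSigma = 20, seed = 3L)
  dwi <- simulateDWI(m, tr, smallMeta())
  liver <- regionMask(m, "liver")
  b0 <- seriesData(dwi)[, , , 1][liver]   # amplitude 1000 >> sigma 20
  vals <- c(b0, seriesData(dwi)[, , , 2][liver],
            seriesData(dwi)[, , , 3][liver])
  resid <- vals - rep(c(1000, 1000 * exp(-50e-3), 1000 * exp(-100e-3)),
                      each = sum(liver))
  expect_gt(length(vals), 1000)
  expect_lt(abs(sd(resid) / 20 - 1), 0.05)
})

test_that("DCE simulation: zero transfer keeps baseline, pre-bolus is flat", {
  m <- smallGeometry()
  vals <- defaultTruthValues()
  for (r in c("viable_rim", "necrotic_core", "liver")) vals[[r]]$ktrans <- 0
  tr <- makePhantomTruth(m, values = vals, noiseSigma = 0)
  dce <- simulateDCE(m, tr, smallMeta())
  rim <- regionMask(m, "viable_rim")
  post <- seriesData(dce)[, , , 80][rim]
  expect_equal(post, rep(1000, sum(rim)))
  # with transfer, the 20 pre-bolus frames stay at baseline in all tissue
  tr2 <- smallTruth(m)
  dce2 <- simulateDCE(m, tr2, smallMeta())
  for (fr in c(1, 10, 20))
    expect_equal(seriesData(dce2)[, , , fr][rim], rep(1000, sum(rim)))
  expect_gt(max(seriesData(dce2)[, , , 40][rim]), 1000)
})

test_that("ve = 0 with positive ktrans is rejected as an undefined kernel", {
  m <- smallGeometry()
  vals <- defaultTruthValues()
  vals$viable_rim$ve <- 0
  tr <- makePhantomTruth(m, values = vals)
  expect_error(simulateDCE(m, tr, smallMeta()), "ve = 0")
})

test_that("DSC simulation: unperfused voxels are flat, perfused dip below baseline", {
  m <- smallGeometry()
  tr <- smallTruth(m)
  dsc <- simulateDSC(m, tr, smallMeta())
  dat <- seriesData(dsc)
  aorta <- regionMask(m, "aorta")  # flow map 0 but carries the AIF signal
  rim <- regionMask(m, "viable_rim")
  liver <- regionMask(m, "liver")
  expect_equal(dat[, , , 1][liver], rep(1000, sum(liver)))
  expect_lt(min(dat[, , , 25][rim]), 1000 * 0.9)
  expect_lt(min(dat[, , , 25][aorta]), 1000)
  expect_error(simulateDSC(m, tr, smallMeta(), residueModel = "plug"))
})

test_that("DSC truth satisfies the central volume theorem at the curve level", {
  tms <- dscTimes()
  gv <- gammaVariateAif()
  ca <- aifConcentration(gv, tms, 40)
  for (mtt in c(2, 6, 12)) {
    ct <- residueConvolve(1.5, mtt, gv, tms, "boxcar", refine = 10L,
                          bolusTime = 40)
    rbv <- computeRBV(ct, concentrationCurve(tms, ca, 20L))
    expect_lt(abs(rbv / (1.5 * mtt) - 1), 0.01)
  }
  # exponential residue integrates to the same blood volume
  ce <- residueConvolve(1.5, 6, gv, tms, "exponential", refine = 10L,
                        bolusTime = 40)
  expect_lt(abs(computeRBV(ce, concentrationCurve(tms, ca, 20L)) / 9 - 1),
            0.01)
})

test_that("central-volume consistency is enforced in the truth object itself", {
  m <- smallGeometry()
  tr <- smallTruth(m)
  pos <- tr@flowMap > 0
  expect_equal(tr@bvMap[pos], (tr@flowMap * tr@mttMap)[pos])
  expect_error(new("PhantomTruth", adcMap = tr@adcMap, s0Map = tr@s0Map,
                   ktransMap = tr@ktransMap, veMap = tr@veMap,
                   flowMap = tr@flowMap, bvMap = tr@bvMap * 2,
                   mttMap = tr@mttMap, aif = tr@aif, dscAif = tr@dscAif,
                   noiseSigma = 0, seed = 1L),
               "central-volume")
})

test_that("cohort generator reproduces the design and its degenerate limits", {
  # all factors 1, cv 0: every record equals the baseline values
  rec <- simulateCohort(nullProfiles(cv = 0),
                        nPerGroup = c(control = 2, Zd = 2, Tha = 2, ZdTha = 2),
                        seed = 1)
  base <- defaultBaselineRecord()
  for (q in c("tumor_volume", "radc", "ktrans", "ve", "rbv", "rbf"))
    expect_equal(rec[[q]], rep(base[[q]], nrow(rec)))
  # default group sizes reproduce the 10/11/11/12 randomization
  rec2 <- simulateCohort(seed = 1)
  expect_equal(as.vector(table(rec2$group)[c("control", "Zd", "Tha", "ZdTha")]),
               c(10, 11, 11, 12) * 5)
  # a profile missing a timepoint is rejected
  prof <- defaultGroupProfiles()
  expect_error(groupEffectProfile("Zd", prof$Zd$factors[-2, ]),
               "missing timepoint")
  expect_error(simulateCohort(profiles = prof[c("Zd", "Tha")]),
               "four groups")
})

test_that("cohort group means converge to baseline x factor", {
  # Zd 4 h rBV factor is 0.30 of baseline by default; the ratio of group
  # means over many subjects recovers it (mean-calibrated lognormal noise)
  reps <- vapply(1:100, function(r) {
    rec <- simulateCohort(nPerGroup = c(control = 11, Zd = 11,
                                        Tha = 2, ZdTha = 2), seed = r)
    at4h <- rec[rec$timepoint == "4h", ]
    mean(at4h$rbv[at4h$group == "Zd"]) /
      mean(at4h$rbv[at4h$group == "control"])
  }, numeric(1))
  expect_lt(abs(mean(reps) / (0.30 / 0.95) - 1), 0.02)

  # marginal convergence at n = 10^4 subjects overall: < 2% relative error
  big <- simulateCohort(nPerGroup = c(control = 2500, Zd = 2500,
                                      Tha = 2500, ZdTha = 2500), seed = 42)
  prof <- defaultGroupProfiles()
  base <- defaultBaselineRecord()
  for (g in c("control", "ZdTha")) {
    sub <- big[big$group == g & big$timepoint == "2d", ]
    fac <- prof[[g]]$factors[prof[[g]]$factors$timepoint == "2d", ]
    expect_lt(abs(mean(sub$rbv) / (base$rbv * fac$rbv) - 1), 0.02)
    expect_lt(abs(mean(sub$tumor_volume) /
                    (base$tumor_volume * fac$volume) - 1), 0.02)
  }
})
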