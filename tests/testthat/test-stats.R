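test_that("Kruskal-Wallis H matches the hand rank-sum value and conventions", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$h_statistic, 7.2)
  expect_equal(kw$df, 2)
  # degenerate all-tied case: H = 0, p = 1 instead of 0/0
  tied <- kruskalWallis(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(tied$h_statistic, 0)
  expect_equal(tied$p_value, 1)
  expect_error(kruskalWallis(list(1, c(2, 3))), "at least 2 finite")
  expect_error(kruskalWallis(list(c(1, 2))), "2 groups")
})

test_that("H is permutation-invariant and equals the brute-force form exhaustively", {
  g <- list(c(3, 9, 1), c(7, 2, 8), c(4, 6, 5))
  h1 <- kruskalWallis(g)$h_statistic
  h2 <- kruskalWallis(lapply(g, rev))$h_statistic
  expect_equal(h1, h2)
  # all partitions of 1..9 into three groups of three
  for (a in utils::combn(9, 3, simplify = FALSE)) {
    rest <- setdiff(1:9, a)
    for (b in utils::combn(rest, 3, simplify = FALSE)) {
      gr <- list(a, b, setdiff(rest, b))
      expect_equal(kruskalWallis(gr)$h_statistic, bruteForceH(gr),
                   tolerance = 1e-12)
    }
  }
  # tied integer datasets: all 3-group size-(2,2,2) samples over {1,2,3}
  vals <- expand.grid(rep(list(1:3), 6))
  for (i in seq_len(nrow(vals))) {
    v <- as.numeric(vals[i, ])
    gr <- list(v[1:2], v[3:4], v[5:6])
    expect_equal(kruskalWallis(gr)$h_statistic, bruteForceH(gr),
                 tolerance = 1e-12)
  }
})

test_that("two-group H reduces to the rank-sum statistic's chi-square form", {
  set.seed(9)
  for (r in 1:20) {
    g <- list(rnorm(6), rnorm(8, 0.5))
    expect_equal(kruskalWallis(g)$h_statistic, bruteForceH(g),
                 tolerance = 1e-12)
  }
})

test_that("post-hoc comparisons enumerate all pairs with capped Bonferroni", {
  set.seed(2)
  groups <- list(control = rnorm(10), Zd = rnorm(11, 2),
                 Tha = rnorm(11, 0.2), ZdTha = rnorm(12, 3))
  ph <- pairwisePosthoc(groups)
  expect_equal(nrow(ph), 6)       # 4 choose 2
  expect_equal(ph$adjusted_p, pmin(1, ph$raw_p * 6))
  expect_true(all(ph$adjusted_p <= 1))
  # a null pair with raw p above 1/6 is capped at exactly 1
  expect_equal(ph$adjusted_p[ph$group_a == "control" & ph$group_b == "Tha"], 1)
})

test_that("stepwise selection finds a dominant predictor and nothing else", {
  set.seed(4)
  n <- 30
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, 0, 0.01)
  sw <- stepwiseRegression(y, data.frame(x1 = x1, x2 = x2, x3 = x3))
  expect_identical(sw$selected_predictors, "x1")
  expect_equal(unname(sw$coefficients["x1"]), 2, tolerance = 0.01)
  expect_equal(sw$step_log$action[1], "enter")
  expect_error(stepwiseRegression(y, data.frame(c1 = rep(1, n))), "constant")
  expect_error(stepwiseRegression(y[1:4], data.frame(x1 = x1[1:4],
                                                     x2 = x2[1:4])),
               "observations")
})

test_that("single-predictor model_r is the signed sample correlation", {
  set.seed(6)
  x <- rnorm(20)
  y <- -1.5 * x + rnorm(20, 0, 0.8)
  sw <- stepwiseRegression(y, data.frame(x = x, z = rnorm(20)))
  expect_identical(sw$selected_predictors, "x")
  expect_equal(sw$model_r, cor(y, x), tolerance = 1e-12)
  expect_equal(sw$model_r^2, sw$model_r_squared, tolerance = 1e-12)
  expect_lt(sw$model_r, 0)
})

test_that("saturated thresholds admit every candidate; duplicates are skipped", {
  set.seed(8)
  n <- 40
  cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- cand$a + 0.5 * cand$b + rnorm(n)
  sw <- stepwiseRegression(y, cand, entryP = 1, exitP = 1)
  expect_setequal(sw$selected_predictors, c("a", "b", "c"))
  # an exact duplicate of a selected predictor is rank deficient
  cand2 <- cand
  cand2$a2 <- cand$a
  expect_warning(sw2 <- stepwiseRegression(y, cand2, entryP = 1, exitP = 1),
                 "rank-deficient")
  expect_false(all(c("a", "a2") %in% sw2$selected_predictors) &&
                 length(sw2$selected_predictors) == 4)
})

test_that("null-candidate selection stays near the nominal forward-entry rate", {
  # with k independent null candidates the expected empty-selection rate is
  # about (1 - entryP)^k; assert the simulation sits in that regime
  empty <- 0
  for (r in 1:200) {
    d <- simulatePredictorStudy(50, 0, 4, seed = 4000 + r)
    if (!length(stepwiseRegression(d$response, d$candidates)$selected_predictors))
      empty <- empty + 1
  }
  expect_gt(empty / 200, 0.68)   # (0.95)^5 = 0.774 minus Monte-Carlo slack
  expect_lt(empty / 200, 0.88)
})

test_that("study analysis compares every endpoint per timepoint across groups", {
  rec <- simulateCohort(seed = 5)
  an <- runStudyAnalysis(rec)
  expect_length(an$comparisons, 6 * 4)   # endpoints x timepoints
  cc <- an$comparisons[["rbv@4h"]]
  expect_s3_class(cc$posthoc, "data.frame")
  expect_equal(nrow(cc$posthoc), 6)
  # the strong default ZdTha effects reach significance at 4 h for rBV
  expect_lt(cc$p_value, 0.05)
  # stepwise ran on the 12-subject combination arm
  expect_true(is.list(an$stepwise))
  expect_null(an$stepwise$skipped)
  # a missing group is reported by name
  expect_error(runStudyAnalysis(rec[rec$group != "Tha", ]), "Tha")
})

test_that("effect-size monotonicity: larger group separation never lowers power", {
  powerAt <- function(factor12d, reps = 60) {
    prof <- defaultGroupProfiles(cv = 0.15)
    prof$ZdTha$factors$volume <- c(1, 1.05, 1.15, 1.5, factor12d)
    hits <- 0
    for (r in seq_len(reps)) {
      rec <- simulateCohort(prof, seed = 7000 + r)
      an <- runStudyAnalysis(rec, endpoints = "tumor_volume",
                             timepoints = "12d")
      ph <- an$comparisons[["tumor_volume@12d"]]$posthoc
      sel <- (ph$group_a == "control" & ph$group_b == "ZdTha") |
        (ph$group_a == "ZdTha" & ph$group_b == "control")
      if (ph$adjusted_p[sel] < 0.05) hits <- hits + 1
    }
    hits / reps
  }
  p <- vapply(c(5.2, 3.5, 1.8), powerAt, numeric(1))
  expect_true(all(diff(p) >= -0.10))  # non-decreasing up to Monte-Carlo slack
})
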