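#' @include AllClasses.R AllGenerics.R utils.R io.R
NULL

#' Kruskal-Wallis omnibus group comparison
#'
#' Nonparametric analysis of variance on ranks with mid-rank ties and tie
#' correction, the per-timepoint omnibus test of the analysis layer. The
#' degenerate all-tied case (every value equal) returns H = 0, p = 1
#' rather than 0/0.
#'
#' @param groups list of numeric vectors, each with at least 2 finite
#'   values.
#' @return list with \code{h_statistic}, \code{df}, \code{p_value},
#'   \code{n_total}.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$h_statistic  # 7.2
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2L) stop("at least 2 groups are required")
  ok <- vapply(groups, function(g) sum(is.finite(g)) >= 2L, logical(1))
  if (!all(ok))
    stop("each group needs at least 2 finite values; offending group(s): ",
         paste(which(!ok), collapse = ", "))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(h_statistic = 0, df = length(groups) - 1L, p_value = 1,
                n_total = length(x)))
  kt <- stats::kruskal.test(x, g)
  list(h_statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n_total = length(x))
}

#' Pairwise post-hoc comparisons with Bonferroni correction
#'
#' All k(k-1)/2 two-sided Wilcoxon rank-sum tests (normal approximation
#' with tie correction, no continuity correction) following the omnibus
#' comparison, with adjusted p = min(1, raw p x number of comparisons).
#'
#' @param groups named list of numeric vectors (>= 2 values each).
#' @param correction only "bonferroni" is offered.
#' @return data.frame with group_a, group_b, raw_p, adjusted_p.
#' @export
pairwisePosthoc <- function(groups, correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  k <- length(groups)
  if (k < 2L) stop("at least 2 groups are required")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pairs <- utils::combn(names(groups), 2)
  raw <- apply(pairs, 2, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    if (length(unique(c(a, b))) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                        correct = FALSE)$p.value)
  })
  m <- ncol(pairs)
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             raw_p = raw, adjusted_p = pmin(1, raw * m))
}

#' Omnibus plus post-hoc comparison of one endpoint
#'
#' @param groups named list of per-group values.
#' @return list with the \code{\link{kruskalWallis}} fields plus a
#'   \code{posthoc} data.frame from \code{\link{pairwisePosthoc}}.
#' @export
groupComparison <- function(groups) {
  out <- kruskalWallis(groups)
  out$posthoc <- pairwisePosthoc(groups)
  out
}

#' Stepwise multiple linear regression by partial-F p-values
#'
#' Forward selection with backward elimination on ordinary least squares:
#' at each step the candidate with the smallest partial-F p-value enters
#' if below \code{entryP}; after each entry, any included predictor whose
#' p-value exceeds \code{exitP} is removed; iteration stops when neither
#' rule fires. These 0.05/0.10 defaults are the conventional stepwise
#' thresholds. Rank-deficient candidates are skipped with a logged
#' warning. For a single-predictor final model the reported signed
#' \code{model_r} equals the sample correlation between response and
#' predictor (its square is the model R^2).
#'
#' @param response numeric response vector.
#' @param candidates named list or data.frame of candidate predictors.
#' @param entryP entry threshold on the partial-F p-value.
#' @param exitP removal threshold.
#' @return list with \code{selected_predictors}, \code{coefficients},
#'   \code{model_r} (signed, single-predictor models; NA otherwise),
#'   \code{model_r_squared}, \code{final_p_values}, \code{entry_p},
#'   \code{exit_p}, \code{step_log} (data.frame of every entry/removal
#'   with its p-value).
#' @export
stepwiseRegression <- function(response, candidates, entryP = 0.05,
                               exitP = 0.10) {
  candidates <- as.data.frame(candidates)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be named")
  n <- length(response)
  if (n <= ncol(candidates) + 2L)
    stop("need more observations than candidates + 2")
  if (any(vapply(candidates, function(x) stats::var(x) == 0, logical(1))))
    stop("constant candidate predictors are not allowed")
  dat <- data.frame(.y = response, candidates, check.names = FALSE)

  selected <- character(0)
  log <- list()
  warned <- character(0)
  # lm() strips backticks from syntactic names
  .coefRow <- function(varName, rows) {
    for (cand in c(varName, sprintf("`%s`", varName)))
      if (cand %in% rows) return(cand)
    NA_character_
  }
  partialP <- function(varName, inModel) {
    rhs <- paste(c("1", sprintf("`%s`", c(inModel, varName))), collapse = " + ")
    fit <- try(stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    sm <- summary(fit)$coefficients
    row <- .coefRow(varName, rownames(sm))
    if (is.na(row)) return(NA_real_)  # rank deficient
    sm[row, "Pr(>|t|)"]
  }
  repeat {
    changed <- FALSE
    avail <- setdiff(names(candidates), selected)
    if (length(avail)) {
      ps <- vapply(avail, partialP, numeric(1), inModel = selected)
      skipped <- avail[is.na(ps)]
      if (length(skipped)) {
        fresh <- setdiff(skipped, warned)
        if (length(fresh))
          warning("rank-deficient candidate(s) skipped: ",
                  paste(fresh, collapse = ", "))
        warned <- union(warned, skipped)
        ps <- ps[!is.na(ps)]
        avail <- setdiff(avail, skipped)
      }
      if (length(ps) && min(ps) < entryP) {
        enter <- avail[which.min(ps)]
        selected <- c(selected, enter)
        log[[length(log) + 1L]] <- data.frame(step = length(log) + 1L,
                                              action = "enter",
                                              predictor = enter,
                                              p = min(ps))
        changed <- TRUE
      }
    }
    # backward pass: drop the worst offender, re-check after each removal
    repeat {
      if (!length(selected)) break
      rhs <- paste(sprintf("`%s`", selected), collapse = " + ")
      fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
      sm <- summary(fit)$coefficients
      pv <- sm[vapply(selected, .coefRow, character(1),
                      rows = rownames(sm)), "Pr(>|t|)"]
      if (max(pv) <= exitP) break
      drop <- selected[which.max(pv)]
      selected <- setdiff(selected, drop)
      log[[length(log) + 1L]] <- data.frame(step = length(log) + 1L,
                                            action = "remove",
                                            predictor = drop,
                                            p = max(pv))
      changed <- TRUE
    }
    if (!changed) break
  }

  if (length(selected)) {
    rhs <- paste(sprintf("`%s`", selected), collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
    sm <- summary(fit)
    coefs <- stats::coef(fit)
    names(coefs) <- gsub("`", "", names(coefs))
    finalP <- sm$coefficients[vapply(selected, .coefRow, character(1),
                                     rows = rownames(sm$coefficients)),
                              "Pr(>|t|)"]
    names(finalP) <- selected
    r2 <- sm$r.squared
    modelR <- if (length(selected) == 1L)
      sign(coefs[[selected]]) * sqrt(r2) else NA_real_
  } else {
    coefs <- c(`(Intercept)` = mean(response))
    finalP <- numeric(0)
    r2 <- 0
    modelR <- NA_real_
  }
  list(selected_predictors = selected,
       coefficients = coefs,
       model_r = modelR,
       model_r_squared = r2,
       final_p_values = finalP,
       entry_p = entryP, exit_p = exitP,
       step_log = if (length(log)) do.call(rbind, log) else
         data.frame(step = integer(0), action = character(0),
                    predictor = character(0), p = numeric(0)))
}

#' Simulate a predictor-selection study
#'
#' One replicate of the design used to exercise the stepwise selector: a
#' response (volume change) driven by a single informative predictor (the
#' ADC change) at a prescribed population correlation, plus independent
#' decoy candidates. With \code{r = 0} all candidates are null.
#'
#' @param n observations per replicate.
#' @param r population correlation between response and the informative
#'   predictor (e.g. -0.65); 0 makes every candidate null.
#' @param nDecoys number of pure-noise candidates.
#' @param seed RNG seed.
#' @return list with \code{response} and \code{candidates} (the
#'   informative one named "d_radc", decoys "decoy1"...).
#' @export
simulatePredictorStudy <- function(n = 12L, r = -0.65, nDecoys = 4L,
                                   seed = 1L) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  withSeed(seed, {
    x <- stats::rnorm(n)
    y <- r * x + sqrt(1 - r^2) * stats::rnorm(n)
    dec <- as.data.frame(matrix(stats::rnorm(n * nDecoys), n))
    names(dec) <- paste0("decoy", seq_len(nDecoys))
    list(response = y, candidates = data.frame(d_radc = x, dec))
  })
}

.endpointColumns <- c("tumor_volume", "radc", "ktrans", "ve", "rbv", "rbf")

# per-subject percent change of each endpoint relative to the pre scan
.changeTable <- function(records) {
  pre <- records[records$timepoint == "pre", ]
  post <- records[records$timepoint != "pre", ]
  i <- match(post$subject_id, pre$subject_id)
  if (any(is.na(i)))
    stop("missing pre-treatment record for subject(s): ",
         paste(unique(post$subject_id[is.na(i)]), collapse = ", "))
  out <- post[, c("subject_id", "group", "timepoint")]
  for (ep in .endpointColumns)
    out[[paste0("d_", ep)]] <- percentChange(pre[[ep]][i], post[[ep]])
  out
}

#' Run the full study analysis on a record table
#'
#' For each requested endpoint and post-treatment timepoint, compares the
#' percent change from the pre scan across the four groups
#' (Kruskal-Wallis omnibus, then pairwise rank-sum post-hoc with
#' Bonferroni correction); then runs stepwise selection of the 12 d
#' volume-change predictors (the percent changes of rADC, Ktrans, ve,
#' rBV, rBF) within one group subset.
#'
#' @param records record table (see \code{\link{validateRecords}}).
#' @param endpoints endpoint columns to compare (default all six).
#' @param timepoints post-treatment timepoints (default 4h, 2d, 6d, 12d).
#' @param stepwiseGroup group whose records feed the stepwise regression
#'   (default "ZdTha", the combination arm).
#' @param stepwiseTimepoint timepoint of the stepwise endpoint (default
#'   "12d").
#' @param entryP,exitP stepwise thresholds.
#' @return list with \code{comparisons} (named
#'   "endpoint@timepoint" -> \code{\link{groupComparison}} result),
#'   \code{stepwise} (\code{\link{stepwiseRegression}} result), and
#'   \code{changes} (the per-subject change table).
#' @export
runStudyAnalysis <- function(records,
                             endpoints = .endpointColumns,
                             timepoints = c("4h", "2d", "6d", "12d"),
                             stepwiseGroup = "ZdTha",
                             stepwiseTimepoint = "12d",
                             entryP = 0.05, exitP = 0.10) {
  records <- validateRecords(records)
  chg <- .changeTable(records)
  comparisons <- list()
  for (tp in timepoints) {
    sub <- chg[chg$timepoint == tp, ]
    missing <- setdiff(.studyGroups, unique(sub$group))
    if (length(missing))
      stop(sprintf("timepoint %s lacks group(s): %s", tp,
                   paste(missing, collapse = ", ")))
    for (ep in endpoints) {
      col <- paste0("d_", ep)
      groups <- split(sub[[col]], factor(sub$group, levels = .studyGroups))
      comparisons[[paste0(ep, "@", tp)]] <- groupComparison(groups)
    }
  }
  sw <- chg[chg$timepoint == stepwiseTimepoint & chg$group == stepwiseGroup, ]
  if (!nrow(sw))
    stop(sprintf("no records for stepwise subset (%s at %s)",
                 stepwiseGroup, stepwiseTimepoint))
  candidates <- sw[, c("d_radc", "d_ktrans", "d_ve", "d_rbv", "d_rbf")]
  stepwise <- if (nrow(sw) > ncol(candidates) + 2L) {
    stepwiseRegression(sw$d_tumor_volume, candidates,
                       entryP = entryP, exitP = exitP)
  } else {
    list(selected_predictors = character(0), coefficients = numeric(0),
         model_r = NA_real_, model_r_squared = NA_real_,
         final_p_values = numeric(0), entry_p = entryP, exit_p = exitP,
         step_log = data.frame(step = integer(0), action = character(0),
                               predictor = character(0), p = numeric(0)),
         skipped = sprintf(
           "stepwise skipped: %d observations, need more than %d",
           nrow(sw), ncol(candidates) + 2L))
  }
  list(comparisons = comparisons, stepwise = stepwise, changes = chg)
}
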