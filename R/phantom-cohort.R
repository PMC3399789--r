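#' @include AllClasses.R AllGenerics.R utils.R phantom-geometry.R
NULL

.studyTimepoints <- c("pre", "4h", "2d", "6d", "12d")
.studyGroups <- c("control", "Zd", "Tha", "ZdTha")
.profileQuantities <- c("volume", "adc", "ktrans", "ve", "rbv", "rbf",
                        "rim", "necrosis")

#' Group effect profile for the longitudinal cohort simulator
#'
#' Per-timepoint multiplicative factors applied to each true quantity of a
#' treatment group, plus the between-subject coefficient of variation. All
#' factors must be positive and the pre-treatment factors all 1.
#'
#' @param group group label.
#' @param factors data.frame with one row per timepoint (column
#'   \code{timepoint}) and one column per quantity:
#'   volume, adc, ktrans, ve, rbv, rbf, rim, necrosis.
#' @param cv between-subject coefficient of variation (lognormal).
#' @return A validated list of class "GroupEffectProfile".
#' @export
groupEffectProfile <- function(group, factors, cv = 0.15) {
  if (!all(.studyTimepoints %in% factors$timepoint))
    stop(sprintf("profile '%s' is missing timepoint(s): %s", group,
                 paste(setdiff(.studyTimepoints, factors$timepoint),
                       collapse = ", ")))
  missing <- setdiff(.profileQuantities, names(factors))
  if (length(missing))
    stop(sprintf("profile '%s' is missing quantity column(s): %s", group,
                 paste(missing, collapse = ", ")))
  factors <- factors[match(.studyTimepoints, factors$timepoint), ]
  vals <- as.matrix(factors[, .profileQuantities])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("effect factors must be positive and finite")
  if (any(abs(vals[1, ] - 1) > 1e-12))
    stop("pre-treatment factors must all equal 1")
  if (cv < 0) stop("cv must be >= 0")
  structure(list(group = group, factors = factors, cv = cv),
            class = "GroupEffectProfile")
}

#' Default group effect trajectories
#'
#' Encodes only the signed, qualitative treatment dynamics of the study
#' design this simulator emulates: the vascular-disrupting agent (Zd)
#' collapses perfusion (rBV, Ktrans) at 4 h with a rapid rebound by 2 d
#' and tumor regrowth thereafter; the antiangiogenic (Tha) alone has a
#' brief early effect with a late rise of the extracellular fraction; the
#' combination sustains the perfusion reduction, slows volume growth the
#' most, enlarges necrosis and thins the viable rim. Magnitudes are
#' package defaults, configurable per profile; they are not estimates of
#' any reported group means.
#'
#' @param cv between-subject coefficient of variation for every group.
#' @return named list of \code{\link{groupEffectProfile}} objects.
#' @export
defaultGroupProfiles <- function(cv = 0.15) {
  tp <- .studyTimepoints
  mk <- function(group, volume, adc, ktrans, ve, rbv, rbf, rim, necrosis)
    groupEffectProfile(group, data.frame(
      timepoint = tp, volume = volume, adc = adc, ktrans = ktrans, ve = ve,
      rbv = rbv, rbf = rbf, rim = rim, necrosis = necrosis), cv = cv)
  list(
    control = mk("control",
                 volume = c(1, 1.05, 1.8, 3.2, 5.5),
                 adc    = c(1, 1.00, 1.00, 1.00, 0.95),
                 ktrans = c(1, 1.00, 1.05, 1.10, 1.10),
                 ve     = c(1, 1.00, 1.00, 1.05, 1.05),
                 rbv    = c(1, 0.95, 0.90, 0.85, 0.80),
                 rbf    = c(1, 1.00, 1.00, 0.95, 0.90),
                 rim    = c(1, 1.00, 1.00, 1.00, 1.00),
                 necrosis = c(1, 1.0, 1.1, 1.2, 1.3)),
    Zd = mk("Zd",
            volume = c(1, 1.05, 1.30, 2.20, 4.50),
            adc    = c(1, 0.85, 1.15, 1.05, 0.90),
            ktrans = c(1, 0.50, 1.05, 1.15, 1.25),
            ve     = c(1, 0.80, 1.00, 1.00, 1.00),
            rbv    = c(1, 0.30, 0.85, 0.85, 0.80),
            rbf    = c(1, 0.70, 1.00, 1.00, 1.00),
            rim    = c(1, 1.00, 0.90, 0.95, 1.00),
            necrosis = c(1, 1.0, 2.0, 1.6, 1.2)),
    Tha = mk("Tha",
             volume = c(1, 1.05, 1.50, 2.80, 5.00),
             adc    = c(1, 1.00, 0.85, 1.15, 1.15),
             ktrans = c(1, 1.00, 1.05, 1.10, 1.10),
             ve     = c(1, 1.00, 1.00, 1.05, 1.40),
             rbv    = c(1, 0.95, 0.90, 0.85, 0.80),
             rbf    = c(1, 1.00, 1.00, 0.90, 0.85),
             rim    = c(1, 1.00, 1.00, 1.00, 1.00),
             necrosis = c(1, 1.0, 1.2, 1.5, 1.8)),
    ZdTha = mk("ZdTha",
               volume = c(1, 1.05, 1.15, 1.50, 2.80),
               adc    = c(1, 0.85, 1.30, 1.25, 1.10),
               ktrans = c(1, 0.40, 0.60, 0.80, 1.00),
               ve     = c(1, 0.80, 0.85, 1.00, 0.90),
               rbv    = c(1, 0.30, 0.50, 0.70, 0.90),
               rbf    = c(1, 0.80, 0.60, 1.00, 1.00),
               rim    = c(1, 1.00, 0.80, 0.60, 0.55),
               necrosis = c(1, 1.0, 2.2, 2.5, 2.6)))
}

#' Baseline (pre-treatment) true summary values
#'
#' Package defaults for a full-grown implanted liver tumor: volume of an
#' ellipsoid somewhat above the 0.8 cm treatment-entry diameter, tumor ADC
#' slightly below liver (cellular tumor), moderate transfer constant and
#' extracellular fraction, and perfusion indexes consistent with the
#' phantom's flow/MTT truth (rbv = rbf x mtt).
#'
#' @return named list of baseline values.
#' @export
defaultBaselineRecord <- function() {
  list(tumor_volume = 700, radc = 0.9, ktrans = 0.25, ve = 0.35,
       rbv = 6, rbf = 1.5, rim_percent = 40, necrosis_percent = 15)
}

# map record column -> profile factor column
.recordFactorMap <- c(tumor_volume = "volume", radc = "adc",
                      ktrans = "ktrans", ve = "ve", rbv = "rbv", rbf = "rbf",
                      rim_percent = "rim", necrosis_percent = "necrosis")

#' Simulate a longitudinal 4-group cohort
#'
#' Generates per-subject, per-timepoint true summary values following the
#' study design this package emulates (4 treatment groups scanned pre and
#' at 4 h, 2 d, 6 d, 12 d). Each quantity is
#' baseline x group factor x lognormal subject noise, with the lognormal
#' mean-calibrated so the group mean converges to baseline x factor. The
#' noise is drawn independently per record and quantity; percentages are
#' clamped to [0, 100] and ve to [0, 1] after noise.
#'
#' @param profiles named list of \code{\link{groupEffectProfile}}s covering
#'   control, Zd, Tha, ZdTha.
#' @param nPerGroup named integer vector of group sizes (>= 2 each); the
#'   default reproduces the study's 10/11/11/12 randomization.
#' @param baseline baseline values, see \code{\link{defaultBaselineRecord}}.
#' @param seed RNG seed.
#' @return record data.frame (see \code{\link{validateRecords}}) with the
#'   per-record total multipliers attached as attribute
#'   \code{"multipliers"} for downstream image materialization.
#' @examples
#' rec <- simulateCohort(nPerGroup = c(control = 3, Zd = 3, Tha = 3, ZdTha = 3))
#' head(rec)
#' @export
simulateCohort <- function(profiles = defaultGroupProfiles(),
                           nPerGroup = c(control = 10L, Zd = 11L,
                                         Tha = 11L, ZdTha = 12L),
                           baseline = defaultBaselineRecord(),
                           seed = 1L) {
  missing <- setdiff(.studyGroups, names(profiles))
  if (length(missing))
    stop("profiles must cover the four groups; missing: ",
         paste(missing, collapse = ", "))
  if (is.null(names(nPerGroup))) names(nPerGroup) <- .studyGroups
  if (any(nPerGroup < 2L)) stop("n per group must be >= 2")

  nTp <- length(.studyTimepoints)
  nQ <- length(.recordFactorMap)
  baseVec <- unlist(baseline[names(.recordFactorMap)])
  nTotal <- sum(nPerGroup[.studyGroups]) * nTp
  valM <- multM <- matrix(NA_real_, nTotal, nQ,
                          dimnames = list(NULL, names(.recordFactorMap)))
  sid <- grp <- tp <- character(nTotal)
  row <- 0L
  for (g in .studyGroups) {
    pr <- profiles[[g]]
    sdlog <- sqrt(log(1 + pr$cv^2))
    facM <- as.matrix(pr$factors[, .recordFactorMap])
    colnames(facM) <- names(.recordFactorMap)
    for (s in seq_len(nPerGroup[[g]])) {
      id <- sprintf("%s_%02d", g, s)
      # lognormal subject noise, mean-calibrated so group means converge
      # to baseline x factor; independent per record and quantity
      eps <- withSeed(deriveSeed(seed, "cohort", id),
                      matrix(exp(stats::rnorm(nTp * nQ, sd = sdlog) -
                                   sdlog^2 / 2), nrow = nTp))
      mm <- facM * eps
      vv <- sweep(mm, 2, baseVec, `*`)
      vv[, "ve"] <- pmin(vv[, "ve"], 1)
      vv[, "rim_percent"] <- pmin(pmax(vv[, "rim_percent"], 0), 100)
      vv[, "necrosis_percent"] <- pmin(pmax(vv[, "necrosis_percent"], 0), 100)
      idx <- row + seq_len(nTp)
      valM[idx, ] <- vv
      multM[idx, ] <- mm
      sid[idx] <- id
      grp[idx] <- g
      tp[idx] <- .studyTimepoints
      row <- row + nTp
    }
  }
  rec <- data.frame(subject_id = sid, group = grp, timepoint = tp,
                    valM, stringsAsFactors = FALSE)
  rec <- validateRecords(rec)
  attr(rec, "multipliers") <- data.frame(
    subject_id = sid, group = grp, timepoint = tp, multM,
    stringsAsFactors = FALSE)
  rec
}
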