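#' @include AllClasses.R AllGenerics.R utils.R
NULL

# Weighted log-linear mono-exponential fit, vectorized over voxels.
# signals: nvox x nb matrix; weights S^2 (the classical variance-stabilizing
# choice for log-transformed magnitude data). Voxels with fewer than 3
# positive samples get NA estimates.
.adcLoglinear <- function(signals, b) {
  pos <- signals > 0
  w <- signals^2 * pos
  y <- log(pmax(signals, .Machine$double.xmin))
  W <- rowSums(w)
  Sx <- as.numeric(w %*% b)
  Sxx <- as.numeric(w %*% b^2)
  Sy <- rowSums(w * y)
  Sxy <- rowSums(w * y * rep(b, each = nrow(signals)))
  delta <- W * Sxx - Sx^2
  slope <- (W * Sxy - Sx * Sy) / delta
  inter <- (Sxx * Sy - Sx * Sxy) / delta
  nUsed <- rowSums(pos)
  bad <- nUsed < 3L | !is.finite(slope)
  # constant signal: zero slope by construction, but guard the 0/0 case
  flat <- !bad & delta <= .Machine$double.eps * W * Sxx
  slope[flat] <- 0
  inter[flat] <- ifelse(W[flat] > 0, Sy[flat] / W[flat], NA_real_)
  slope[bad] <- NA_real_
  inter[bad] <- NA_real_
  list(adc = -slope, s0 = exp(inter), nUsed = nUsed)
}

# Vectorized Levenberg-Marquardt refinement of (s0, adc) on the signal
# scale, initialized from the log-linear estimates. All samples (including
# zeros from the Rician floor) participate; this is what removes the
# log-domain noise bias at high b.
.adcNonlinear <- function(signals, b, init, maxit = 60L, tol = 1e-12) {
  nv <- nrow(signals)
  s0 <- init$s0
  adc <- init$adc
  bad <- !is.finite(s0) | !is.finite(adc)
  s0[bad] <- apply(signals, 1, max)[bad]
  adc[bad] <- 1e-3
  lambda <- rep(1e-3, nv)
  B <- rep(b, each = nv)
  sse <- function(s0v, adcv) {
    f <- s0v * exp(-outer(adcv, b))
    rowSums((signals - f)^2)
  }
  cur <- sse(s0, adc)
  for (it in seq_len(maxit)) {
    E <- exp(-outer(adc, b))
    f <- s0 * E
    r <- signals - f
    D <- -s0 * matrix(B, nv) * E
    A11 <- rowSums(E * E)
    A12 <- rowSums(E * D)
    A22 <- rowSums(D * D)
    g1 <- rowSums(E * r)
    g2 <- rowSums(D * r)
    d11 <- A11 * (1 + lambda)
    d22 <- A22 * (1 + lambda)
    det <- d11 * d22 - A12^2
    det[det == 0] <- NA_real_
    step1 <- (g1 * d22 - g2 * A12) / det
    step2 <- (g2 * d11 - g1 * A12) / det
    s0c <- s0 + step1
    adcc <- adc + step2
    cand <- sse(s0c, adcc)
    ok <- is.finite(cand) & cand <= cur
    s0[ok] <- s0c[ok]; adc[ok] <- adcc[ok]; cur[ok] <- cand[ok]
    lambda[ok] <- pmax(lambda[ok] / 3, 1e-12)
    lambda[!ok] <- pmin(lambda[!ok] * 4, 1e12)
    if (all(!ok | (abs(step1) <= tol * pmax(abs(s0), 1) &
                   abs(step2) <= tol * pmax(abs(adc), 1e-6))))
      break
  }
  list(adc = adc, s0 = s0, sse = cur)
}

# shared engine: returns per-voxel estimates + diagnostics
.fitAdcMatrix <- function(signals, b, method = c("nonlinear", "loglinear")) {
  method <- match.arg(method)
  stopifnotFinite(signals, "DWI signal")
  if (any(signals < 0)) stop("DWI signal must be nonnegative")
  if (length(b) != ncol(signals))
    stop("b-value count does not match the signal series length")
  ll <- .adcLoglinear(signals, b)
  if (identical(method, "loglinear")) {
    adc <- ll$adc; s0 <- ll$s0
    f <- s0 * exp(-outer(adc, b))
    sseV <- rowSums((signals - f)^2, na.rm = TRUE)
    nUsed <- ll$nUsed
  } else {
    # non-positive samples are kept on the signal scale
    usable <- rowSums(signals > 0) >= 3L
    nl <- .adcNonlinear(signals, b, ll)
    adc <- ifelse(usable, nl$adc, NA_real_)
    s0 <- ifelse(usable, nl$s0, NA_real_)
    sseV <- nl$sse
    nUsed <- rep(length(b), nrow(signals))
    nUsed[!usable] <- rowSums(signals > 0)[!usable]
  }
  sst <- rowSums((signals - rowMeans(signals))^2)
  r2 <- ifelse(sst > 0, 1 - sseV / sst, NA_real_)
  clipped <- is.finite(adc) & adc < 0
  adc[clipped] <- 0
  list(adc = adc, s0 = s0, r_squared = r2, n_points_used = nUsed,
       clipped = clipped)
}

#' Fit a mono-exponential ADC to one signal-versus-b vector
#'
#' Mono-exponential diffusion model \eqn{S(b) = S_0 e^{-b\,ADC}} fitted to
#' all b-values. The log-linear method is a weighted least-squares fit of
#' \eqn{\ln S} on b with weights \eqn{S^2} (non-positive samples are
#' excluded, the log being undefined); the nonlinear method refines it by
#' Levenberg-Marquardt on the signal scale, keeping all samples. Nonlinear
#' is the default: at the Rician noise floor of high-b magnitude images
#' the log-domain fit is biased while the signal-scale fit is not.
#' Negative fitted ADC is clipped to 0 and flagged.
#'
#' @param signals per-b signal vector (nonnegative).
#' @param bValues diffusion weightings, s/mm^2.
#' @param method "nonlinear" (default) or "loglinear".
#' @return list with \code{adc} (mm^2/s), \code{s0}, \code{r_squared},
#'   \code{n_points_used}, \code{clipped}.
#' @examples
#' b <- c(0, 50, 100, 150, 200, 250, 300, 500, 750, 1000)
#' fitADC(800 * exp(-b * 1.2e-3), b)$adc
#' @export
fitADC <- function(signals, bValues, method = c("nonlinear", "loglinear")) {
  signals <- as.numeric(signals)
  stopifnotFinite(signals, "DWI signal")
  if (sum(signals > 0) < 3L)
    stop("fit error: fewer than 3 positive signal samples")
  res <- .fitAdcMatrix(matrix(signals, nrow = 1), bValues, method)
  lapply(res, `[`, 1L)
}

#' Per-voxel ADC map
#'
#' Voxel-wise mono-exponential fit over a mask (or the whole grid). Voxels
#' where the fit fails (fewer than 3 positive samples) are NA, never
#' silently zero; voxels outside the mask are NA.
#'
#' @param series \linkS4class{ImageSeries4D} of kind "dwi".
#' @param masks optional \linkS4class{RoiMaskSet}; with \code{region},
#'   restricts fitting to that region.
#' @param region region role to fit over when \code{masks} is given
#'   (default "tumor" plus liver and aorta: every non-background voxel).
#' @param method see \code{\link{fitADC}}.
#' @return A \linkS4class{ParamMap} of ADC in mm^2/s with diagnostics
#'   \code{s0}, \code{r_squared} and \code{clipped}.
#' @export
adcMap <- function(series, masks = NULL, region = NULL,
                   method = c("nonlinear", "loglinear")) {
  if (!identical(seriesKind(series), "dwi"))
    stop(sprintf("adcMap requires a dwi series, got '%s'", seriesKind(series)))
  dat <- seriesData(series)
  shape <- dim(dat)[1:3]
  nb <- dim(dat)[4]
  sel <- rep(TRUE, prod(shape))
  if (!is.null(masks)) {
    checkGridMatch(series, masks)
    sel <- if (is.null(region)) as.numeric(maskLabels(masks)) != 0
           else as.logical(regionMask(masks, region))
  }
  m <- matrix(dat, ncol = nb)[sel, , drop = FALSE]
  res <- .fitAdcMatrix(m, bValues(series), method)
  fill <- function(v) {
    out <- array(NA_real_, dim = shape)
    out[sel] <- v
    out
  }
  new("ParamMap", values = fill(res$adc), what = "ADC", units = "mm^2/s",
      diagnostics = list(s0 = fill(res$s0), r_squared = fill(res$r_squared),
                         clipped = fill(as.numeric(res$clipped))))
}

#' Mean parameter value over a region
#'
#' Mean over finite voxels of the region across all slices, mirroring
#' whole-tumor ROI averaging. Requires the region to hold at least 10
#' voxels (the delineation size floor).
#'
#' @param map \linkS4class{ParamMap}.
#' @param masks \linkS4class{RoiMaskSet} on the same grid.
#' @param region region role (e.g. "tumor", "liver").
#' @return scalar mean in the map's units.
#' @export
regionMean <- function(map, masks, region) {
  if (!identical(dim(mapValues(map)), dim(maskLabels(masks))))
    stop("map and mask grids differ; no silent resampling")
  sel <- regionMask(masks, region)
  if (sum(sel) < 10L)
    stop(sprintf("region '%s' has %d voxels, below the 10-voxel ROI floor",
                 region, sum(sel)))
  v <- mapValues(map)[sel]
  v <- v[is.finite(v)]
  if (!length(v)) stop(sprintf("region '%s' has no fitted voxels", region))
  mean(v)
}

#' Relative ADC
#'
#' Tumor ADC normalized to same-examination healthy-liver ADC.
#'
#' @param tumorAdc whole-tumor mean ADC (mm^2/s).
#' @param liverAdc normal-liver mean ADC (mm^2/s), > 0.
#' @return dimensionless ratio.
#' @export
relativeADC <- function(tumorAdc, liverAdc) {
  if (!is.finite(liverAdc) || liverAdc <= 0)
    stop("liver ADC must be positive")
  tumorAdc / liverAdc
}

#' Percent change from a pre-treatment value
#'
#' \eqn{100 (x_{post} - x_{pre}) / x_{pre}}; the shared endpoint transform
#' for rADC and tumor volume.
#'
#' @param pre pre-treatment value, non-zero.
#' @param post post-treatment value.
#' @return percent change.
#' @export
percentChange <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre == 0))
    stop("pre-treatment value must be finite and non-zero")
  100 * (post - pre) / pre
}
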