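#' @include AllClasses.R AllGenerics.R utils.R kinetics.R
NULL

#' Convert DSC signal to a Delta-R2* concentration curve
#'
#' Tracer-dilution conversion of susceptibility-contrast signal:
#' \eqn{\Delta R_2^*(t) = -\ln(S(t)/\bar S_{base}) / TE} with TE in
#' seconds, proportional to contrast concentration. Scale-invariant in the
#' signal and zero-mean over the baseline by construction.
#'
#' @param signal per-frame signal, all samples > 0.
#' @param nBaseline pre-bolus baseline frame count.
#' @param echoTime echo time in ms.
#' @param frameDuration seconds per frame.
#' @return A \linkS4class{ConcentrationCurve} in 1/s.
#' @examples
#' ## a signal drop to exp(-0.046) of baseline at TE = 46 ms is 1.0 1/s
#' @export
toDeltaR2star <- function(signal, nBaseline, echoTime, frameDuration) {
  stopifnotFinite(signal, "DSC signal")
  bad <- which(signal <= 0)
  if (length(bad))
    stop(sprintf("non-positive DSC signal at frame %d: log conversion undefined",
                 bad[1]))
  if (echoTime <= 0) stop("echo time must be positive")
  base <- mean(signal[seq_len(nBaseline)])
  teS <- echoTime / 1000
  concentrationCurve(frameTimes(length(signal), frameDuration),
                     -log(signal / base) / teS, nBaseline)
}

#' Relative blood volume by integral ratio
#'
#' Tracer-dilution rBV (arbitrary units): the ratio of the trapezoidal
#' integrals of the tissue and arterial concentration curves over a common
#' frame window. No recirculation correction is applied; the default
#' window is the full acquisition.
#'
#' @param tissue,aif \linkS4class{ConcentrationCurve}s on a shared grid.
#' @param window integer frame range c(first, last); default full curve.
#' @return rBV, arbitrary units.
#' @export
computeRBV <- function(tissue, aif, window = NULL) {
  times <- curveTimes(tissue)
  if (!isTRUE(all.equal(times, curveTimes(aif))))
    stop("tissue and AIF curves must share the time grid")
  n <- length(times)
  window <- if (is.null(window)) c(1L, n) else as.integer(window)
  if (window[1] < 1L || window[2] > n || window[2] <= window[1])
    stop("integration window must contain at least 2 frames within the acquisition")
  idx <- seq(window[1], window[2])
  denom <- pracma::trapz(times[idx], curveValues(aif)[idx])
  if (denom <= 0) stop("computation error: AIF integral is not positive")
  pracma::trapz(times[idx], curveValues(tissue)[idx]) / denom
}

#' Residue-function estimation by truncated-SVD deconvolution
#'
#' Discretizes the tracer-dilution convolution \eqn{C_t = \Delta t\, A\,
#' (F R)} with A the lower-triangular Toeplitz matrix of AIF samples,
#' inverts it by SVD with singular values below
#' \code{threshold} x (largest singular value) zeroed, and reports the
#' flow-scaled residue. rBF is the maximum of the scaled residue, rBV the
#' integral ratio (\code{\link{computeRBV}}), and MTT their quotient by
#' the central volume theorem. The standard (non-circulant) formulation is
#' used: curves are assumed delay-free.
#'
#' @param tissue,aif \linkS4class{ConcentrationCurve}s on a shared grid.
#' @param threshold truncation fraction of the largest singular value, in
#'   [0, 1); default 0.2, the common choice for this conditioning.
#' @return list with \code{scaled_residue} (F R(t) samples, a.u./s),
#'   \code{rbf}, \code{rbv}, \code{mtt} (s), \code{svd_threshold_used}.
#' @export
deconvolveTSVD <- function(tissue, aif, threshold = 0.2) {
  times <- curveTimes(tissue)
  if (!isTRUE(all.equal(times, curveTimes(aif))))
    stop("tissue and AIF curves must share the time grid")
  if (threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  ca <- curveValues(aif)
  ct <- curveValues(tissue)
  if (all(ca == 0)) stop("computation error: all-zero AIF")
  n <- length(ca)
  dt <- times[2] - times[1]
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j:n, j] <- ca[seq_len(n - j + 1L)]
  A <- dt * A
  sv <- svd(A)
  keep <- sv$d > 0 & sv$d >= threshold * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  fr <- sv$v %*% (dinv * (t(sv$u) %*% ct))
  fr <- as.numeric(fr)
  rbf <- max(fr)
  rbv <- computeRBV(tissue, aif)
  list(scaled_residue = fr,
       rbf = rbf,
       rbv = rbv,
       mtt = if (rbf > 0) rbv / rbf else NA_real_,
       svd_threshold_used = threshold)
}
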