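#' @include AllClasses.R AllGenerics.R utils.R kinetics.R
NULL

#' Convert dynamic signal to relative concentration
#'
#' Relative enhancement \eqn{C_{rel}(t) = (S(t) - \bar S_{base}) /
#' \bar S_{base}} with \eqn{\bar S_{base}} the mean over the pre-bolus
#' baseline frames; scale-invariant by construction.
#'
#' @param signal per-frame signal vector.
#' @param nBaseline pre-bolus baseline frame count.
#' @param frameDuration seconds per frame.
#' @return A \linkS4class{ConcentrationCurve} at frame midpoints.
#' @export
toRelativeConcentration <- function(signal, nBaseline, frameDuration) {
  stopifnotFinite(signal, "dynamic signal")
  base <- mean(signal[seq_len(nBaseline)])
  if (!is.finite(base) || base <= 0)
    stop("baseline mean signal must be positive")
  concentrationCurve(frameTimes(length(signal), frameDuration),
                     (signal - base) / base, nBaseline)
}

#' Mean region curve from a dynamic series
#'
#' Averages the signal over a region at each frame and converts to
#' relative concentration (\code{\link{toRelativeConcentration}}) for DCE,
#' or to the Delta-R2* curve (\code{\link{toDeltaR2star}}) for DSC.
#'
#' @param series \linkS4class{ImageSeries4D} of kind "dce" or "dsc".
#' @param masks \linkS4class{RoiMaskSet} on the same grid.
#' @param region region role.
#' @return A \linkS4class{ConcentrationCurve}.
#' @export
regionCurve <- function(series, masks, region) {
  kind <- seriesKind(series)
  if (!kind %in% c("dce", "dsc"))
    stop("regionCurve requires a dynamic (dce/dsc) series")
  checkGridMatch(series, masks)
  sel <- regionMask(masks, region)
  if (sum(sel) < 10L)
    stop(sprintf("region '%s' has %d voxels, below the 10-voxel ROI floor",
                 region, sum(sel)))
  dat <- seriesData(series)
  m <- matrix(dat, ncol = dim(dat)[4])[as.logical(sel), , drop = FALSE]
  sig <- colMeans(m)
  meta <- acqMeta(series)
  if (identical(kind, "dce"))
    toRelativeConcentration(sig, meta@baselineFrames, meta@dceFrameDuration)
  else
    toDeltaR2star(sig, meta@baselineFrames, meta@echoTime,
                  meta@dscFrameDuration)
}

#' Extract the arterial input function from an aorta curve
#'
#' "measured" mode returns the aorta concentration curve itself;
#' "biexp_fit" fits the biexponential population decay form (amplitudes
#' a1, a2 and rates m1, m2, bolus arrival fixed at the end of the baseline
#' frames) by variable projection — the amplitudes are solved linearly
#' for any rate pair, and the profiled residual is minimized over the two
#' rates from a coarse log-spaced grid start. This is robust to the
#' near-collinearity of slowly separating exponentials that defeats naive
#' four-parameter descent. Returns an \linkS4class{AifModel} with residual
#' diagnostics attached. A bolus is required: the post-bolus maximum must
#' exceed 5 pre-bolus standard deviations.
#'
#' @param aortaCurve \linkS4class{ConcentrationCurve} from the aorta ROI.
#' @param mode "measured" or "biexp_fit".
#' @return the curve, or an \linkS4class{AifModel} with attributes
#'   \code{residualNorm} and \code{converged}.
#' @export
extractAIF <- function(aortaCurve, mode = c("measured", "biexp_fit")) {
  mode <- match.arg(mode)
  times <- curveTimes(aortaCurve)
  vals <- curveValues(aortaCurve)
  nb <- baselineFrames(aortaCurve)
  if (nb < 2L || nb >= length(vals))
    stop("aorta curve must carry a valid baseline frame count")
  pre <- vals[seq_len(nb)]
  post <- vals[-seq_len(nb)]
  if (max(post) <= 0 || max(post) <= 5 * stats::sd(pre))
    stop("extraction error: no detectable bolus ",
         "(post-bolus max below 5 pre-bolus standard deviations)")
  if (identical(mode, "measured")) return(aortaCurve)

  dt <- times[2] - times[1]
  bolusTime <- nb * dt
  tauMin <- (times[-seq_len(nb)] - bolusTime) / 60
  y <- post

  # variable projection: profile out the (linear) amplitudes
  amplitudes <- function(m) {
    X <- cbind(exp(-m[1] * tauMin), exp(-m[2] * tauMin))
    cf <- tryCatch(qr.solve(X, y), error = function(e) c(NA_real_, NA_real_))
    list(cf = cf, fitted = if (all(is.finite(cf))) X %*% cf else NULL)
  }
  profiled <- function(logm) {
    a <- amplitudes(exp(logm))
    if (is.null(a$fitted)) return(1e30)
    sum((y - a$fitted)^2)
  }
  grid <- expand.grid(l1 = log(10^seq(-2, 1, by = 0.25)),
                      l2 = log(10^seq(-3, 0, by = 0.25)))
  grid <- grid[grid$l1 > grid$l2, ]
  sse <- apply(grid, 1, profiled)
  start <- as.numeric(grid[which.min(sse), ])
  op <- stats::optim(start, profiled, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-15))
  m <- sort(exp(op$par), decreasing = TRUE)  # m1 is the fast rate
  am <- amplitudes(m)
  converged <- all(is.finite(am$cf)) && all(am$cf > 0)
  if (!converged) {  # degenerate data: fall back to a single exponential
    cf1 <- stats::lm(log(pmax(y, 1e-12)) ~ tauMin)
    m <- c(max(1e-4, -unname(stats::coef(cf1)[2])), 1e-4)
    am <- amplitudes(m)
    am$cf <- pmax(am$cf, 1e-9)
  }
  rn <- sqrt(op$value)
  out <- aifModel(doseScale = 1, a1 = am$cf[1], a2 = am$cf[2],
                  m1 = m[1], m2 = m[2], bolusArrivalFrame = nb)
  attr(out, "residualNorm") <- rn
  attr(out, "converged") <- converged
  out
}

#' Fit the standard Tofts model to a tissue curve
#'
#' Bounded nonlinear least squares of \code{\link{toftsForward}} against a
#' tissue concentration curve, estimating the volume transfer constant
#' Ktrans (1/min) and the extracellular volume fraction ve. Fitting is on
#' the relative-concentration scale (no AIF absolute scaling or
#' hematocrit correction), so Ktrans is comparable within-study only.
#' Non-convergence is reported through the \code{converged} flag, never an
#' exception; an all-zero tissue curve yields Ktrans = 0 with zero
#' residual.
#'
#' @param tissue \linkS4class{ConcentrationCurve}.
#' @param aif sampled AIF on the same grid or an \linkS4class{AifModel}
#'   (evaluated with fine-grid quadrature, \code{refine}).
#' @param init optional c(ktrans, ve) start; default c(0.1, 0.3).
#' @param bounds list with \code{lower} and \code{upper} c(ktrans, ve);
#'   default Ktrans in [0, 5] 1/min, ve in [1e-3, 1].
#' @param refine quadrature subdivision for an AifModel AIF (default 8).
#' @param bolusTime bolus arrival (s); defaults to
#'   \code{baselineFrames * dt} of the tissue curve.
#' @return list with \code{ktrans}, \code{ve}, \code{residual_norm},
#'   \code{converged}, \code{n_iterations}.
#' @export
fitTofts <- function(tissue, aif, init = c(ktrans = 0.1, ve = 0.3),
                     bounds = list(lower = c(0, 1e-3), upper = c(5, 1)),
                     refine = 8L, bolusTime = NULL) {
  times <- curveTimes(tissue)
  y <- curveValues(tissue)
  stopifnotFinite(y, "tissue curve")
  if (is(aif, "ConcentrationCurve") &&
      !isTRUE(all.equal(curveTimes(aif), times)))
    stop("tissue and AIF curves must share the time grid")
  if (is.null(bolusTime))
    bolusTime <- baselineFrames(tissue) * (times[2] - times[1])
  useRefine <- if (is(aif, "ArterialInput")) as.integer(refine) else 1L

  if (all(abs(y) < .Machine$double.eps))
    return(list(ktrans = 0, ve = init[[2]], residual_norm = 0,
                converged = TRUE, n_iterations = 0L))

  obj <- function(p) {
    # finite-difference gradient probes can step just outside the bounds
    p <- pmax(pmin(p, bounds$upper), bounds$lower)
    ct <- curveValues(toftsForward(p[1], p[2], aif, times,
                                   refine = useRefine,
                                   bolusTime = bolusTime))
    v <- sum((y - ct)^2)
    if (!is.finite(v)) 1e30 else v
  }
  run <- function(start) try(
    stats::optim(start, obj, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = 500, factr = 1e5)), silent = TRUE)
  fit <- run(c(init[[1]], init[[2]]))
  if (inherits(fit, "try-error"))
    return(list(ktrans = NA_real_, ve = NA_real_, residual_norm = NA_real_,
                converged = FALSE, n_iterations = NA_integer_))
  evals <- fit$counts[["function"]]
  if (fit$convergence != 0L) {
    # a line-search abort at a near-optimal point is common; a restart
    # from the found point settles whether the optimum was reached
    fit2 <- run(fit$par)
    if (!inherits(fit2, "try-error") && fit2$value <= fit$value) {
      improved <- fit$value - fit2$value
      fit2$convergence <- ifelse(
        fit2$convergence == 0L || improved <= 1e-9 * (1 + fit$value), 0L, 1L)
      evals <- evals + fit2$counts[["function"]]
      fit <- fit2
    }
  }
  list(ktrans = fit$par[1], ve = fit$par[2],
       residual_norm = sqrt(fit$value),
       converged = fit$convergence == 0L,
       n_iterations = as.integer(evals))
}
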