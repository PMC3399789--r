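#' @include AllClasses.R AllGenerics.R utils.R kinetics.R phantom-geometry.R
NULL

.checkTruthGrid <- function(masks, truth) {
  if (!identical(dim(maskLabels(masks)), dim(truth@adcMap)))
    stop("truth maps do not cover the mask grid")
  invisible(TRUE)
}

#' Simulate a multi-b DWI series
#'
#' Forward mono-exponential diffusion signal \eqn{S(b) = S_0 e^{-b\,ADC}}
#' per voxel, corrupted by Rician noise of scale \code{noiseSigma}
#' (Gaussian noise on two quadrature channels, magnitude afterwards) —
#' the noise model of magnitude MRI, whose floor at high b is what biases
#' naive log-linear ADC fitting.
#'
#' @param masks \linkS4class{RoiMaskSet} on the truth grid.
#' @param truth \linkS4class{PhantomTruth}.
#' @param meta \linkS4class{AcquisitionMeta} supplying the b-values.
#' @return An \linkS4class{ImageSeries4D} of kind "dwi"; bit-reproducible
#'   for a fixed truth seed.
#' @export
simulateDWI <- function(masks, truth, meta = acquisitionMeta()) {
  .checkTruthGrid(masks, truth)
  b <- meta@bValues
  shape <- dim(truth@adcMap)
  s0 <- as.numeric(truth@s0Map)
  adc <- as.numeric(truth@adcMap)
  sig <- vapply(b, function(bb) s0 * exp(-bb * adc),
                numeric(length(s0)))
  sig <- withSeed(deriveSeed(truth@seed, "dwi"),
                  riceCorrupt(sig, truth@noiseSigma))
  imageSeries4D(array(sig, dim = c(shape, length(b))), meta, "dwi")
}

#' Simulate a DCE-MRI dynamic series
#'
#' Forward standard Tofts model per tissue class with linearized
#' enhancement: tissue concentration from
#' \code{\link{toftsForward}} driven by the phantom's biexponential AIF
#' (fine-grid quadrature, \code{refine = 10}), and signal
#' \eqn{S(t) = S_0 (1 + \alpha\, C(t))}. Aorta voxels carry the AIF signal
#' itself; all pre-bolus frames have zero concentration.
#'
#' @param masks,truth,meta as in \code{\link{simulateDWI}}.
#' @param alpha enhancement linearity constant (signal per unit relative
#'   concentration); default 1.
#' @return An \linkS4class{ImageSeries4D} of kind "dce".
#' @export
simulateDCE <- function(masks, truth, meta = acquisitionMeta(), alpha = 1) {
  .checkTruthGrid(masks, truth)
  times <- frameTimes(meta@nFrames, meta@dceFrameDuration)
  bolusTime <- meta@baselineFrames * meta@dceFrameDuration
  shape <- dim(truth@adcMap)
  nvox <- prod(shape)
  kt <- as.numeric(truth@ktransMap)
  ve <- as.numeric(truth@veMap)
  if (any(kt > 0 & ve == 0))
    stop("ve = 0 with ktrans > 0: transfer kernel undefined")
  aorta <- as.numeric(regionMask(masks, "aorta"))

  conc <- matrix(0, nvox, meta@nFrames)
  classes <- unique(data.frame(kt = kt, ve = ve)[kt > 0 & aorta == 0, ])
  for (i in seq_len(nrow(classes))) {
    ct <- curveValues(toftsForward(classes$kt[i], classes$ve[i], truth@aif,
                                   times, refine = 10L,
                                   bolusTime = bolusTime))
    sel <- kt == classes$kt[i] & ve == classes$ve[i] & aorta == 0
    conc[sel, ] <- rep(ct, each = sum(sel))
  }
  if (any(aorta > 0)) {
    cp <- aifConcentration(truth@aif, times, bolusTime)
    conc[aorta > 0, ] <- rep(cp, each = sum(aorta > 0))
  }
  sig <- as.numeric(truth@s0Map) * (1 + alpha * conc)
  sig <- withSeed(deriveSeed(truth@seed, "dce"),
                  riceCorrupt(sig, truth@noiseSigma))
  imageSeries4D(array(sig, dim = c(shape, meta@nFrames)), meta, "dce")
}

#' Simulate a DSC-MRI dynamic series
#'
#' Forward tracer-dilution model: tissue concentration
#' \eqn{C(t) = F (C_a \ast R)(t)} with a boxcar (default) or exponential
#' residue, driven by the phantom's first-pass AIF, and
#' susceptibility-contrast signal \eqn{S(t) = S_0 e^{-TE\, C(t)}} (TE in
#' seconds; the proportionality constant between concentration and
#' Delta-R2* is absorbed into the arbitrary concentration units). Perfused
#' voxels dip below baseline after the bolus; aorta voxels carry the AIF.
#'
#' @param masks,truth,meta as in \code{\link{simulateDWI}}.
#' @param residueModel "boxcar" or "exponential".
#' @return An \linkS4class{ImageSeries4D} of kind "dsc".
#' @export
simulateDSC <- function(masks, truth, meta = acquisitionMeta(),
                        residueModel = c("boxcar", "exponential")) {
  residueModel <- match.arg(residueModel)
  .checkTruthGrid(masks, truth)
  times <- frameTimes(meta@nFrames, meta@dscFrameDuration)
  bolusTime <- meta@baselineFrames * meta@dscFrameDuration
  shape <- dim(truth@adcMap)
  nvox <- prod(shape)
  fl <- as.numeric(truth@flowMap)
  mtt <- as.numeric(truth@mttMap)
  aorta <- as.numeric(regionMask(masks, "aorta"))

  conc <- matrix(0, nvox, meta@nFrames)
  classes <- unique(data.frame(fl = fl, mtt = mtt)[fl > 0 & aorta == 0, ])
  for (i in seq_len(nrow(classes))) {
    ct <- curveValues(residueConvolve(classes$fl[i], classes$mtt[i],
                                      truth@dscAif, times,
                                      residueModel = residueModel,
                                      refine = 10L, bolusTime = bolusTime))
    sel <- fl == classes$fl[i] & mtt == classes$mtt[i] & aorta == 0
    conc[sel, ] <- rep(ct, each = sum(sel))
  }
  if (any(aorta > 0)) {
    ca <- aifConcentration(truth@dscAif, times, bolusTime)
    conc[aorta > 0, ] <- rep(ca, each = sum(aorta > 0))
  }
  teS <- meta@echoTime / 1000
  sig <- as.numeric(truth@s0Map) * exp(-teS * conc)
  sig <- withSeed(deriveSeed(truth@seed, "dsc"),
                  riceCorrupt(sig, truth@noiseSigma))
  imageSeries4D(array(sig, dim = c(shape, meta@nFrames)), meta, "dsc")
}
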