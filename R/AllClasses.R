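#' @import methods
NULL

#' Acquisition metadata for a 4D series
#'
#' Holds the pulse-sequence parameters the quantification needs: the
#' diffusion weightings of the DWI protocol, the dynamic frame durations of
#' the DCE and DSC protocols, the number of dynamic frames and of pre-bolus
#' baseline frames, the echo time used by the susceptibility-contrast
#' conversion, and the voxel geometry.
#'
#' @slot bValues numeric, diffusion weightings in s/mm^2; strictly
#'   increasing, first value 0.
#' @slot dceFrameDuration numeric(1), seconds per DCE frame.
#' @slot dscFrameDuration numeric(1), seconds per DSC frame.
#' @slot nFrames integer(1), dynamic frame count (DCE/DSC).
#' @slot baselineFrames integer(1), pre-bolus frames; the bolus arrives at
#'   the end of frame \code{baselineFrames}.
#' @slot echoTime numeric(1), echo time in ms (DSC conversion).
#' @slot sliceThickness,sliceGap numeric(1), mm.
#' @slot inPlaneSpacing numeric(2), mm per voxel in x and y.
#' @export
setClass("AcquisitionMeta", representation(
  bValues = "numeric",
  dceFrameDuration = "numeric",
  dscFrameDuration = "numeric",
  nFrames = "integer",
  baselineFrames = "integer",
  echoTime = "numeric",
  sliceThickness = "numeric",
  sliceGap = "numeric",
  inPlaneSpacing = "numeric"
))

setValidity("AcquisitionMeta", function(object) {
  msgs <- character()
  b <- object@bValues
  if (length(b) < 2L || b[1] != 0 || any(diff(b) <= 0))
    msgs <- c(msgs, "bValues must be strictly increasing with first value 0")
  if (object@baselineFrames < 2L || object@baselineFrames >= object@nFrames)
    msgs <- c(msgs, "baselineFrames must be >= 2 and < nFrames")
  geom <- c(object@dceFrameDuration, object@dscFrameDuration,
            object@echoTime, object@sliceThickness + object@sliceGap,
            object@inPlaneSpacing)
  if (object@sliceGap < 0) msgs <- c(msgs, "sliceGap must be >= 0")
  if (any(!is.finite(geom)) || any(geom <= 0))
    msgs <- c(msgs, "frame durations, echo time and voxel geometry must be positive")
  if (length(object@inPlaneSpacing) != 2L)
    msgs <- c(msgs, "inPlaneSpacing must have length 2")
  if (length(msgs)) msgs else TRUE
})

#' Construct acquisition metadata
#'
#' Defaults reproduce the study protocol this package emulates: 10 b-values
#' from 0 to 1000 s/mm^2, 80 DCE frames of 3.7 s and 80 DSC frames of 2 s
#' with the contrast bolus arriving after frame 20, a TE of 46 ms for the
#' DSC sequence, and 2 mm slices separated by a 0.2 mm gap.
#'
#' @param bValues diffusion weightings (s/mm^2).
#' @param dceFrameDuration,dscFrameDuration seconds per dynamic frame.
#' @param nFrames dynamic frame count.
#' @param baselineFrames pre-bolus frame count.
#' @param echoTime echo time, ms.
#' @param sliceThickness,sliceGap slice geometry, mm.
#' @param inPlaneSpacing in-plane voxel size, mm (length 2).
#' @return An \linkS4class{AcquisitionMeta} object.
#' @examples
#' meta <- acquisitionMeta()
#' bValues(meta)
#' @export
acquisitionMeta <- function(bValues = c(0, 50, 100, 150, 200, 250, 300, 500, 750, 1000),
                            dceFrameDuration = 3.7,
                            dscFrameDuration = 2,
                            nFrames = 80L,
                            baselineFrames = 20L,
                            echoTime = 46,
                            sliceThickness = 2,
                            sliceGap = 0.2,
                            inPlaneSpacing = c(0.5, 0.5)) {
  new("AcquisitionMeta",
      bValues = as.numeric(bValues),
      dceFrameDuration = as.numeric(dceFrameDuration),
      dscFrameDuration = as.numeric(dscFrameDuration),
      nFrames = as.integer(nFrames),
      baselineFrames = as.integer(baselineFrames),
      echoTime = as.numeric(echoTime),
      sliceThickness = as.numeric(sliceThickness),
      sliceGap = as.numeric(sliceGap),
      inPlaneSpacing = as.numeric(inPlaneSpacing))
}

#' A 4D image series
#'
#' A nonnegative signal array indexed (x, y, z, series) where the last axis
#' is the b-value axis for DWI and the dynamic-frame axis for DCE/DSC.
#' Voxel indexing is grid-based with the series axis last; this convention
#' is asserted at every boundary.
#'
#' @slot data 4D numeric array, nonnegative, finite.
#' @slot meta \linkS4class{AcquisitionMeta}.
#' @slot seriesKind one of "dwi", "dce", "dsc".
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("ImageSeries4D", representation(
  data = "array",
  meta = "AcquisitionMeta",
  seriesKind = "character",
  affine = "matrix"
))

setValidity("ImageSeries4D", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 4L)
    return("data must be a 4D array (x, y, z, series)")
  if (!object@seriesKind %in% c("dwi", "dce", "dsc"))
    msgs <- c(msgs, "seriesKind must be one of dwi, dce, dsc")
  expected <- if (identical(object@seriesKind, "dwi"))
    length(object@meta@bValues) else object@meta@nFrames
  if (dim(object@data)[4] != expected)
    msgs <- c(msgs, sprintf(
      "series axis length %d does not match metadata (%d expected for %s)",
      dim(object@data)[4], expected, object@seriesKind))
  if (any(!is.finite(object@data)))
    msgs <- c(msgs, "signal must be finite")
  else if (any(object@data < 0))
    msgs <- c(msgs, "signal must be nonnegative")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msgs <- c(msgs, "affine must be 4x4")
  if (length(msgs)) msgs else TRUE
})

#' Construct a 4D image series
#'
#' @param data 4D array (x, y, z, series).
#' @param meta \linkS4class{AcquisitionMeta}.
#' @param seriesKind "dwi", "dce" or "dsc".
#' @param affine optional 4x4 voxel-to-world matrix; by default a diagonal
#'   scaling by the voxel size (in-plane spacing and slice pitch
#'   thickness + gap).
#' @return An \linkS4class{ImageSeries4D}.
#' @export
imageSeries4D <- function(data, meta, seriesKind, affine = NULL) {
  if (is.null(affine)) {
    sp <- c(meta@inPlaneSpacing, meta@sliceThickness + meta@sliceGap)
    affine <- diag(c(sp, 1))
  }
  new("ImageSeries4D", data = data, meta = meta,
      seriesKind = seriesKind, affine = affine)
}

#' Integer-labelled ROI mask set
#'
#' A label volume on the image grid together with a legend mapping labels
#' to semantic region roles. The tumor is the union of the viable rim and
#' the necrotic core; all other regions are pairwise disjoint. Masks are
#' stored on the image grid, never as world-space polygons.
#'
#' @slot labels 3D integer array.
#' @slot legend named integer vector mapping role
#'   (background/viable_rim/necrotic_core/liver/aorta) to label value.
#' @slot spacing numeric(3): in-plane spacing (mm) and slice pitch
#'   (thickness + gap, mm), used for all metric measurements.
#' @export
setClass("RoiMaskSet", representation(
  labels = "array",
  legend = "integer",
  spacing = "numeric"
))

.roiRoles <- c("background", "viable_rim", "necrotic_core", "liver", "aorta")

setValidity("RoiMaskSet", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3D array")
  if (is.null(names(object@legend)) ||
      !all(names(object@legend) %in% .roiRoles))
    msgs <- c(msgs, paste("legend names must be among:",
                          paste(.roiRoles, collapse = ", ")))
  if (anyDuplicated(object@legend))
    msgs <- c(msgs, "legend label values must be unique")
  if (!all(unique(as.integer(object@labels)) %in% object@legend))
    msgs <- c(msgs, "labels contain values absent from the legend")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive values")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ROI mask set
#'
#' @param labels 3D integer array.
#' @param legend named integer vector (role -> label).
#' @param spacing numeric(3), mm: in-plane x, y and slice pitch.
#' @return A \linkS4class{RoiMaskSet}.
#' @export
roiMaskSet <- function(labels,
                       legend = c(background = 0L, viable_rim = 1L,
                                  necrotic_core = 2L, liver = 3L, aorta = 4L),
                       spacing = c(0.5, 0.5, 2.2)) {
  storage.mode(labels) <- "integer"
  new("RoiMaskSet", labels = labels,
      legend = vapply(legend, as.integer, integer(1)),
      spacing = as.numeric(spacing))
}

#' Per-voxel parameter map
#'
#' A scalar map of one fitted quantity (ADC, Ktrans, ve, rBV, rBF) with its
#' units and fit diagnostics. Voxels where the fit failed are NA, never
#' silently zero.
#'
#' @slot values 3D numeric array (NA where the fit failed or outside the mask).
#' @slot what quantity name.
#' @slot units unit string.
#' @slot diagnostics list of same-shaped diagnostic arrays (e.g. r_squared,
#'   clipped flags).
#' @export
setClass("ParamMap", representation(
  values = "array",
  what = "character",
  units = "character",
  diagnostics = "list"
))

setValidity("ParamMap", function(object) {
  if (length(dim(object@values)) != 3L) "values must be a 3D array" else TRUE
})

#' Dynamic concentration-time curve
#'
#' Relative concentration sampled at dynamic frame midpoints on a uniform
#' time grid, with the pre-bolus baseline frame count recorded.
#'
#' @slot times seconds, strictly increasing, uniformly spaced.
#' @slot values relative concentration (dimensionless, or 1/s for the
#'   susceptibility-contrast Delta-R2* curve).
#' @slot baselineFrames pre-bolus frame count.
#' @export
setClass("ConcentrationCurve", representation(
  times = "numeric",
  values = "numeric",
  baselineFrames = "integer"
))

setValidity("ConcentrationCurve", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@values))
    msgs <- c(msgs, "times and values must have equal length")
  d <- diff(object@times)
  if (length(d) && (any(d <= 0) ||
      diff(range(d)) > 1e-8 * max(abs(d))))
    msgs <- c(msgs, "times must be strictly increasing and uniformly spaced")
  if (object@baselineFrames < 0L ||
      object@baselineFrames > length(object@times))
    msgs <- c(msgs, "baselineFrames out of range")
  if (length(msgs)) msgs else TRUE
})

#' Construct a concentration curve
#' @param times seconds (uniform grid).
#' @param values concentration values.
#' @param baselineFrames pre-bolus frame count.
#' @return A \linkS4class{ConcentrationCurve}.
#' @export
concentrationCurve <- function(times, values, baselineFrames) {
  new("ConcentrationCurve", times = as.numeric(times),
      values = as.numeric(values), baselineFrames = as.integer(baselineFrames))
}

#' Population arterial input function model
#'
#' Biexponential plasma decay after an instantaneous bolus at the end of
#' the baseline frames: Cp(t) = dose * (a1 exp(-m1 tau) + a2 exp(-m2 tau))
#' for tau = t - t0 >= 0 (tau in minutes), zero before arrival.
#'
#' @slot doseScale overall amplitude, arbitrary units.
#' @slot a1,a2 amplitudes (> 0).
#' @slot m1,m2 decay rates, 1/min (> 0); m1 is the fast component.
#' @slot bolusArrivalFrame frame after which the bolus arrives (equals the
#'   baseline frame count of the paired acquisition).
#' @export
setClass("AifModel", representation(
  doseScale = "numeric",
  a1 = "numeric", a2 = "numeric",
  m1 = "numeric", m2 = "numeric",
  bolusArrivalFrame = "integer"
))

setValidity("AifModel", function(object) {
  p <- c(object@doseScale, object@a1, object@a2, object@m1, object@m2)
  msgs <- character()
  if (any(!is.finite(p)) || any(p <= 0))
    msgs <- c(msgs, "doseScale, amplitudes and decay rates must be positive")
  if (object@bolusArrivalFrame < 1L)
    msgs <- c(msgs, "bolusArrivalFrame must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AIF model
#'
#' Default amplitudes and decay rates follow the classical biexponential
#' population plasma-decay parameterization (fast distribution phase plus
#' slow elimination phase) with arrival after the 20th dynamic frame.
#'
#' @param doseScale amplitude scale (a.u.).
#' @param a1,a2 component amplitudes.
#' @param m1,m2 component decay rates (1/min).
#' @param bolusArrivalFrame arrival frame index.
#' @return An \linkS4class{AifModel}.
#' @export
aifModel <- function(doseScale = 1, a1 = 3.99, a2 = 4.78,
                     m1 = 0.144, m2 = 0.0111, bolusArrivalFrame = 20L) {
  new("AifModel", doseScale = as.numeric(doseScale),
      a1 = as.numeric(a1), a2 = as.numeric(a2),
      m1 = as.numeric(m1), m2 = as.numeric(m2),
      bolusArrivalFrame = as.integer(bolusArrivalFrame))
}

#' Gamma-variate first-pass bolus model
#'
#' The standard parameterization of a dispersed first-pass arterial bolus
#' for susceptibility-contrast imaging:
#' \deqn{C_a(t) = K\,(\tau/t_p)^{\alpha} e^{\alpha(1 - \tau/t_p)}, \quad
#'   \tau = t - t_0 \ge 0,}
#' which rises smoothly from zero and peaks at \eqn{K} a time \eqn{t_p}
#' after bolus arrival. Recirculation is not modelled.
#'
#' @slot doseScale peak concentration K, a.u.
#' @slot shape dimensionless shape exponent alpha (> 0).
#' @slot timeToPeak seconds from arrival to peak (> 0).
#' @slot bolusArrivalFrame frame after which the bolus arrives.
#' @export
setClass("GammaVariateAif", representation(
  doseScale = "numeric",
  shape = "numeric",
  timeToPeak = "numeric",
  bolusArrivalFrame = "integer"
))

setValidity("GammaVariateAif", function(object) {
  p <- c(object@doseScale, object@shape, object@timeToPeak)
  if (any(!is.finite(p)) || any(p <= 0))
    return("doseScale, shape and timeToPeak must be positive")
  if (object@bolusArrivalFrame < 1L) return("bolusArrivalFrame must be >= 1")
  TRUE
})

#' Construct a gamma-variate AIF
#'
#' Defaults emulate a small-animal first-pass bolus on a 2 s dynamic
#' protocol: peak 6 a.u. reached 5 s after arrival with shape 3.
#'
#' @param doseScale peak concentration (a.u.).
#' @param shape shape exponent.
#' @param timeToPeak seconds to peak after arrival.
#' @param bolusArrivalFrame arrival frame index.
#' @return A \linkS4class{GammaVariateAif}.
#' @export
gammaVariateAif <- function(doseScale = 6, shape = 3, timeToPeak = 5,
                            bolusArrivalFrame = 20L) {
  new("GammaVariateAif", doseScale = as.numeric(doseScale),
      shape = as.numeric(shape), timeToPeak = as.numeric(timeToPeak),
      bolusArrivalFrame = as.integer(bolusArrivalFrame))
}

#' @rdname gammaVariateAif
#' @export
setClassUnion("ArterialInput", c("AifModel", "GammaVariateAif"))

#' Ground-truth parameter maps of a digital phantom
#'
#' Per-voxel true quantities from which the simulators generate signals,
#' and against which recovery tests compare fits. Wherever the flow map is
#' positive the truth satisfies the central volume theorem:
#' bvMap = flowMap * mttMap.
#'
#' @slot adcMap mm^2/s. @slot s0Map a.u. @slot ktransMap 1/min.
#' @slot veMap fraction. @slot flowMap a.u. @slot bvMap a.u.
#' @slot mttMap seconds.
#' @slot aif \linkS4class{AifModel} driving DCE simulation.
#' @slot dscAif arterial input driving DSC simulation (by default a
#'   \linkS4class{GammaVariateAif} first-pass bolus).
#' @slot noiseSigma Rician noise scale (a.u.).
#' @slot seed integer seed for reproducible simulation.
#' @export
setClass("PhantomTruth", representation(
  adcMap = "array", s0Map = "array",
  ktransMap = "array", veMap = "array",
  flowMap = "array", bvMap = "array", mttMap = "array",
  aif = "AifModel", dscAif = "ArterialInput",
  noiseSigma = "numeric", seed = "integer"
))

setValidity("PhantomTruth", function(object) {
  msgs <- character()
  maps <- list(adc = object@adcMap, s0 = object@s0Map,
               ktrans = object@ktransMap, ve = object@veMap,
               flow = object@flowMap, bv = object@bvMap, mtt = object@mttMap)
  shp <- dim(object@adcMap)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!identical(dim(m), shp))
      msgs <- c(msgs, sprintf("%s map shape differs from adc map", nm))
    if (any(m < 0, na.rm = TRUE))
      msgs <- c(msgs, sprintf("%s map must be nonnegative", nm))
  }
  if (any(object@veMap > 1)) msgs <- c(msgs, "veMap must be <= 1")
  pos <- object@flowMap > 0
  if (any(pos)) {
    err <- abs(object@bvMap[pos] - object@flowMap[pos] * object@mttMap[pos])
    if (max(err) > 1e-9 * max(object@bvMap))
      msgs <- c(msgs, "central-volume consistency violated: bv != flow * mtt")
  }
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  if (length(msgs)) msgs else TRUE
})
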