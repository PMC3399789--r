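#' @include AllClasses.R
NULL

#' Accessors for the core data objects
#'
#' Slot access goes through these accessors everywhere.
#'
#' @param object an object of the documented class.
#' @param ... unused.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seriesData", function(object, ...) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setMethod("seriesData", "ImageSeries4D", function(object, ...) object@data)

#' @rdname accessors
#' @export
setGeneric("acqMeta", function(object, ...) standardGeneric("acqMeta"))
#' @rdname accessors
#' @export
setMethod("acqMeta", "ImageSeries4D", function(object, ...) object@meta)

#' @rdname accessors
#' @export
setGeneric("seriesKind", function(object, ...) standardGeneric("seriesKind"))
#' @rdname accessors
#' @export
setMethod("seriesKind", "ImageSeries4D", function(object, ...) object@seriesKind)

#' @rdname accessors
#' @export
setGeneric("bValues", function(object, ...) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setMethod("bValues", "AcquisitionMeta", function(object, ...) object@bValues)
#' @rdname accessors
#' @export
setMethod("bValues", "ImageSeries4D", function(object, ...) object@meta@bValues)

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(object, ...) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setMethod("maskLabels", "RoiMaskSet", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setGeneric("maskLegend", function(object, ...) standardGeneric("maskLegend"))
#' @rdname accessors
#' @export
setMethod("maskLegend", "RoiMaskSet", function(object, ...) object@legend)

#' @rdname accessors
#' @export
setGeneric("maskSpacing", function(object, ...) standardGeneric("maskSpacing"))
#' @rdname accessors
#' @export
setMethod("maskSpacing", "RoiMaskSet", function(object, ...) object@spacing)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object, ...) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "ParamMap", function(object, ...) object@values)

#' @rdname accessors
#' @export
setGeneric("mapDiagnostics", function(object, ...) standardGeneric("mapDiagnostics"))
#' @rdname accessors
#' @export
setMethod("mapDiagnostics", "ParamMap", function(object, ...) object@diagnostics)

#' @rdname accessors
#' @export
setGeneric("curveTimes", function(object, ...) standardGeneric("curveTimes"))
#' @rdname accessors
#' @export
setMethod("curveTimes", "ConcentrationCurve", function(object, ...) object@times)

#' @rdname accessors
#' @export
setGeneric("curveValues", function(object, ...) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setMethod("curveValues", "ConcentrationCurve", function(object, ...) object@values)

#' @rdname accessors
#' @export
setGeneric("baselineFrames", function(object, ...) standardGeneric("baselineFrames"))
#' @rdname accessors
#' @export
setMethod("baselineFrames", "ConcentrationCurve",
          function(object, ...) object@baselineFrames)
#' @rdname accessors
#' @export
setMethod("baselineFrames", "AcquisitionMeta",
          function(object, ...) object@baselineFrames)

#' Logical mask of a semantic region
#'
#' Resolves a region role to a logical voxel mask. The "tumor" role is the
#' union of the viable rim and the necrotic core.
#'
#' @param object a \linkS4class{RoiMaskSet}.
#' @param region one of "tumor", "viable_rim", "necrotic_core", "liver",
#'   "aorta", "background".
#' @return logical 3D array.
#' @export
setGeneric("regionMask", function(object, region) standardGeneric("regionMask"))

#' @rdname regionMask
#' @export
setMethod("regionMask", "RoiMaskSet", function(object, region) {
  region <- match.arg(region, c("tumor", .roiRoles))
  lg <- object@legend
  labs <- if (identical(region, "tumor")) {
    lab <- lg[c("viable_rim", "necrotic_core")]
    lab <- lab[!is.na(lab)]
    if (!length(lab))
      stop("mask legend defines neither viable_rim nor necrotic_core; ",
           "the tumor region is undefined")
    lab
  } else {
    if (!region %in% names(lg))
      stop(sprintf("region '%s' is not present in the mask legend", region))
    lg[[region]]
  }
  array(object@labels %in% labs, dim = dim(object@labels))
})

#' @rdname regionMask
#' @export
setGeneric("regionVoxelCount", function(object, region)
  standardGeneric("regionVoxelCount"))
#' @rdname regionMask
#' @export
setMethod("regionVoxelCount", "RoiMaskSet", function(object, region)
  sum(regionMask(object, region)))

setMethod("show", "AcquisitionMeta", function(object) {
  cat("AcquisitionMeta:",
      length(object@bValues), "b-values (",
      min(object@bValues), "-", max(object@bValues), "s/mm^2 ),",
      object@nFrames, "dynamic frames,",
      object@baselineFrames, "baseline frames\n")
  cat("  DCE frame", object@dceFrameDuration, "s; DSC frame",
      object@dscFrameDuration, "s; TE", object@echoTime, "ms\n")
  cat("  slices", object@sliceThickness, "mm +", object@sliceGap,
      "mm gap; in-plane", paste(object@inPlaneSpacing, collapse = " x "),
      "mm\n")
})

setMethod("show", "ImageSeries4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageSeries4D [%s]: %d x %d x %d voxels, %d %s\n",
              object@seriesKind, d[1], d[2], d[3], d[4],
              if (object@seriesKind == "dwi") "b-values" else "frames"))
})

setMethod("show", "RoiMaskSet", function(object) {
  d <- dim(object@labels)
  cat(sprintf("RoiMaskSet: %d x %d x %d grid\n", d[1], d[2], d[3]))
  for (nm in names(object@legend)) {
    n <- sum(object@labels == object@legend[[nm]])
    if (nm != "background")
      cat(sprintf("  %-14s label %d: %d voxels\n", nm, object@legend[[nm]], n))
  }
})

setMethod("show", "ParamMap", function(object) {
  v <- object@values[is.finite(object@values)]
  cat(sprintf("ParamMap <%s> [%s]: %d fitted voxels", object@what,
              object@units, length(v)))
  if (length(v))
    cat(sprintf(", median %.4g (IQR %.4g-%.4g)",
                stats::median(v), stats::quantile(v, 0.25),
                stats::quantile(v, 0.75)))
  cat("\n")
})

setMethod("show", "ConcentrationCurve", function(object) {
  cat(sprintf("ConcentrationCurve: %d frames, dt %.3g s, %d baseline; peak %.4g\n",
              length(object@times),
              if (length(object@times) > 1) diff(object@times[1:2]) else NA_real_,
              object@baselineFrames, max(object@values)))
})

setMethod("show", "AifModel", function(object) {
  cat(sprintf(
    "AifModel: dose %.3g, a = (%.3g, %.3g), m = (%.3g, %.3g) 1/min, arrival after frame %d\n",
    object@doseScale, object@a1, object@a2, object@m1, object@m2,
    object@bolusArrivalFrame))
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@adcMap)
  cat(sprintf("PhantomTruth: %d x %d x %d grid, noise sigma %.3g, seed %d\n",
              d[1], d[2], d[3], object@noiseSigma, object@seed))
})
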