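#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Digitize the phantom anatomy as a label volume
#'
#' Builds the ROI geometry the quantification consumes: an ellipsoidal
#' tumor split into a viable rim and a necrotic core (the core is the inner
#' ellipsoid whose semi-axes are the tumor's minus the rim thickness), a
#' rectangular block of normal liver, and a cylindrical aorta segment for
#' AIF extraction. Voxel membership is decided on voxel centers; the slice
#' pitch used for coordinates and volumes is thickness + gap, attributing
#' the inter-slice gap to the nearer slice.
#'
#' Every referenced region must contain at least 10 voxels, mirroring the
#' ROI-size floor used in consensus delineation on real images.
#'
#' @param shape integer(3), grid dimensions.
#' @param spacing numeric(3), mm: in-plane x, y spacing and slice pitch.
#' @param tumorCenter numeric(3), mm, ellipsoid center (grid coordinates,
#'   origin at the corner voxel center).
#' @param tumorRadii numeric(3), mm, ellipsoid semi-axes.
#' @param rimThickness numeric(1), mm; must be smaller than the smallest
#'   semi-axis. A thickness equal to or above the smallest radius is a
#'   geometry error; \code{rimThickness = Inf} is not allowed — pass a core
#'   radius of 0 by using \code{rimThickness = min(tumorRadii)} minus a
#'   voxel if a near-solid rim is wanted.
#' @param liverBox list with \code{min} and \code{max} numeric(3) corners
#'   (mm) of the normal-liver block, or NULL to place a default block
#'   beside the tumor.
#' @param aortaCylinder list with \code{center} numeric(2) (mm, in-plane),
#'   \code{radius} (mm) and \code{zRange} numeric(2) (mm), or NULL for a
#'   default placement.
#' @return A \linkS4class{RoiMaskSet}; the per-region voxel counts are
#'   attached as attribute \code{"voxelCounts"}.
#' @examples
#' m <- makeGeometry(shape = c(48, 48, 16), spacing = c(1, 1, 2.2),
#'                   tumorRadii = c(10, 10, 8), rimThickness = 3)
#' regionVoxelCount(m, "tumor")
#' @export
makeGeometry <- function(shape = c(64, 64, 64),
                         spacing = c(0.5, 0.5, 0.5),
                         tumorCenter = (shape / 2) * spacing,
                         tumorRadii = c(8, 8, 8),
                         rimThickness = 2,
                         liverBox = NULL,
                         aortaCylinder = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) stop("shape must be 3 dims >= 2")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (rimThickness >= min(tumorRadii))
    stop(sprintf(
      "geometry error: rim thickness %.3g mm must be smaller than the smallest tumor radius %.3g mm",
      rimThickness, min(tumorRadii)))
  extent <- (shape - 1) * spacing
  if (any(tumorCenter - tumorRadii < 0) || any(tumorCenter + tumorRadii > extent))
    stop("geometry error: tumor ellipsoid does not fit inside the grid")

  x <- (seq_len(shape[1]) - 1) * spacing[1]
  y <- (seq_len(shape[2]) - 1) * spacing[2]
  z <- (seq_len(shape[3]) - 1) * spacing[3]
  X <- array(rep(x, times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(y, each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(z, each = shape[1] * shape[2]), dim = shape)

  inEllipsoid <- function(center, radii) {
    ((X - center[1]) / radii[1])^2 + ((Y - center[2]) / radii[2])^2 +
      ((Z - center[3]) / radii[3])^2 <= 1
  }
  tumor <- inEllipsoid(tumorCenter, tumorRadii)
  core <- inEllipsoid(tumorCenter, tumorRadii - rimThickness)
  core <- core & tumor
  rim <- tumor & !core

  if (is.null(liverBox)) {
    gapx <- min(2, 4 * spacing[1])
    liverBox <- list(
      min = c(min(extent[1], tumorCenter[1] + tumorRadii[1] + gapx),
              tumorCenter[2] - tumorRadii[2] / 2,
              tumorCenter[3] - tumorRadii[3] / 2),
      max = c(extent[1], tumorCenter[2] + tumorRadii[2] / 2,
              tumorCenter[3] + tumorRadii[3] / 2))
  }
  liver <- X >= liverBox$min[1] & X <= liverBox$max[1] &
    Y >= liverBox$min[2] & Y <= liverBox$max[2] &
    Z >= liverBox$min[3] & Z <= liverBox$max[3] & !tumor

  if (is.null(aortaCylinder)) {
    aortaCylinder <- list(
      center = c(max(0, tumorCenter[1] - tumorRadii[1] - min(2, 4 * spacing[1]) -
                       2 * spacing[1]),
                 tumorCenter[2]),
      radius = max(1.1 * spacing[1], 1.1 * spacing[2], 1),
      zRange = c(0, extent[3]))
  }
  if (any(aortaCylinder$center - aortaCylinder$radius < 0) ||
      aortaCylinder$center[1] + aortaCylinder$radius > extent[1] ||
      aortaCylinder$center[2] + aortaCylinder$radius > extent[2])
    stop("geometry error: aorta cylinder does not fit inside the grid")
  aorta <- (X - aortaCylinder$center[1])^2 + (Y - aortaCylinder$center[2])^2 <=
    aortaCylinder$radius^2
  aorta <- aorta & Z >= aortaCylinder$zRange[1] & Z <= aortaCylinder$zRange[2] &
    !tumor & !liver

  labels <- array(0L, dim = shape)
  labels[rim] <- 1L
  labels[core] <- 2L
  labels[liver] <- 3L
  labels[aorta] <- 4L

  counts <- c(tumor = sum(tumor), viable_rim = sum(rim),
              necrotic_core = sum(core), liver = sum(liver),
              aorta = sum(aorta))
  small <- counts[counts < 10L]
  if (length(small))
    stop("geometry error: region(s) below the 10-voxel ROI floor: ",
         paste(sprintf("%s (%d)", names(small), small), collapse = ", "))

  m <- roiMaskSet(labels, spacing = spacing)
  attr(m, "voxelCounts") <- counts
  m
}

#' Build ground-truth maps from region-wise values
#'
#' Paints per-region true parameter values onto the phantom grid. The
#' defaults are generic soft-tissue/tumor literature ranges (viable tumor:
#' low ADC, high Ktrans and flow; necrosis: high ADC, near-zero transfer
#' and flow), not claims about any particular animal. The blood-volume map
#' is derived as flow x MTT so the truth itself satisfies the central
#' volume theorem.
#'
#' @param masks \linkS4class{RoiMaskSet} from \code{\link{makeGeometry}}.
#' @param values named list of per-region value lists; regions
#'   \code{viable_rim}, \code{necrotic_core}, \code{liver}, \code{aorta},
#'   each holding \code{adc} (mm^2/s), \code{s0} (a.u.), \code{ktrans}
#'   (1/min), \code{ve} (fraction), \code{flow} (a.u.), \code{mtt} (s).
#' @param aif DCE arterial input model (\linkS4class{AifModel}).
#' @param dscAif DSC arterial input model; defaults to the gamma-variate
#'   first-pass bolus of \code{\link{gammaVariateAif}}.
#' @param noiseSigma Rician noise scale (a.u.).
#' @param seed simulation seed.
#' @return A \linkS4class{PhantomTruth}.
#' @export
makePhantomTruth <- function(masks,
                             values = defaultTruthValues(),
                             aif = aifModel(),
                             dscAif = gammaVariateAif(),
                             noiseSigma = 0,
                             seed = 1L) {
  shape <- dim(maskLabels(masks))
  zero <- array(0, dim = shape)
  adc <- s0 <- kt <- ve <- fl <- mtt <- zero
  for (region in names(values)) {
    sel <- regionMask(masks, region)
    v <- values[[region]]
    adc[sel] <- v$adc; s0[sel] <- v$s0; kt[sel] <- v$ktrans
    ve[sel] <- v$ve; fl[sel] <- v$flow; mtt[sel] <- v$mtt
  }
  new("PhantomTruth", adcMap = adc, s0Map = s0, ktransMap = kt, veMap = ve,
      flowMap = fl, bvMap = fl * mtt, mttMap = mtt,
      aif = aif, dscAif = dscAif,
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' @rdname makePhantomTruth
#' @export
defaultTruthValues <- function() {
  list(
    viable_rim    = list(adc = 0.9e-3, s0 = 1000, ktrans = 0.25, ve = 0.35,
                         flow = 1.5, mtt = 4),
    necrotic_core = list(adc = 2.2e-3, s0 = 1000, ktrans = 0.02, ve = 0.6,
                         flow = 0.05, mtt = 8),
    liver         = list(adc = 1.0e-3, s0 = 1000, ktrans = 0.10, ve = 0.20,
                         flow = 1.0, mtt = 6),
    aorta         = list(adc = 3.0e-3, s0 = 1000, ktrans = 0, ve = 1,
                         flow = 0, mtt = 0))
}
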