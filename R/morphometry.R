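#' @include AllClasses.R AllGenerics.R utils.R
NULL

.voxelVolume <- function(masks, meta = NULL) {
  if (is.null(meta)) prod(maskSpacing(masks))
  else prod(meta@inPlaneSpacing) * (meta@sliceThickness + meta@sliceGap)
}

#' Region volume from a label mask
#'
#' Voxel count times in-plane area times slice pitch. The per-slice extent
#' is thickness + gap: tissue in the inter-slice gap is attributed to the
#' nearer slice, the convention under which 2 mm slices with a 0.2 mm gap
#' contribute 2.2 mm each to through-plane extent.
#'
#' @param masks \linkS4class{RoiMaskSet}.
#' @param region region role.
#' @param meta optional \linkS4class{AcquisitionMeta}; by default the
#'   mask's own spacing (whose third component is the slice pitch) is used.
#' @return volume in mm^3.
#' @export
regionVolume <- function(masks, region, meta = NULL) {
  n <- regionVoxelCount(masks, region)
  if (n == 0L)
    stop(sprintf("region '%s' is empty", region))
  n * .voxelVolume(masks, meta)
}

#' Total tumor volume
#'
#' Volume of the full tumor (viable rim plus necrotic core) by voxel
#' counting over all slices; see \code{\link{regionVolume}} for the slice
#' pitch convention.
#'
#' @inheritParams regionVolume
#' @return tumor volume in mm^3.
#' @export
tumorVolume <- function(masks, meta = NULL) regionVolume(masks, "tumor", meta)

#' Tumor volume change
#'
#' Percent change of tumor volume from the pre-treatment scan; delegates
#' to \code{\link{percentChange}}.
#'
#' @param preVolume,postVolume tumor volumes, mm^3.
#' @return percent change.
#' @export
volumeChangePercent <- function(preVolume, postVolume)
  percentChange(preVolume, postVolume)

# per-slice voxel center coordinates (mm) of a region
.sliceCoords <- function(sel, spacing) {
  idx <- which(sel, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  data.frame(x = (idx[, 1] - 1) * spacing[1],
             y = (idx[, 2] - 1) * spacing[2],
             z = idx[, 3])
}

.maxPairDist <- function(xy) {
  if (nrow(xy) == 1L) return(0)
  h <- unique(grDevices::chull(xy))
  p <- xy[h, , drop = FALSE]
  d <- as.matrix(stats::dist(p))
  max(d)
}

#' Maximum in-plane diameter of a region
#'
#' Caliper-style measurement: the maximum pairwise distance between region
#' voxels within any single slice, maximized over slices. The edge-to-edge
#' convention is used — one in-plane voxel extent (the larger in-plane
#' spacing) is added to the center-to-center distance, so a single voxel
#' reports its own extent.
#'
#' @param masks \linkS4class{RoiMaskSet}.
#' @param region region role.
#' @param convention "edge_to_edge" (default) or "center_to_center".
#' @return diameter in mm.
#' @export
maxInPlaneDiameter <- function(masks, region,
                               convention = c("edge_to_edge",
                                              "center_to_center")) {
  convention <- match.arg(convention)
  sel <- regionMask(masks, region)
  if (!any(sel)) stop(sprintf("region '%s' is empty", region))
  sp <- maskSpacing(masks)
  co <- .sliceCoords(sel, sp)
  best <- 0
  for (z in unique(co$z)) {
    xy <- as.matrix(co[co$z == z, c("x", "y")])
    best <- max(best, .maxPairDist(xy))
  }
  if (identical(convention, "edge_to_edge")) best + max(sp[1:2]) else best
}

# Maximal in-plane radial thickness of the viable rim, measured on the
# slice(s) where the tumor reaches its maximal in-plane diameter — the
# caliper-style reference slice. Off-center slices are excluded on
# purpose: an oblique cut through a shell exaggerates its apparent
# in-plane width without bound, so the reference-slice measurement is the
# one that reflects the true shell thickness. For each rim voxel on the
# reference slice, the distance to the nearest non-tumor voxel center
# plus the distance to the nearest necrotic-core voxel center
# approximates the local radial width; one in-plane voxel extent of
# center-to-center overshoot is subtracted.
.maxRimThickness <- function(masks) {
  sp <- maskSpacing(masks)
  rim <- regionMask(masks, "viable_rim")
  core <- regionMask(masks, "necrotic_core")
  tumor <- rim | core
  if (!any(rim)) return(0)

  # per-slice tumor diameters; reference slices tie within half a voxel
  co <- .sliceCoords(tumor, sp)
  diam <- vapply(sort(unique(co$z)), function(z)
    .maxPairDist(as.matrix(co[co$z == z, c("x", "y")])), numeric(1))
  zs <- sort(unique(co$z))
  ref <- zs[diam >= max(diam) - max(sp[1:2]) / 2]

  d2min <- function(a, b) {
    # nearest-neighbor distances a -> b, in mm, chunked
    n <- nrow(a)
    out <- numeric(n)
    step <- max(1L, 200000L %/% max(1L, nrow(b)))
    for (s in seq(1L, n, by = step)) {
      e <- min(n, s + step - 1L)
      dx <- outer(a[s:e, 1], b[, 1], "-")
      dy <- outer(a[s:e, 2], b[, 2], "-")
      out[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
    }
    out
  }
  best <- 0
  for (z in ref) {
    rimX <- which(rim[, , z], arr.ind = TRUE)
    coreX <- which(core[, , z], arr.ind = TRUE)
    if (!nrow(rimX) || !nrow(coreX)) next
    outX <- which(!tumor[, , z], arr.ind = TRUE)
    if (!nrow(outX)) next
    mm <- function(m) cbind((m[, 1] - 1) * sp[1], (m[, 2] - 1) * sp[2])
    th <- d2min(mm(rimX), mm(outX)) + d2min(mm(rimX), mm(coreX)) -
      max(sp[1:2])
    best <- max(best, th)
  }
  max(best, 0)
}

#' Relative viable rim
#'
#' 100 x (maximum rim diameter) / (maximum tumor diameter), the viable-rim
#' response index. "Maximum rim diameter" is operationalized as the
#' maximal in-plane radial thickness of the viable rim (outer tumor
#' boundary to necrosis boundary along the widest direction), which is
#' what keeps the index below 100 for an annular rim; the Feret diameter
#' of the rim region would degenerately equal the tumor diameter. In the
#' no-necrosis limit (rim fills the tumor) the index is 100 by
#' convention; an empty rim gives 0.
#'
#' @param masks \linkS4class{RoiMaskSet} with rim, core and tumor regions.
#' @return percent in [0, 100].
#' @export
relativeViableRim <- function(masks) {
  lg <- maskLegend(masks)
  if (!all(c("viable_rim", "necrotic_core") %in% names(lg)))
    stop("mask legend must define viable_rim and necrotic_core")
  nRim <- regionVoxelCount(masks, "viable_rim")
  nCore <- regionVoxelCount(masks, "necrotic_core")
  if (nRim == 0L) return(0)
  if (nCore == 0L) return(100)
  th <- .maxRimThickness(masks)
  dTumor <- maxInPlaneDiameter(masks, "tumor")
  min(100, 100 * th / dTumor)
}

#' Relative necrosis volume
#'
#' 100 x necrotic-core volume / total tumor volume; the voxel-volume
#' factor cancels, so this is a pure count ratio.
#'
#' @param masks \linkS4class{RoiMaskSet}.
#' @param meta unused for the ratio; accepted for interface symmetry.
#' @return percent in [0, 100].
#' @export
relativeNecrosisVolume <- function(masks, meta = NULL) {
  nTumor <- regionVoxelCount(masks, "tumor")
  if (nTumor == 0L) stop("tumor region is empty")
  nCore <- if ("necrotic_core" %in% names(maskLegend(masks)))
    regionVoxelCount(masks, "necrotic_core") else 0L
  100 * nCore / nTumor
}

#' All morphometric endpoints of one mask set
#'
#' @param masks \linkS4class{RoiMaskSet}.
#' @param meta optional \linkS4class{AcquisitionMeta} for the volume.
#' @return one-row data.frame: tumor_volume (mm^3), max_tumor_diameter
#'   (mm), rim_percent, necrosis_percent.
#' @export
morphometryRecord <- function(masks, meta = NULL) {
  data.frame(
    tumor_volume = tumorVolume(masks, meta),
    max_tumor_diameter = maxInPlaneDiameter(masks, "tumor"),
    rim_percent = relativeViableRim(masks),
    necrosis_percent = relativeNecrosisVolume(masks))
}
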