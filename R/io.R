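#' @include AllClasses.R AllGenerics.R
NULL

.sidecarFromMeta <- function(meta, seriesKind) {
  list(series_kind = seriesKind,
       b_values = meta@bValues,
       dce_frame_duration_s = meta@dceFrameDuration,
       dsc_frame_duration_s = meta@dscFrameDuration,
       n_frames = meta@nFrames,
       baseline_frames = meta@baselineFrames,
       echo_time_ms = meta@echoTime,
       slice_thickness_mm = meta@sliceThickness,
       slice_gap_mm = meta@sliceGap,
       in_plane_spacing_mm = meta@inPlaneSpacing)
}

.metaFromSidecar <- function(sc) {
  acquisitionMeta(
    bValues = sc$b_values,
    dceFrameDuration = sc$dce_frame_duration_s,
    dscFrameDuration = sc$dsc_frame_duration_s,
    nFrames = sc$n_frames,
    baselineFrames = sc$baseline_frames,
    echoTime = sc$echo_time_ms,
    sliceThickness = sc$slice_thickness_mm,
    sliceGap = sc$slice_gap_mm,
    inPlaneSpacing = sc$in_plane_spacing_mm)
}

#' Read an acquisition sidecar
#'
#' JSON (.json) or YAML (.yaml/.yml) sidecar carrying the acquisition
#' metadata and the series kind.
#'
#' @param path sidecar file path.
#' @return list with elements \code{meta} (\linkS4class{AcquisitionMeta})
#'   and \code{seriesKind}.
#' @export
readSidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar not found: ", path)
  sc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  list(meta = .metaFromSidecar(sc), seriesKind = sc$series_kind)
}

#' Write an acquisition sidecar
#'
#' @param meta \linkS4class{AcquisitionMeta}.
#' @param seriesKind "dwi", "dce" or "dsc".
#' @param path output path (.json or .yaml).
#' @return \code{path}, invisibly.
#' @export
writeSidecar <- function(meta, seriesKind, path) {
  sc <- .sidecarFromMeta(meta, seriesKind)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(sc, path)
  else jsonlite::write_json(sc, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Read a 4D series with its sidecar
#'
#' Reads a 4D NIfTI-1 volume and its acquisition sidecar, validating that
#' the series axis length matches the metadata (b-value count for DWI,
#' frame count for DCE/DSC) and that the signal is nonnegative and finite.
#' Axis convention: spatial (x, y, z) first, series axis last.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param sidecar sidecar path (JSON/YAML).
#' @return An \linkS4class{ImageSeries4D}.
#' @export
readSeries <- function(path, sidecar) {
  sc <- readSidecar(sidecar)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4D NIfTI volume, got %d dimensions", length(d)))
  expected <- if (identical(sc$seriesKind, "dwi"))
    length(sc$meta@bValues) else sc$meta@nFrames
  if (d[4] != expected)
    stop(sprintf(
      "series axis has %d volumes but the sidecar specifies %d (%s)",
      d[4], expected, sc$seriesKind))
  dat <- array(as.numeric(img), dim = d)
  if (any(!is.finite(dat))) stop("signal contains non-finite values")
  if (any(dat < 0)) stop("signal contains negative values")
  imageSeries4D(dat, sc$meta, sc$seriesKind,
                affine = structure(RNifti::xform(img), dim = c(4L, 4L)))
}

#' Write a 4D series and its sidecar
#'
#' @param series \linkS4class{ImageSeries4D}.
#' @param path output NIfTI path.
#' @param sidecar output sidecar path; defaults to \code{path} with a
#'   .json extension.
#' @return \code{path}, invisibly.
#' @export
writeSeries <- function(series, path,
                        sidecar = sub("\\.nii(\\.gz)?$", ".json", path)) {
  sp <- c(acqMeta(series)@inPlaneSpacing,
          acqMeta(series)@sliceThickness + acqMeta(series)@sliceGap)
  img <- RNifti::asNifti(seriesData(series), pixdim = c(sp, 1))
  RNifti::writeNifti(img, path)
  writeSidecar(acqMeta(series), seriesKind(series), sidecar)
  invisible(path)
}

#' Read / write a label mask volume
#'
#' The legend travels in a JSON sidecar next to the NIfTI label volume.
#'
#' @param path NIfTI label volume.
#' @param sidecar legend sidecar (JSON); defaults to \code{path} with a
#'   .labels.json extension.
#' @return \code{readMaskSet}: a \linkS4class{RoiMaskSet}.
#' @export
readMaskSet <- function(path, sidecar = sub("\\.nii(\\.gz)?$", ".labels.json", path)) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("label volume must be 3D")
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  roiMaskSet(array(as.integer(img), dim = dim(img)),
             legend = unlist(sc$legend), spacing = sc$spacing_mm)
}

#' @rdname readMaskSet
#' @param masks \linkS4class{RoiMaskSet} to write.
#' @export
writeMaskSet <- function(masks, path,
                         sidecar = sub("\\.nii(\\.gz)?$", ".labels.json", path)) {
  img <- RNifti::asNifti(maskLabels(masks), pixdim = maskSpacing(masks))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(legend = as.list(maskLegend(masks)),
                            spacing_mm = maskSpacing(masks)),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.recordColumns <- c("subject_id", "group", "timepoint", "tumor_volume",
                    "radc", "ktrans", "ve", "rbv", "rbf",
                    "rim_percent", "necrosis_percent")
.recordUnits <- c("", "", "", "mm^3", "dimensionless", "1/min", "fraction",
                  "a.u.", "a.u.", "%", "%")

#' Validate a subject-timepoint record table
#'
#' Checks column presence, (subject, timepoint) uniqueness, and the
#' physical ranges: volume > 0, ve in [0, 1], percentages in [0, 100].
#'
#' @param records data.frame of per-subject per-timepoint summaries.
#' @return \code{records}, invisibly, with columns in canonical order.
#' @export
validateRecords <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  missing <- setdiff(.recordColumns, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  key <- paste(records$subject_id, records$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (subject, timepoint) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (any(records$tumor_volume <= 0, na.rm = TRUE))
    stop("tumor_volume must be positive")
  if (any(records$ve < 0 | records$ve > 1, na.rm = TRUE))
    stop("ve must lie in [0, 1]")
  for (p in c("rim_percent", "necrosis_percent"))
    if (any(records[[p]] < 0 | records[[p]] > 100, na.rm = TRUE))
      stop(p, " must lie in [0, 100]")
  invisible(records[, .recordColumns])
}

#' Write / read subject-timepoint record tables
#'
#' CSV with one row per record, fixed column order, and the units recorded
#' in a leading comment line. \code{readRecords(writeRecords(x))} returns
#' the input within float representation.
#'
#' @param records data.frame (see \code{\link{validateRecords}}).
#' @param path CSV path.
#' @return \code{writeRecords}: \code{path} invisibly;
#'   \code{readRecords}: the record data.frame.
#' @export
writeRecords <- function(records, path) {
  records <- validateRecords(records)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ",
                    paste(sprintf("%s[%s]", .recordColumns, .recordUnits),
                          collapse = " ")), con)
  utils::write.csv(format(records, digits = 12, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRecords
#' @export
readRecords <- function(path) {
  rec <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  num <- setdiff(.recordColumns, c("subject_id", "group", "timepoint"))
  for (nm in num) rec[[nm]] <- as.numeric(rec[[nm]])
  validateRecords(rec)
  rec
}
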