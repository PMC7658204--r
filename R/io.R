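#' Read and write CT volumes and label maps as NIfTI-1
#'
#' Volumes and label maps are stored as NIfTI-1 with 32-bit floating point
#' data and the voxel spacing in the header. On read, files with a defined
#' orientation are reoriented to the canonical in-memory convention
#' (x = left, y = posterior, z = superior: LPS); on write, that orientation
#' is recorded in the qform. Label files are validated against the organ
#' coding: every voxel must be within 1e-3 of an integer in 0..6.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [ct_volume()]; `read_labels()` a
#'   [label_map()].
#' @name ctorg_io
NULL

canonical_read <- function(path) {
  img <- RNifti::readNifti(path)
  # reorient when the header defines an orientation; suppress the warning
  # RNifti emits for orientation-less files (e.g. minimal headers)
  withCallingHandlers(
    RNifti::orientation(img) <- "LPS",
    warning = function(w) invokeRestart("muffleWarning"))
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s' is not a 3D volume", path), call. = FALSE)
  list(arr = array(as.numeric(arr), dim(arr)), spacing = abs(sp))
}

canonical_write <- function(arr, spacing, path) {
  img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
  RNifti::pixdim(img) <- spacing
  # LPS storage: index axes map to (-x, -y, +z) of the RAS world frame
  m <- diag(c(-spacing[1], -spacing[2], spacing[3], 1))
  RNifti::qform(img) <- structure(m, code = 1L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname ctorg_io
#' @export
read_volume <- function(path) {
  x <- canonical_read(path)
  ct_volume(x$arr, x$spacing)
}

#' @rdname ctorg_io
#' @export
read_labels <- function(path) {
  x <- canonical_read(path)
  r <- round(x$arr)
  if (max(abs(x$arr - r)) > 1e-3)
    stop(errorCondition(
      sprintf("'%s' contains non-integer label values", path),
      class = c("ctmorphseg_format_error", "ctmorphseg_error")))
  if (any(r < 0) || any(r > 6))
    stop(errorCondition(
      sprintf("'%s' contains label codes outside 0..6", path),
      class = c("ctmorphseg_format_error", "ctmorphseg_error")))
  label_map(r, x$spacing)
}

#' @rdname ctorg_io
#' @param ct A [ct_volume()] to write.
#' @export
write_volume <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  canonical_write(ct$hu, ct$spacing, path)
}

#' @rdname ctorg_io
#' @param map A [label_map()] to write (codes stored as floats).
#' @export
write_labels <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  canonical_write(map$codes, map$spacing, path)
}

#' Canonical dataset file names
#'
#' The volume/label naming convention: case number n is stored as
#' `volume-n.nii.gz` with segmentation `labels-n.nii.gz`.
#'
#' @param case_number Non-negative integer case number.
#' @param dir Optional directory to prefix.
#' @return Named character vector `c(volume = , labels = )`.
#' @examples
#' pair_paths(0)
#' @export
pair_paths <- function(case_number, dir = NULL) {
  n <- as.integer(case_number)
  if (length(n) != 1L || is.na(n) || n < 0L)
    stop("`case_number` must be a non-negative integer", call. = FALSE)
  p <- c(volume = sprintf("volume-%d.nii.gz", n),
         labels = sprintf("labels-%d.nii.gz", n))
  if (!is.null(dir)) p[] <- file.path(dir, p)
  p
}
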