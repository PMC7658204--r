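#' Binary voxel mask
#'
#' A 3D logical grid aligned to a CT volume, with per-axis voxel spacing in
#' millimetres. All morphological operations in the package consume and
#' produce this type.
#'
#' @param grid A 3D `logical` array (numeric input is coerced with `!= 0`).
#' @param spacing Numeric length-3 vector of positive voxel sizes in mm
#'   (x, y, z).
#' @return An object of class `binary_mask`: a list with elements `grid`
#'   and `spacing`.
#' @examples
#' m <- binary_mask(array(FALSE, c(8, 8, 8)), spacing = c(1, 1, 2))
#' m
#' @export
binary_mask <- function(grid, spacing = c(1, 1, 1)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  if (!is.logical(grid)) {
    grid <- array(as.vector(grid) != 0, dim(grid))
  }
  if (anyNA(grid)) stop("`grid` must not contain NA", call. = FALSE)
  spacing <- check_spacing(spacing)
  structure(list(grid = grid, spacing = spacing), class = "binary_mask")
}

#' CT volume in Hounsfield units
#'
#' A 3D scalar grid of Hounsfield units (HU) with per-axis voxel spacing in
#' mm. The canonical in-memory orientation is x = left/right,
#' y = anterior/posterior (exam table towards +y for a supine patient),
#' z = inferior/superior.
#'
#' @param hu A 3D numeric array of finite Hounsfield values.
#' @param spacing Numeric length-3 vector of positive voxel sizes in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(hu, spacing = c(1, 1, 1)) {
  if (!is.array(hu) || length(dim(hu)) != 3L)
    stop("`hu` must be a 3D array", call. = FALSE)
  hu <- array(as.numeric(hu), dim(hu))
  if (!all(is.finite(hu))) stop("`hu` must be finite", call. = FALSE)
  spacing <- check_spacing(spacing)
  structure(list(hu = hu, spacing = spacing), class = "ct_volume")
}

#' Multi-organ label map
#'
#' A 3D integer grid using the standard organ coding: 0 background, 1 liver,
#' 2 bladder, 3 lungs, 4 kidneys, 5 bone, 6 brain.
#'
#' @param codes A 3D array of integer codes in 0..6.
#' @param spacing Numeric length-3 vector of positive voxel sizes in mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(codes, spacing = c(1, 1, 1)) {
  if (!is.array(codes) || length(dim(codes)) != 3L)
    stop("`codes` must be a 3D array", call. = FALSE)
  codes <- array(as.integer(round(as.numeric(codes))), dim(codes))
  if (anyNA(codes) || any(codes < 0L) || any(codes > 6L))
    stop("label codes must be integers in 0..6", call. = FALSE)
  spacing <- check_spacing(spacing)
  structure(list(codes = codes, spacing = spacing), class = "label_map")
}

#' Organ label codes
#'
#' Named integer vector mapping organ class names to their label codes.
#'
#' @return A named integer vector.
#' @export
organ_codes <- function() {
  c(background = 0L, liver = 1L, bladder = 2L, lungs = 3L,
    kidneys = 4L, bone = 5L, brain = 6L)
}

#' Structuring element
#'
#' A small binary kernel with odd extent along every axis so that its origin
#' is the exact centre voxel. Even-sized requests are promoted upward by the
#' constructors ([make_sphere_se()], [make_prism_se()]).
#'
#' @param grid A 3D logical array with odd size along every axis and at
#'   least one voxel set.
#' @return An object of class `struct_el` with elements `grid` and `origin`
#'   (the 1-based centre index).
#' @export
struct_el <- function(grid) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("structuring element must be a 3D array", call. = FALSE)
  if (!is.logical(grid)) grid <- array(as.vector(grid) != 0, dim(grid))
  d <- dim(grid)
  if (any(d %% 2L == 0L))
    stop("structuring element must have odd extent along every axis", call. = FALSE)
  if (!any(grid)) stop("structuring element must have at least one voxel set", call. = FALSE)
  structure(list(grid = grid, origin = (d + 1L) %/% 2L), class = "struct_el")
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  spacing
}

# shared shape/spacing compatibility check
check_same_geometry <- function(a, b, what = "objects") {
  ga <- if (!is.null(a$grid)) a$grid else if (!is.null(a$hu)) a$hu else a$codes
  gb <- if (!is.null(b$grid)) b$grid else if (!is.null(b$hu)) b$hu else b$codes
  if (!identical(dim(ga), dim(gb)))
    stop(sprintf("%s must have identical shapes", what), call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop(sprintf("%s must have identical spacings", what), call. = FALSE)
  invisible(TRUE)
}

#' Complement of a binary mask
#'
#' @param mask A [binary_mask()].
#' @return A `binary_mask` with every voxel flipped.
#' @export
mask_complement <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  binary_mask(!mask$grid, mask$spacing)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, spacing %s mm, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], paste(format(x$spacing, trim = TRUE), collapse = " x "),
              sum(x$grid), 100 * mean(x$grid)))
  invisible(x)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], paste(format(x$spacing, trim = TRUE), collapse = " x "),
              min(x$hu), max(x$hu)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$codes)
  tab <- table(factor(x$codes, levels = 0:6))
  present <- tab[tab > 0]
  nm <- names(organ_codes())[as.integer(names(present)) + 1L]
  cat(sprintf("<label_map> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing, trim = TRUE), collapse = " x ")))
  cat("  classes:", paste(sprintf("%s(%s)=%d", nm, names(present), as.integer(present)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.struct_el <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<struct_el> %d x %d x %d, %d voxels set\n", d[1], d[2], d[3], sum(x$grid)))
  invisible(x)
}
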