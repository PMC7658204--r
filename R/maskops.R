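#' Connected-component labeling
#'
#' Labels the foreground of a mask into connected components under the given
#' 3D neighbourhood. Component ids are deterministic: components are sorted
#' by voxel count descending, ties broken by the smallest linear voxel index
#' contained.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 6 (face neighbours), 18 (faces + edges) or 26 (full
#'   neighbourhood, the default; diagonal contact counts).
#' @return An object of class `component_labeling`: list with `labels` (3D
#'   integer array, 0 = background) and `sizes` (voxel count per component,
#'   ordered by id).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  d <- dim(mask$grid)
  raw <- ccl3d_cpp(as.vector(mask$grid), d, connectivity)
  ncomp <- max(raw, 0L)
  if (ncomp == 0L) {
    return(structure(list(labels = array(0L, d), sizes = integer(0),
                          spacing = mask$spacing),
                     class = "component_labeling"))
  }
  sizes <- tabulate(raw, nbins = ncomp)
  # raw ids are assigned in order of first linear index, so raw id order IS
  # the tie-break order; sort by size descending, then raw id.
  ord <- order(-sizes, seq_len(ncomp))
  remap <- integer(ncomp)
  remap[ord] <- seq_len(ncomp)
  labels <- array(ifelse(raw > 0L, remap[pmax(raw, 1L)], 0L), d)
  structure(list(labels = labels, sizes = sizes[ord], spacing = mask$spacing),
            class = "component_labeling")
}

#' @export
print.component_labeling <- function(x, ...) {
  cat(sprintf("<component_labeling> %d components, sizes: %s\n",
              length(x$sizes),
              paste(utils::head(x$sizes, 10), collapse = ", ")))
  invisible(x)
}

#' Keep the k largest connected components
#'
#' @inheritParams label_components
#' @param k Positive number of components to keep.
#' @return A `binary_mask` that is the union of the k largest components
#'   (ties broken by smallest linear voxel index).
#' @section Errors: If the mask has fewer than `k` components, an error of
#'   class `ctmorphseg_too_few_components` is signalled; its `n_found` field
#'   carries the number of components present.
#' @export
largest_components <- function(mask, k, connectivity = 26L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("`k` must be a positive integer", call. = FALSE)
  cl <- label_components(mask, connectivity)
  n <- length(cl$sizes)
  if (n < k) {
    stop(errorCondition(
      sprintf("mask has %d connected component(s), need %d", n, k),
      class = c("ctmorphseg_too_few_components", "ctmorphseg_error"),
      n_found = n))
  }
  binary_mask(cl$labels >= 1L & cl$labels <= k, mask$spacing)
}

#' Remove components touching the axial in-plane border
#'
#' Deletes every 3D connected component that has at least one voxel on the
#' in-plane (x or y) border of any z-slice. Components touching only the
#' first/last z-slice are kept — so exterior air and a punctured exam-table
#' cavity are removed while lungs whose airway exits through the top slice
#' survive.
#'
#' @inheritParams label_components
#' @return A `binary_mask`.
#' @export
remove_boundary_connected <- function(mask, connectivity = 26L) {
  cl <- label_components(mask, connectivity)
  if (length(cl$sizes) == 0L) return(mask)
  d <- dim(mask$grid)
  border <- array(FALSE, d)
  border[c(1L, d[1]), , ] <- TRUE
  border[, c(1L, d[2]), ] <- TRUE
  bad <- unique(cl$labels[border & cl$labels > 0L])
  keep <- cl$labels > 0L & !(cl$labels %in% bad)
  binary_mask(array(keep, d), mask$spacing)
}

#' Per-slice axial hole filling
#'
#' For every z-slice independently, fills 2D background regions
#' (4-connectivity) that do not touch the slice's in-plane border. This is
#' how the bone algorithm fills the marrow centres of large bones.
#'
#' @param mask A [binary_mask()].
#' @return A `binary_mask`; the operation is extensive and idempotent.
#' @export
fill_holes_axial <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$grid)
  g <- mask$grid
  for (z in seq_len(d[3])) {
    sl <- g[, , z]
    bg <- !sl
    if (!any(bg)) next
    # 6-connectivity on a 1-thick volume is in-plane 4-connectivity
    lab <- array(ccl3d_cpp(as.vector(bg), c(d[1], d[2], 1L), 6L), c(d[1], d[2]))
    border_ids <- unique(c(lab[c(1L, d[1]), ], lab[, c(1L, d[2])]))
    border_ids <- border_ids[border_ids > 0L]
    hole <- lab > 0L & !(lab %in% border_ids)
    if (any(hole)) g[, , z] <- sl | hole
  }
  binary_mask(g, mask$spacing)
}

#' Morphological reconstruction from seeds
#'
#' Returns the union of exactly those connected components of `reference`
#' that intersect `seeds` (seeds are first intersected with the reference).
#' Equivalent to iterating geodesic dilation of the seeds inside the
#' reference to a fixpoint; used to undo the shrinking effect of erosion.
#'
#' @param reference A [binary_mask()] whose components are candidates.
#' @param seeds A [binary_mask()] of markers (same geometry).
#' @inheritParams label_components
#' @return A `binary_mask`; a subset of `reference`. Empty seeds give an
#'   empty mask.
#' @export
reconstruct_from_seeds <- function(reference, seeds, connectivity = 26L) {
  stopifnot(inherits(reference, "binary_mask"), inherits(seeds, "binary_mask"))
  check_same_geometry(reference, seeds, "reference and seeds")
  marks <- seeds$grid & reference$grid
  if (!any(marks)) return(binary_mask(array(FALSE, dim(reference$grid)), reference$spacing))
  cl <- label_components(reference, connectivity)
  hit <- unique(cl$labels[marks])
  hit <- hit[hit > 0L]
  binary_mask(array(cl$labels %in% hit, dim(reference$grid)), reference$spacing)
}
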