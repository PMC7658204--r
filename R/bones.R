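#' Parameters for the skeleton segmentation algorithm
#'
#' @param tau1_hu Soft-tissue threshold in HU (default 0): almost all bone
#'   tissue, including marrow, lies above it.
#' @param tau2_hu Cortical threshold in HU (default 200): the hard exterior
#'   of each bone lies above it.
#' @param close_diameter_mm Diameter (mm) of the spherical closing element
#'   that bridges gaps in thin cortical bone (default 25).
#' @return A list of class `bone_params`.
#' @export
bone_params <- function(tau1_hu = 0, tau2_hu = 200, close_diameter_mm = 25) {
  if (!(tau1_hu < tau2_hu)) stop("`tau1_hu` must be below `tau2_hu`", call. = FALSE)
  if (close_diameter_mm <= 0) stop("`close_diameter_mm` must be positive", call. = FALSE)
  structure(list(tau1_hu = tau1_hu, tau2_hu = tau2_hu,
                 close_diameter_mm = close_diameter_mm),
            class = "bone_params")
}

#' Unsupervised morphological skeleton segmentation
#'
#' Segments the skeleton by thresholding and morphology, in five steps:
#' \enumerate{
#'   \item Threshold at `tau2_hu` (strict >), extracting the dense cortical
#'     exteriors of the bones together with other hyper-intense tissue.
#'   \item Keep only the largest connected component — the skeleton. This
#'     discards hyper-intense tissue not connected to it (e.g.
#'     contrast-enhanced organs), and also drops ribs that are disconnected
#'     from the spine in cropped scans — a known, accepted limitation.
#'   \item Close with a spherical element of diameter `close_diameter_mm`,
#'     bridging gaps where cortical bone is too thin to resolve and covering
#'     the marrow interiors.
#'   \item Intersect with `hu > tau1_hu`, removing most of the soft tissue
#'     the closing captured while keeping marrow.
#'   \item Fill, per axial slice, holes not connected to the slice border,
#'     completing the centres of large bones.
#' }
#'
#' @param ct A [ct_volume()].
#' @param params A [bone_params()].
#' @param connectivity 3D neighbourhood for component analysis (default 26).
#' @param backend Morphology back-end passed to [closing()].
#' @param verbose If `TRUE`, log each step's voxel count via `message()`.
#' @return A `binary_mask` of the skeleton with attribute `steps` (voxel
#'   count log).
#' @section Errors: An empty `tau2_hu` threshold mask (no bone-intensity
#'   voxels) is an error.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 1))
#' bones <- segment_bones(ph$ct)
#' dice(bones, label_mask(ph$labels, 5))
#' @export
segment_bones <- function(ct, params = bone_params(), connectivity = 26L,
                          backend = NULL, verbose = FALSE) {
  stopifnot(inherits(ct, "ct_volume"), inherits(params, "bone_params"))
  log <- list()
  note <- function(step, mask) {
    log[[length(log) + 1L]] <<- data.frame(step = step, voxels = sum(mask$grid))
    if (verbose) message(sprintf("[bones] %-28s %d voxels", step, sum(mask$grid)))
    mask
  }

  m <- note("1: threshold cortical",
            binary_mask(ct$hu > params$tau2_hu, ct$spacing))
  if (!any(m$grid))
    stop("no bone-intensity voxels: threshold mask at tau2 is empty", call. = FALSE)

  m <- note("2: largest component", largest_components(m, 1L, connectivity))

  sphere <- make_sphere_se(params$close_diameter_mm, ct$spacing)
  m <- note("3: close with sphere", closing(m, sphere, backend))

  m <- note("4: intersect hu > tau1",
            binary_mask(m$grid & ct$hu > params$tau1_hu, ct$spacing))

  out <- note("5: fill axial holes", fill_holes_axial(m))

  attr(out, "steps") <- do.call(rbind, log)
  out
}
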