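#' Parameters for the lung segmentation algorithm
#'
#' @param tau_hu Air threshold in HU; voxels with `hu <= tau_hu` form the
#'   thresholded air image. Default -150.
#' @param prism_mm Physical length (mm) of the table-puncturing prism along
#'   the anterior-posterior (y) axis. Default 10.
#' @param open_diameter_mm Diameter (mm) of the spherical opening element
#'   that removes the chest wall and small air pockets. Default 10.
#' @param strict If `TRUE` (default), finding fewer than two candidate
#'   components is an error; otherwise the single component is returned and
#'   flagged.
#' @return A list of class `lung_params`.
#' @export
lung_params <- function(tau_hu = -150, prism_mm = 10, open_diameter_mm = 10,
                        strict = TRUE) {
  stopifnot(is.numeric(tau_hu), length(tau_hu) == 1L)
  if (prism_mm <= 0) stop("`prism_mm` must be positive", call. = FALSE)
  if (open_diameter_mm <= 0) stop("`open_diameter_mm` must be positive", call. = FALSE)
  structure(list(tau_hu = tau_hu, prism_mm = prism_mm,
                 open_diameter_mm = open_diameter_mm, strict = isTRUE(strict)),
            class = "lung_params")
}

#' Unsupervised morphological lung segmentation
#'
#' Detects and segments the lungs as the two largest air pockets inside the
#' body, in six steps:
#' \enumerate{
#'   \item Threshold: keep voxels with `hu <= tau_hu` (the air image f_tau).
#'   \item Close f_tau with a 1 x ceil(prism_mm/d) x 1 voxel prism (d = the
#'     y-axis spacing in mm), puncturing the thin wall of the exam table so
#'     its hollow interior joins the exterior air.
#'   \item Remove every component connected to the in-plane border of any
#'     axial slice (exterior air and the punctured table cavity).
#'   \item Open with a spherical element of diameter `open_diameter_mm`,
#'     removing the chest wall and other small air pockets.
#'   \item Keep the two largest connected components — the lungs.
#'   \item Undo the erosion of step 4 by morphological reconstruction:
#'     return the components of f_tau connected to the detected lungs.
#' }
#' The trachea and main bronchi remain attached to the result whenever they
#' are air-connected to the lungs; no separation at the carina is attempted.
#'
#' @param ct A [ct_volume()].
#' @param params A [lung_params()].
#' @param connectivity 3D neighbourhood for component analysis (default 26).
#' @param backend Morphology back-end passed to [closing()]/[opening()].
#' @param verbose If `TRUE`, log each step's voxel count via `message()`.
#' @return A `binary_mask` of the lungs (plus attached airways), with
#'   attributes `steps` (a data.frame log of voxel counts per step) and
#'   `n_candidates` (component count at step 5). When `strict = FALSE` and
#'   only one candidate exists, attribute `single_component` is `TRUE`.
#' @section Errors: With `strict = TRUE`, fewer than two components at step
#'   5 signals an error of class `ctmorphseg_too_few_components` naming the
#'   failing step.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 1))
#' lungs <- segment_lungs(ph$ct)
#' dice(lungs, label_mask(ph$labels, 3))
#' @export
segment_lungs <- function(ct, params = lung_params(), connectivity = 26L,
                          backend = NULL, verbose = FALSE) {
  stopifnot(inherits(ct, "ct_volume"), inherits(params, "lung_params"))
  log <- list()
  note <- function(step, mask) {
    log[[length(log) + 1L]] <<- data.frame(step = step, voxels = sum(mask$grid))
    if (verbose) message(sprintf("[lungs] %-28s %d voxels", step, sum(mask$grid)))
    mask
  }

  f_tau <- note("1: threshold air",
                binary_mask(ct$hu <= params$tau_hu, ct$spacing))

  d_y <- ct$spacing[2]
  prism <- make_prism_se(c(1L, as.integer(ceiling(params$prism_mm / d_y)), 1L))
  m <- note("2: close with prism", closing(f_tau, prism, backend))

  m <- note("3: remove border-connected", remove_boundary_connected(m, connectivity))

  sphere <- make_sphere_se(params$open_diameter_mm, ct$spacing)
  m <- note("4: open with sphere", opening(m, sphere, backend))

  cl <- label_components(m, connectivity)
  n <- length(cl$sizes)
  single <- FALSE
  if (n < 2L) {
    if (params$strict || n == 0L) {
      stop(errorCondition(
        sprintf("lung step 5: found %d candidate component(s), expected 2", n),
        class = c("ctmorphseg_too_few_components", "ctmorphseg_error"),
        n_found = n))
    }
    warning("lung step 5: only one candidate component; returning it",
            call. = FALSE)
    single <- TRUE
  }
  m <- note("5: two largest components",
            binary_mask(cl$labels >= 1L & cl$labels <= min(2L, n), ct$spacing))

  seeds <- binary_mask(m$grid & f_tau$grid, ct$spacing)
  out <- note("6: reconstruct from f_tau",
              reconstruct_from_seeds(f_tau, seeds, connectivity))

  attr(out, "steps") <- do.call(rbind, log)
  attr(out, "n_candidates") <- n
  if (single) attr(out, "single_component") <- TRUE
  out
}
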