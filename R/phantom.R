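#' Synthetic CT phantom specification
#'
#' Parameter bundle for [generate_phantom()]. The phantom is a scaled-down
#' torso rendered at the given shape/spacing: air background, a hollow exam
#' table with a thin dense wall below the body, an elliptic-cylinder
#' soft-tissue body, a skeleton (spine, rib arcs, pelvic wings) with dense
#' cortical shell around low-density marrow, two air-filled lungs joined by
#' bronchi and a trachea exiting through the top slice, soft abdominal blobs
#' and optional hyper-intense decoy blobs mimicking contrast-enhanced
#' organs, plus seeded additive Gaussian noise.
#'
#' All default intensities sit on the correct side of the segmentation
#' thresholds (-150, 0, 200 HU) with a margin; noise is truncated at 40% of
#' the smallest such margin so it can never carry a voxel across a
#' threshold, and quantised to 1/8 HU so volumes survive 32-bit float
#' storage bit-exactly.
#'
#' @param shape Integer voxel triple; the default 96 x 96 x 112 at 2 mm
#'   spacing gives a 192 x 192 x 224 mm field of view.
#' @param spacing Voxel size triple in mm.
#' @param body_hu Soft-tissue intensity (default 40).
#' @param lung_hu Lung air intensity (default -780); must be below -150.
#' @param air_hu Background air intensity (default -1000).
#' @param table List: `wall_hu` (default 100), `wall_thickness_mm` (default
#'   2, must stay below 10 so the lung step-2 prism can puncture it),
#'   `present` flag.
#' @param skeleton List: `cortical_hu` (default 700, above 200),
#'   `marrow_hu` (default 150, between 0 and 200), `shell_thickness_mm`
#'   (default 3).
#' @param decoys List of `list(hu=, radius_mm=)` hyper-intense blobs
#'   disconnected from the skeleton (default: two 8 mm blobs at 250 HU).
#'   Up to four are placed at fixed abdominal sites.
#' @param noise_sigma_hu Gaussian noise standard deviation (default 10).
#' @param seed Integer RNG seed for the noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 112L), spacing = c(2, 2, 2),
                         body_hu = 40, lung_hu = -780, air_hu = -1000,
                         table = list(wall_hu = 100, wall_thickness_mm = 2,
                                      present = TRUE),
                         skeleton = list(cortical_hu = 700, marrow_hu = 150,
                                         shell_thickness_mm = 3),
                         decoys = list(list(hu = 250, radius_mm = 8),
                                       list(hu = 250, radius_mm = 8)),
                         noise_sigma_hu = 10, seed = 1L) {
  shape <- as.integer(shape)
  spacing <- check_spacing(spacing)
  table <- utils::modifyList(list(wall_hu = 100, wall_thickness_mm = 2,
                                  present = TRUE), table)
  skeleton <- utils::modifyList(list(cortical_hu = 700, marrow_hu = 150,
                                     shell_thickness_mm = 3), skeleton)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (!(lung_hu < -150)) stop("`lung_hu` must be below -150", call. = FALSE)
  if (!(air_hu < -150)) stop("`air_hu` must be below -150", call. = FALSE)
  if (!(skeleton$marrow_hu > 0 && skeleton$marrow_hu < 200))
    stop("marrow_hu must lie in (0, 200)", call. = FALSE)
  if (!(skeleton$cortical_hu > 200))
    stop("cortical_hu must exceed 200", call. = FALSE)
  if (!(table$wall_thickness_mm > 0 && table$wall_thickness_mm < 10))
    stop("table wall thickness must lie in (0, 10) mm", call. = FALSE)
  if (noise_sigma_hu < 0) stop("`noise_sigma_hu` must be >= 0", call. = FALSE)
  fov <- shape * spacing
  if (any(fov[1:2] < 176) || fov[3] < 200 || any(fov[1:2] > 320) || fov[3] > 340)
    stop(sprintf(paste0("field of view %.0f x %.0f x %.0f mm cannot hold the ",
                        "built-in anatomy (need 176-320 mm in x/y, 200-340 mm in z)"),
                 fov[1], fov[2], fov[3]), call. = FALSE)
  structure(list(shape = shape, spacing = spacing, body_hu = body_hu,
                 lung_hu = lung_hu, air_hu = air_hu, table = table,
                 skeleton = skeleton, decoys = decoys,
                 noise_sigma_hu = noise_sigma_hu, seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre coordinate grids in mm
phantom_coords <- function(shape, spacing) {
  ax <- lapply(1:3, function(k) (seq_len(shape[k]) - 0.5) * spacing[k])
  list(
    X = array(rep(ax[[1]], times = shape[2] * shape[3]), shape),
    Y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape),
    Z = array(rep(ax[[3]], each = shape[1] * shape[2]), shape)
  )
}

ellipsoid_mask <- function(co, centre, semi) {
  ((co$X - centre[1]) / semi[1])^2 + ((co$Y - centre[2]) / semi[2])^2 +
    ((co$Z - centre[3]) / semi[3])^2 <= 1
}

sphere_mask <- function(co, centre, r) {
  (co$X - centre[1])^2 + (co$Y - centre[2])^2 + (co$Z - centre[3])^2 <= r^2
}

# union of balls of radius r (mm) stamped at points along a path
stamp_tube <- function(mask, pts, r, shape, spacing) {
  for (row in seq_len(nrow(pts))) {
    p <- pts[row, ]
    lo <- pmax(1L, as.integer(floor((p - r) / spacing + 0.5)))
    hi <- pmin(shape, as.integer(ceiling((p + r) / spacing + 0.5)))
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    cx <- (ix - 0.5) * spacing[1] - p[1]
    cy <- (iy - 0.5) * spacing[2] - p[2]
    cz <- (iz - 0.5) * spacing[3] - p[3]
    d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
    mask[ix, iy, iz] <- mask[ix, iy, iz] | (d2 <= r^2)
  }
  mask
}

# All geometric region masks of the phantom; pure function of the spec.
phantom_geometry <- function(spec) {
  shape <- spec$shape; spacing <- spec$spacing
  fov <- shape * spacing
  co <- phantom_coords(shape, spacing)
  cx <- fov[1] / 2
  cyb <- fov[2] / 2 - 8          # body centre, shifted anteriorly
  Lz <- fov[3]
  shell <- spec$skeleton$shell_thickness_mm

  # body: elliptic cylinder spanning all z
  body_semi <- c(80, 56)
  body <- ((co$X - cx) / body_semi[1])^2 + ((co$Y - cyb) / body_semi[2])^2 <= 1

  # exam table: hollow slab posterior to the body, open at both z ends
  w <- spec$table$wall_thickness_mm
  slab <- co$X >= 14 & co$X <= fov[1] - 14 &
          co$Y >= fov[2] - 36 & co$Y <= fov[2] - 8
  interior <- co$X >= 14 + w & co$X <= fov[1] - 14 - w &
              co$Y >= fov[2] - 36 + w & co$Y <= fov[2] - 8 - w
  table_wall <- slab & !interior
  table_interior <- interior

  # spine: vertical tube with cortical shell and marrow core
  cys <- cyb + 32
  r_out <- 12; r_in <- r_out - shell
  R2 <- (co$X - cx)^2 + (co$Y - cys)^2
  zin <- co$Z >= 4 & co$Z <= Lz - 8
  spine_cort <- R2 <= r_out^2 & R2 > r_in^2 & zin
  spine_marrow <- R2 <= r_in^2 & zin

  # pelvic wings: ellipsoid shells attached to the spine
  pelvis_cort <- array(FALSE, shape); pelvis_marrow <- array(FALSE, shape)
  for (s in c(-1, 1)) {
    ctr <- c(cx + s * 34, cyb + 22, 40)
    semi <- c(34, 18, 20)
    outer_m <- ellipsoid_mask(co, ctr, semi)
    inner_m <- ellipsoid_mask(co, ctr, semi - shell)
    pelvis_cort <- pelvis_cort | (outer_m & !inner_m)
    pelvis_marrow <- pelvis_marrow | inner_m
  }

  # ribs: solid cortical arcs sloping inferiorly, attached to the spine
  ribs <- array(FALSE, shape)
  rib_semi <- body_semi - 10
  phi <- seq(0, 110 * pi / 180, length.out = 70)
  for (za in c(110, 150, 190)) {
    for (s in c(-1, 1)) {
      pts <- cbind(cx + s * rib_semi[1] * sin(phi),
                   cyb + rib_semi[2] * cos(phi),
                   za - 30 * phi / max(phi))
      ribs <- stamp_tube(ribs, pts, 4, shape, spacing)
    }
  }

  cortical <- spine_cort | pelvis_cort | ribs
  marrow <- (spine_marrow | pelvis_marrow) & !cortical

  # lungs: two ellipsoids joined by a bronchial bridge and a trachea that
  # exits through the top z slice
  zl <- Lz - 84
  lung_centres <- list(c(cx - 36, cyb - 8, zl), c(cx + 36, cyb - 8, zl))
  lungs <- ellipsoid_mask(co, lung_centres[[1]], c(22, 30, 44)) |
           ellipsoid_mask(co, lung_centres[[2]], c(22, 30, 44))
  yb <- cyb - 8
  bridge <- (co$Y - yb)^2 + (co$Z - (zl + 10))^2 <= 16 &
            co$X >= cx - 36 & co$X <= cx + 36
  trachea <- (co$X - cx)^2 + (co$Y - yb)^2 <= 16 & co$Z >= zl + 10
  airways <- lungs | bridge | trachea

  # soft abdominal blobs (liver-like, bladder-like) and hyper-intense decoys
  liver <- sphere_mask(co, c(cx + 22, cyb - 16, 64), 16)
  bladder <- sphere_mask(co, c(cx, cyb - 12, 24), 12)
  decoy_sites <- list(c(cx - 44, cyb - 28, 72), c(cx + 48, cyb - 30, 76),
                      c(cx - 30, cyb - 34, 100), c(cx + 20, cyb - 42, 100))
  if (length(spec$decoys) > length(decoy_sites))
    stop(sprintf("at most %d decoys are supported", length(decoy_sites)), call. = FALSE)
  decoy_masks <- list()
  for (i in seq_along(spec$decoys)) {
    decoy_masks[[i]] <- sphere_mask(co, decoy_sites[[i]], spec$decoys[[i]]$radius_mm)
  }

  list(body = body, table_wall = table_wall, table_interior = table_interior,
       cortical = cortical, marrow = marrow, ribs = ribs,
       airways = airways, lungs_only = lungs,
       liver = liver, bladder = bladder, decoy_masks = decoy_masks,
       lung_centres = lung_centres, yb = yb, zl = zl, cx = cx, cyb = cyb,
       rib_z = c(110, 150, 190))
}

#' Generate a synthetic CT phantom with ground truth
#'
#' Renders the phantom described by a [phantom_spec()] into a CT volume and
#' a matching ground-truth label map. Rendering overwrites in order: air
#' background, exam table, body, skeleton, airways/lungs, soft blobs,
#' decoys, then truncated Gaussian noise (seeded, so identical specs give
#' bit-identical output). The label map codes the lungs together with their
#' attached airways as 3 and the full skeleton (cortical + marrow) as 5;
#' ancillary structures (table, soft blobs, decoys) are background 0.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `ct_phantom` with elements `ct` ([ct_volume()]),
#'   `labels` ([label_map()]), `regions` (named list of logical region
#'   arrays for bookkeeping in tests) and `spec`. The `ct` element carries
#'   the spec and regions as attributes so [degrade_phantom()] can derive
#'   its variants.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 42))
#' ph$ct
#' ph$labels
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  shape <- spec$shape

  # structural consistency: organs must not collide
  if (any(geo$airways & (geo$cortical | geo$marrow)))
    stop("phantom validation: airways overlap the skeleton", call. = FALSE)
  if (any((geo$table_wall | geo$table_interior) & geo$body))
    stop("phantom validation: exam table overlaps the body", call. = FALSE)
  for (dm in geo$decoy_masks) {
    if (any(dm & (geo$cortical | geo$marrow | geo$airways)))
      stop("phantom validation: a decoy overlaps the skeleton or lungs", call. = FALSE)
    if (any(dm & !geo$body))
      stop("phantom validation: a decoy extends outside the body", call. = FALSE)
  }

  hu <- array(spec$air_hu, shape)
  if (isTRUE(spec$table$present)) {
    hu[geo$table_wall] <- spec$table$wall_hu
    hu[geo$table_interior] <- spec$air_hu
  }
  hu[geo$body] <- spec$body_hu
  hu[geo$cortical] <- spec$skeleton$cortical_hu
  hu[geo$marrow] <- spec$skeleton$marrow_hu
  hu[geo$airways] <- spec$lung_hu
  hu[geo$liver] <- 60
  hu[geo$bladder] <- 35
  for (i in seq_along(geo$decoy_masks)) {
    hu[geo$decoy_masks[[i]]] <- spec$decoys[[i]]$hu
  }

  if (spec$noise_sigma_hu > 0) {
    used_hu <- c(spec$air_hu, spec$lung_hu, spec$body_hu, spec$table$wall_hu,
                 spec$skeleton$marrow_hu, spec$skeleton$cortical_hu, 60, 35,
                 vapply(spec$decoys, `[[`, numeric(1), "hu"))
    margin <- min(abs(outer(used_hu, c(-150, 0, 200), `-`)))
    cap <- 0.4 * margin
    noise <- with_preserved_seed(spec$seed, stats::rnorm(prod(shape), 0, spec$noise_sigma_hu))
    noise <- pmin(pmax(noise, -cap), cap)
    noise <- round(noise * 8) / 8  # dyadic steps survive float32 storage exactly
    hu <- hu + array(noise, shape)
  }

  codes <- array(0L, shape)
  codes[geo$cortical | geo$marrow] <- 5L
  codes[geo$airways] <- 3L

  ct <- ct_volume(hu, spec$spacing)
  labels <- label_map(codes, spec$spacing)
  regions <- list(
    body = geo$body, table_wall = geo$table_wall,
    table_interior = geo$table_interior,
    outside_air = !geo$body & !geo$table_wall & !geo$table_interior,
    skeleton = geo$cortical | geo$marrow, cortical = geo$cortical,
    marrow = geo$marrow, ribs = geo$ribs, airways = geo$airways,
    liver = geo$liver, bladder = geo$bladder, decoys = geo$decoy_masks)
  attr(ct, "phantom_spec") <- spec
  attr(ct, "phantom_regions") <- regions
  structure(list(ct = ct, labels = labels, regions = regions, spec = spec),
            class = "ct_phantom")
}

# run expr with a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat("<ct_phantom>\n")
  print(x$ct)
  print(x$labels)
  invisible(x)
}

#' Adversarial phantom variants
#'
#' Produces degraded versions of a phantom CT volume that reproduce the
#' documented failure modes of the morphological algorithms:
#' \describe{
#'   \item{`crop_abdomen`}{Cuts the scan below the ribs' spinal
#'     attachments, leaving rib fragments disconnected from the spine — the
#'     bone algorithm then drops them at its largest-component step.}
#'   \item{`remove_table`}{Replaces the exam table with air; lung
#'     segmentation must be essentially unchanged (table handling is a
#'     no-op without a table).}
#'   \item{`merge_lungs`}{Carves a wide air channel bridging the two lungs,
#'     so the opening step cannot separate them and the lung algorithm
#'     finds a single candidate component.}
#' }
#'
#' @param ct A [ct_volume()] produced by [generate_phantom()] (it carries
#'   the phantom geometry needed to locate the structures).
#' @param mode One of `"crop_abdomen"`, `"remove_table"`, `"merge_lungs"`.
#' @return A [ct_volume()]; for `crop_abdomen` the attribute `kept_slices`
#'   records the retained z-slice indices so ground truth can be cropped in
#'   parallel.
#' @export
degrade_phantom <- function(ct, mode = c("crop_abdomen", "remove_table", "merge_lungs")) {
  stopifnot(inherits(ct, "ct_volume"))
  mode <- match.arg(mode)
  spec <- attr(ct, "phantom_spec")
  if (is.null(spec))
    stop("`ct` does not carry phantom geometry; generate it with generate_phantom()",
         call. = FALSE)
  geo <- phantom_geometry(spec)
  hu <- ct$hu
  out <- switch(mode,
    crop_abdomen = {
      z_cut <- min(geo$rib_z) - 14  # below the lowest spinal attachment
      keep <- which((seq_len(dim(hu)[3]) - 0.5) * ct$spacing[3] <= z_cut)
      cc <- ct_volume(hu[, , keep, drop = FALSE], ct$spacing)
      attr(cc, "kept_slices") <- keep
      cc
    },
    remove_table = {
      hu[geo$table_wall | geo$table_interior] <- spec$air_hu
      ct_volume(hu, ct$spacing)
    },
    merge_lungs = {
      co <- phantom_coords(spec$shape, spec$spacing)
      chan <- (co$Y - geo$yb)^2 + (co$Z - geo$zl)^2 <= 7^2 &
              co$X >= geo$lung_centres[[1]][1] & co$X <= geo$lung_centres[[2]][1]
      hu[chan] <- spec$lung_hu
      ct_volume(hu, ct$spacing)
    })
  attr(out, "phantom_spec") <- spec
  out
}
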