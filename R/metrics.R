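#' Binarize one class of a label map
#'
#' @param map A [label_map()].
#' @param class_id Integer organ code (0..6).
#' @return A [binary_mask()] of voxels carrying that code.
#' @export
label_mask <- function(map, class_id) {
  stopifnot(inherits(map, "label_map"))
  class_id <- as.integer(class_id)
  binary_mask(map$codes == class_id, map$spacing)
}

#' Dice overlap score
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks score 1 by convention.
#'
#' @param a,b [binary_mask()] objects of identical shape.
#' @return A fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("masks must have identical shapes", call. = FALSE)
  na <- sum(a$grid); nb <- sum(b$grid)
  if (na + nb == 0L) return(1)
  2 * sum(a$grid & b$grid) / (na + nb)
}

# Surface voxels: foreground with at least one face-adjacent background
# neighbour, the volume border counting as background.
mask_surface <- function(grid) {
  d <- dim(grid)
  all_nb_fg <- array(TRUE, d)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      v <- integer(3); v[ax] <- s
      all_nb_fg <- all_nb_fg & shift_logical(grid, v)
    }
  }
  grid & !all_nb_fg
}

#' Symmetric surface distances
#'
#' Extracts each mask's surface (foreground voxels with a face-adjacent
#' background neighbour; the volume border counts as background) and
#' measures voxel-centre-to-voxel-centre Euclidean distances in mm.
#' The mean symmetric surface distance (MSSD) is the mean of all
#' nearest-opposite-surface distances pooled over both directions; the
#' Hausdorff distance is the larger of the two directed maxima.
#'
#' @param a,b Non-empty [binary_mask()] objects with identical shape and
#'   spacing.
#' @return Named numeric vector `c(mssd = , hausdorff = )`, in mm.
#' @export
surface_distances <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_same_geometry(a, b, "masks")
  if (!any(a$grid) || !any(b$grid))
    stop("surface distances are undefined for an empty mask", call. = FALSE)
  pa <- which(mask_surface(a$grid), arr.ind = TRUE)
  pb <- which(mask_surface(b$grid), arr.ind = TRUE)
  pa <- sweep(pa, 2L, a$spacing, `*`)
  pb <- sweep(pb, 2L, b$spacing, `*`)
  dab <- nn_dists_cpp(pa, pb)
  dba <- nn_dists_cpp(pb, pa)
  c(mssd = mean(c(dab, dba)), hausdorff = max(max(dab), max(dba)))
}

#' Per-class segmentation metrics report
#'
#' Evaluates a predicted label map against a reference by one-vs-rest
#' binarization of each requested class, reporting Dice, mean symmetric
#' surface distance and Hausdorff distance per class.
#'
#' A class empty in both maps scores Dice 1 with distances `NA` and is
#' flagged `absent`; a class empty in exactly one map scores its Dice (0)
#' with distances `NA` (surfaces undefined).
#'
#' @param pred,truth [label_map()] objects with identical shape and spacing.
#' @param classes Integer vector of organ codes to evaluate. Defaults to
#'   all non-background codes present in either map.
#' @return An object of class `metrics_report`: list with `per_class` (a
#'   data.frame with columns class, name, dice, mssd, hausdorff, absent)
#'   and `mean_dice`.
#' @export
evaluate_labelmaps <- function(pred, truth, classes = NULL) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  check_same_geometry(pred, truth, "label maps")
  if (is.null(classes)) {
    classes <- sort(unique(c(pred$codes[pred$codes > 0L], truth$codes[truth$codes > 0L])))
    if (length(classes) == 0L) classes <- integer(0)
  }
  classes <- as.integer(classes)
  codes <- organ_codes()
  rows <- lapply(classes, function(cid) {
    pm <- label_mask(pred, cid)
    tm <- label_mask(truth, cid)
    both_empty <- !any(pm$grid) && !any(tm$grid)
    d <- if (both_empty) 1 else dice(pm, tm)
    if (any(pm$grid) && any(tm$grid)) {
      sd <- surface_distances(pm, tm)
    } else {
      sd <- c(mssd = NA_real_, hausdorff = NA_real_)
    }
    data.frame(class = cid, name = names(codes)[match(cid, codes)],
               dice = d, mssd = sd[["mssd"]], hausdorff = sd[["hausdorff"]],
               absent = both_empty)
  })
  per_class <- do.call(rbind, rows)
  structure(list(per_class = per_class,
                 mean_dice = if (nrow(per_class)) mean(per_class$dice) else NA_real_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  df <- x$per_class
  if (nrow(df)) {
    df$dice <- sprintf("%.4f", df$dice)
    df$mssd <- ifelse(is.na(df$mssd), "-", sprintf("%.2f mm", df$mssd))
    df$hausdorff <- ifelse(is.na(df$hausdorff), "-", sprintf("%.2f mm", df$hausdorff))
    print(df, row.names = FALSE)
  }
  cat(sprintf("mean Dice: %.4f\n", x$mean_dice))
  invisible(x)
}
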