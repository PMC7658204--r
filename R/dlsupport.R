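#' Anti-aliasing smoothing factors
#'
#' Per-axis Gaussian sigma (in source-voxel units) used before resampling a
#' volume with per-axis spacing `source_mm` to isotropic `target_mm`:
#' `sigma_k = (1/3) * max(target/source_k - 1, 0)`. Axes already at or above
#' the target resolution get sigma 0 (no smoothing); the heuristic places
#' the Gaussian cutoff at the ratio of sampling rates.
#'
#' @param target_mm Desired isotropic resolution in mm.
#' @param source_mm Per-axis source spacing in mm.
#' @return Numeric length-3 vector of sigmas (source-voxel units).
#' @examples
#' resample_sigmas(3, c(1, 1, 1))  # 2/3 on every axis
#' resample_sigmas(3, c(5, 5, 5))  # 0: upsampling, clamp active
#' @export
resample_sigmas <- function(target_mm, source_mm) {
  if (target_mm <= 0) stop("`target_mm` must be positive", call. = FALSE)
  source_mm <- check_spacing(source_mm)
  pmax(target_mm / source_mm - 1, 0) / 3
}

# 1D Gaussian smoothing along one array axis, kernel truncated at 3 sigma,
# edge-replicated boundary
smooth_axis <- function(a, sigma, axis) {
  if (sigma <= 0) return(a)
  t <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-((-t):t)^2 / (2 * sigma^2))
  w <- w / sum(w)
  n <- dim(a)[axis]
  out <- array(0, dim(a))
  for (i in seq_along(w)) {
    off <- i - t - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + w[i] * shifted
  }
  out
}

# trilinear resample of a 3D array onto a new voxel grid (centre-aligned)
trilinear_resample <- function(arr, src_spacing, tgt_shape, tgt_spacing) {
  d <- dim(arr)
  cs <- lapply(1:3, function(ax) {
    pos <- (seq_len(tgt_shape[ax]) - 0.5) * tgt_spacing[ax]
    pmin(pmax(pos / src_spacing[ax] + 0.5, 1), d[ax])
  })
  i0 <- lapply(1:3, function(ax) pmin(floor(cs[[ax]]), max(d[ax] - 1L, 1L)))
  fr <- lapply(1:3, function(ax) cs[[ax]] - i0[[ax]])

  n1 <- tgt_shape[1]; n2 <- tgt_shape[2]; n3 <- tgt_shape[3]
  I <- rep(i0[[1]], times = n2 * n3)
  J <- rep(rep(i0[[2]], each = n1), times = n3)
  K <- rep(i0[[3]], each = n1 * n2)
  FX <- rep(fr[[1]], times = n2 * n3)
  FY <- rep(rep(fr[[2]], each = n1), times = n3)
  FZ <- rep(fr[[3]], each = n1 * n2)

  acc <- numeric(n1 * n2 * n3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - FX else FX
    wy <- if (dy == 0) 1 - FY else FY
    wz <- if (dz == 0) 1 - FZ else FZ
    w <- wx * wy * wz
    if (all(w == 0)) next
    ii <- pmin(I + dx, d[1]); jj <- pmin(J + dy, d[2]); kk <- pmin(K + dz, d[3])
    acc <- acc + w * arr[cbind(ii, jj, kk)]
  }
  array(acc, tgt_shape)
}

#' Anti-aliased resampling of a CT volume
#'
#' Smooths each axis with the Gaussian whose sigma is given by
#' [resample_sigmas()] (acting as a low-pass filter against aliasing), then
#' trilinearly interpolates onto an isotropic grid of `target_mm` spacing.
#' Axes at or above the target resolution are not smoothed; resampling to
#' the source spacing is the identity up to interpolation tolerance.
#'
#' @param ct A [ct_volume()].
#' @param target_mm Desired isotropic resolution in mm (default 3).
#' @return A [ct_volume()] with spacing `rep(target_mm, 3)` and shape
#'   `max(1, round(extent / target_mm))` per axis.
#' @export
antialias_resample <- function(ct, target_mm = 3) {
  stopifnot(inherits(ct, "ct_volume"))
  if (target_mm <= 0) stop("`target_mm` must be positive", call. = FALSE)
  sig <- resample_sigmas(target_mm, ct$spacing)
  arr <- ct$hu
  for (ax in 1:3) arr <- smooth_axis(arr, sig[ax], ax)
  tgt_shape <- pmax(1L, as.integer(round(dim(arr) * ct$spacing / target_mm)))
  out <- trilinear_resample(arr, ct$spacing, tgt_shape, rep(target_mm, 3))
  ct_volume(out, rep(target_mm, 3))
}

#' Nearest-neighbour label upsampling
#'
#' Maps every target voxel to the label of the nearest source voxel centre.
#' No new codes are introduced.
#'
#' @param map A [label_map()].
#' @param target_shape Integer voxel triple of the output grid.
#' @param target_spacing Per-axis spacing (mm) of the output grid.
#' @return A [label_map()] on the target grid.
#' @export
nearest_upsample_labels <- function(map, target_shape, target_spacing) {
  stopifnot(inherits(map, "label_map"))
  target_shape <- as.integer(target_shape)
  target_spacing <- check_spacing(target_spacing)
  d <- dim(map$codes)
  idx <- lapply(1:3, function(ax) {
    pos <- (seq_len(target_shape[ax]) - 0.5) * target_spacing[ax]
    pmin(pmax(as.integer(round(pos / map$spacing[ax] + 0.5)), 1L), d[ax])
  })
  out <- map$codes[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  label_map(array(out, target_shape), target_spacing)
}

#' Tile cover for sliding-window inference
#'
#' Covers a volume with the minimal number of fixed-size, partially
#' overlapping tiles per axis (`ceil(extent / tile)` tiles, offsets evenly
#' spaced from 0 to `extent - tile`). Volumes smaller than one tile along an
#' axis are treated as zero-padded to the tile size (single offset 0).
#'
#' @param volume_shape Integer voxel triple.
#' @param tile_shape Integer voxel triple (default the 120 x 120 x 160
#'   network input).
#' @return Integer matrix of 0-based tile offsets, one row per tile,
#'   with attribute `tile_shape`. Tile t covers voxels
#'   `offset + 1 .. offset + tile_shape` (1-based).
#' @export
tile_cover <- function(volume_shape, tile_shape = c(120L, 120L, 160L)) {
  v <- as.integer(volume_shape); t <- as.integer(tile_shape)
  if (length(v) != 3L || length(t) != 3L || any(v < 1L) || any(t < 1L))
    stop("shapes must be 3 positive integers", call. = FALSE)
  per_axis <- lapply(1:3, function(ax) {
    if (v[ax] <= t[ax]) return(0L)
    n <- as.integer(ceiling(v[ax] / t[ax]))
    as.integer(round(seq(0, v[ax] - t[ax], length.out = n)))
  })
  g <- as.matrix(expand.grid(x = per_axis[[1]], y = per_axis[[2]], z = per_axis[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  storage.mode(g) <- "integer"
  attr(g, "tile_shape") <- t
  g
}

#' Per-voxel class probability map
#'
#' A 4D array (3 spatial axes x C classes) holding a probability
#' distribution at every voxel.
#'
#' @param probs 4D numeric array; per-voxel class probabilities must lie in
#'   `[0, 1]` and sum to 1 within 1e-5.
#' @param classes Integer label codes corresponding to the 4th dimension
#'   (default `0:(C-1)`).
#' @return An object of class `prob_map`.
#' @export
prob_map <- function(probs, classes = NULL) {
  if (!is.array(probs) || length(dim(probs)) != 4L)
    stop("`probs` must be a 4D array", call. = FALSE)
  if (min(probs) < -1e-9 || max(probs) > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  s <- apply(probs, c(1, 2, 3), sum)
  if (max(abs(s - 1)) > 1e-5)
    stop("per-voxel probabilities must sum to 1 (tolerance 1e-5)", call. = FALSE)
  classes <- if (is.null(classes)) seq_len(dim(probs)[4]) - 1L else as.integer(classes)
  if (length(classes) != dim(probs)[4])
    stop("`classes` must match the 4th dimension", call. = FALSE)
  structure(list(probs = probs, classes = classes), class = "prob_map")
}

#' Average overlapping tile predictions
#'
#' Recombines per-tile probability maps into a volume-sized map by
#' unweighted per-voxel averaging over all tiles covering the voxel. The
#' mean of distributions is a distribution, so per-voxel normalisation is
#' preserved.
#'
#' @param tile_probs List of `list(offset = , probs = )` where `offset` is a
#'   0-based integer triple (a row of [tile_cover()]) and `probs` a 4D array
#'   over the tile.
#' @param volume_shape Integer voxel triple of the full volume.
#' @param classes Integer label codes for the class axis.
#' @return A [prob_map()] over the full volume.
#' @export
average_overlaps <- function(tile_probs, volume_shape, classes = NULL) {
  v <- as.integer(volume_shape)
  stopifnot(length(tile_probs) >= 1L)
  nc <- dim(tile_probs[[1]]$probs)[4]
  acc <- array(0, c(v, nc))
  cnt <- array(0L, v)
  for (tp in tile_probs) {
    off <- as.integer(tp$offset)
    td <- dim(tp$probs)[1:3]
    ix <- off[1] + seq_len(td[1]); iy <- off[2] + seq_len(td[2]); iz <- off[3] + seq_len(td[3])
    if (max(ix) > v[1] || max(iy) > v[2] || max(iz) > v[3])
      stop("tile extends beyond the volume", call. = FALSE)
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + tp$probs
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
  }
  if (any(cnt == 0L))
    stop("internal error: some voxels are covered by no tile", call. = FALSE)
  for (c in seq_len(nc)) acc[, , , c] <- acc[, , , c] / cnt
  prob_map(acc, classes)
}

#' Smooth IOU (soft Jaccard) loss
#'
#' For each class c the loss is
#' `L_c = 1 - (p_c . y_c) / (|p_c|_1 + |y_c|_1 - p_c . y_c)` where `p_c` is
#' the predicted probability channel and `y_c` the one-hot reference; the
#' returned value is the mean of `L_c` over all requested classes,
#' background included. On binary probabilities this equals 1 minus the
#' Jaccard index. A class absent from both prediction support and reference
#' (zero denominator) contributes loss 0.
#'
#' @param p A [prob_map()] (or bare 4D array).
#' @param y A [label_map()] over the same spatial grid.
#' @param classes Integer label codes to average over; defaults to the
#'   prob map's classes (all channels, including background).
#' @return The mean loss (scalar in `[0, 1]`), with attribute `per_class`.
#' @export
iou_loss <- function(p, y, classes = NULL) {
  if (!inherits(p, "prob_map")) p <- prob_map(p)
  stopifnot(inherits(y, "label_map"))
  if (!identical(dim(p$probs)[1:3], dim(y$codes)))
    stop("probability map and labels must share the spatial grid", call. = FALSE)
  classes <- if (is.null(classes)) p$classes else as.integer(classes)
  per <- vapply(classes, function(cid) {
    ch <- match(cid, p$classes)
    if (is.na(ch)) stop(sprintf("class %d has no probability channel", cid), call. = FALSE)
    pc <- p$probs[, , , ch]
    yc <- as.numeric(y$codes == cid)
    num <- sum(pc * yc)
    den <- sum(pc) + sum(yc) - num
    if (den == 0) 0 else 1 - num / den
  }, numeric(1))
  structure(mean(per), per_class = stats::setNames(per, classes))
}
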