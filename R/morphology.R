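#' @section Fourier-domain binary morphology:
#' Dilation of a binary image f by a structuring element k is the support of
#' the real-valued convolution f * k: a voxel is set wherever the convolution
#' is non-zero. Since the ideal convolution of 0/1 inputs is integer-valued,
#' the implementation thresholds at 0.5, which is maximally robust to FFT
#' round-off. Erosion is computed by duality as the complement of the
#' dilation of the complement. Opening and closing are the usual
#' compositions.
#' @name morphology
NULL

# Linear convolution of two 3D numeric arrays via zero-padded FFTs, cropped
# centred on the kernel origin so the output shape equals dim(f). Padding is
# rounded up to 2/3/5-smooth lengths for fast transforms.
fft_conv3 <- function(f, k) {
  dn <- dim(f)
  dm <- dim(k)
  pad <- vapply(dn + dm - 1L, function(n) stats::nextn(n, c(2L, 3L, 5L)), integer(1))
  fa <- array(0, pad)
  fa[seq_len(dn[1]), seq_len(dn[2]), seq_len(dn[3])] <- f
  ka <- array(0, pad)
  ka[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- k
  conv <- Re(stats::fft(stats::fft(fa) * stats::fft(ka), inverse = TRUE)) / prod(pad)
  o <- (dm - 1L) %/% 2L
  conv[o[1] + seq_len(dn[1]), o[2] + seq_len(dn[2]), o[3] + seq_len(dn[3])]
}

# translate a logical array by integer offset v, filling with FALSE
shift_logical <- function(a, v) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    lo <- max(1L, 1L - v[ax]); hi <- min(d[ax], d[ax] - v[ax])
    if (lo > hi) return(out)
    src[[ax]] <- lo:hi
    dst[[ax]] <- (lo + v[ax]):(hi + v[ax])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

dilate_grid_direct <- function(f, se) {
  idx <- which(se$grid, arr.ind = TRUE)
  out <- array(FALSE, dim(f))
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ] - se$origin
    out <- out | shift_logical(f, v)
  }
  out
}

dilate_grid_fft <- function(f, se) {
  conv <- fft_conv3(array(as.numeric(f), dim(f)),
                    array(as.numeric(se$grid), dim(se$grid)))
  conv >= 0.5
}

# point reflection of the se about its origin (identity for symmetric ses)
se_reflect <- function(se) {
  d <- dim(se$grid)
  struct_el(se$grid[d[1]:1, d[2]:1, d[3]:1, drop = FALSE])
}

check_se_fits <- function(mask, se) {
  if (any(dim(se$grid) > dim(mask$grid)))
    stop("structuring element is larger than the mask along some axis",
         call. = FALSE)
}

morph_backend <- function(backend = NULL) {
  b <- backend %||% getOption("ctmorphseg.backend", "fft")
  if (!b %in% c("fft", "direct")) stop("backend must be 'fft' or 'direct'", call. = FALSE)
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary dilation
#'
#' Dilates a mask by a structuring element. The default back-end computes the
#' real-valued convolution of mask and kernel with zero-padded FFTs and sets
#' every voxel where the convolution reaches 0.5 (the ideal value is a
#' non-negative integer). The `direct` back-end forms the Minkowski sum
#' explicitly as a union of translated masks; both back-ends agree
#' voxel-for-voxel. Out-of-bounds voxels are treated as background.
#'
#' @param mask A [binary_mask()].
#' @param se A [struct_el()]; must fit inside the mask along every axis.
#' @param backend `"fft"` (default, see `options(ctmorphseg.backend=)`) or
#'   `"direct"`.
#' @return A `binary_mask` of the same shape.
#' @seealso [erode()], [opening()], [closing()]
#' @export
dilate <- function(mask, se, backend = NULL) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "struct_el"))
  check_se_fits(mask, se)
  g <- switch(morph_backend(backend),
              fft = dilate_grid_fft(mask$grid, se),
              direct = dilate_grid_direct(mask$grid, se))
  binary_mask(g, mask$spacing)
}

#' Binary erosion
#'
#' Erosion is computed by duality as the complement of the dilation of the
#' complement by the point-reflected structuring element (the reflection
#' makes erosion the exact adjoint of dilation; for the symmetric spheres,
#' prisms and cubes used by the segmentation algorithms it is the identity).
#' The volume border behaves as if objects continued past it: they are not
#' eaten inward by erosion (an all-true volume stays all-true).
#'
#' @inheritParams dilate
#' @return A `binary_mask` of the same shape.
#' @export
erode <- function(mask, se, backend = NULL) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "struct_el"))
  check_se_fits(mask, se)
  ser <- se_reflect(se)
  g <- switch(morph_backend(backend),
              fft = !dilate_grid_fft(!mask$grid, ser),
              direct = !dilate_grid_direct(!mask$grid, ser))
  binary_mask(g, mask$spacing)
}

#' Morphological opening and closing
#'
#' Opening is erosion followed by dilation (removes objects smaller than the
#' structuring element); closing is dilation followed by erosion (fills gaps
#' narrower than the structuring element).
#'
#' The compositions are evaluated on a background-extended domain: the mask
#' is padded by the structuring-element half-extent, the two steps run on
#' the padded grid, and the result is cropped back ("safe border"). This
#' makes the composites equal to their infinite-domain counterparts
#' restricted to the volume, so opening is anti-extensive, closing is
#' extensive, and both are exactly idempotent — properties a naive
#' composition of border-convention primitives does not keep near the
#' volume border.
#'
#' @inheritParams dilate
#' @return A `binary_mask` of the same shape.
#' @export
opening <- function(mask, se, backend = NULL) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "struct_el"))
  check_se_fits(mask, se)
  binary_mask(compose_padded(mask$grid, se, erode_first = TRUE,
                             morph_backend(backend)), mask$spacing)
}

#' @rdname opening
#' @export
closing <- function(mask, se, backend = NULL) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "struct_el"))
  check_se_fits(mask, se)
  binary_mask(compose_padded(mask$grid, se, erode_first = FALSE,
                             morph_backend(backend)), mask$spacing)
}

# erosion/dilation composition on a grid padded by the se half-extent;
# equals the infinite-domain composite cropped to the original window
compose_padded <- function(g, se, erode_first, backend) {
  h <- (dim(se$grid) - 1L) %/% 2L
  d <- dim(g)
  gp <- array(FALSE, d + 2L * h)
  win <- lapply(1:3, function(ax) h[ax] + seq_len(d[ax]))
  gp[win[[1]], win[[2]], win[[3]]] <- g
  dil <- function(x) switch(backend,
                            fft = dilate_grid_fft(x, se),
                            direct = dilate_grid_direct(x, se))
  ser <- se_reflect(se)
  ero <- function(x) switch(backend,
                            fft = !dilate_grid_fft(!x, ser),
                            direct = !dilate_grid_direct(!x, ser))
  out <- if (erode_first) dil(ero(gp)) else ero(dil(gp))
  out[win[[1]], win[[2]], win[[3]]]
}

#' Spherical structuring element in physical units
#'
#' Rasterises a sphere of the given physical diameter onto the voxel grid,
#' honouring anisotropic spacing: voxel v (offset from the centre voxel) is
#' set iff sum_k (v_k * spacing_k)^2 <= (diameter/2)^2. The grid is the
#' smallest odd bounding box. A diameter smaller than the smallest voxel
#' yields a single-voxel element.
#'
#' @param diameter_mm Positive sphere diameter in mm.
#' @param spacing Per-axis voxel size in mm.
#' @return A [struct_el()].
#' @examples
#' make_sphere_se(10, c(2, 2, 2))  # 5 x 5 x 5
#' @export
make_sphere_se <- function(diameter_mm, spacing) {
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L || diameter_mm <= 0)
    stop("`diameter_mm` must be a positive number", call. = FALSE)
  spacing <- check_spacing(spacing)
  r <- diameter_mm / 2
  half <- pmax(0L, as.integer(floor(r / spacing)))
  d <- 2L * half + 1L
  off <- lapply(1:3, function(ax) ((seq_len(d[ax]) - half[ax] - 1L) * spacing[ax])^2)
  g <- outer(outer(off[[1]], off[[2]], `+`), off[[3]], `+`) <= r^2
  struct_el(array(g, d))
}

#' Rectangular prism structuring element
#'
#' A fully set rectangular prism of the given voxel extents. Each extent is
#' promoted up to the nearest odd integer so the element has a centre origin.
#'
#' @param extent_voxels Integer length-3 vector of positive extents, in
#'   voxels.
#' @return A [struct_el()].
#' @examples
#' make_prism_se(c(1, 4, 1))  # promoted to 1 x 5 x 1
#' @export
make_prism_se <- function(extent_voxels) {
  e <- as.integer(extent_voxels)
  if (length(e) != 3L || anyNA(e) || any(e < 1L))
    stop("`extent_voxels` must be 3 positive integers", call. = FALSE)
  e <- e + (e %% 2L == 0L)  # promote even to odd
  struct_el(array(TRUE, e))
}
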