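# Independent brute-force oracles and fixture generators. These deliberately
# avoid the package's internal code paths: the dilation oracle stamps the
# structuring element over every foreground voxel (the set-theoretic
# Minkowski sum), the component oracle is a plain R flood fill, the
# reconstruction oracle iterates conditional dilation to a fixpoint, and the
# surface-distance oracle is an all-pairs scan.

random_mask <- function(shape, p = 0.1, spacing = c(1, 1, 1)) {
  binary_mask(array(stats::runif(prod(shape)) < p, shape), spacing)
}

random_se <- function(max_extent = 7L, symmetric = FALSE) {
  d <- 2L * sample.int((max_extent + 1L) %/% 2L, 3L, replace = TRUE) - 1L
  g <- array(stats::runif(prod(d)) < 0.5, d)
  if (symmetric) g <- g | g[d[1]:1, d[2]:1, d[3]:1, drop = FALSE]
  g[(d[1] + 1L) %/% 2L, (d[2] + 1L) %/% 2L, (d[3] + 1L) %/% 2L] <- TRUE  # origin set
  struct_el(g)
}

se_reflect_grid <- function(se) {
  d <- dim(se$grid)
  struct_el(se$grid[d[1]:1, d[2]:1, d[3]:1, drop = FALSE])
}

# Minkowski sum: union of the se translated to every foreground voxel
oracle_dilate_grid <- function(grid, se) {
  d <- dim(grid); m <- dim(se$grid); o <- se$origin
  out <- array(FALSE, d)
  fg <- which(grid, arr.ind = TRUE)
  sev <- which(se$grid, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    pos <- sweep(sev, 2L, fg[r, ] - o, `+`)
    keep <- pos[, 1] >= 1 & pos[, 1] <= d[1] &
            pos[, 2] >= 1 & pos[, 2] <= d[2] &
            pos[, 3] >= 1 & pos[, 3] <= d[3]
    if (any(keep)) out[pos[keep, , drop = FALSE]] <- TRUE
  }
  out
}

# adjoint erosion: complement-dilation by the point-reflected element
oracle_erode_grid <- function(grid, se) !oracle_dilate_grid(!grid, se_reflect_grid(se))

# open/close: compose on a background-padded domain (the infinite-domain
# composite restricted to the window), independently of the package's code
oracle_pad <- function(grid, h) {
  d <- dim(grid)
  out <- array(FALSE, d + 2L * h)
  out[h[1] + seq_len(d[1]), h[2] + seq_len(d[2]), h[3] + seq_len(d[3])] <- grid
  out
}
oracle_crop <- function(grid, h, d) {
  grid[h[1] + seq_len(d[1]), h[2] + seq_len(d[2]), h[3] + seq_len(d[3])]
}
oracle_open_grid <- function(grid, se) {
  h <- (dim(se$grid) - 1L) %/% 2L
  g <- oracle_pad(grid, h)
  oracle_crop(oracle_dilate_grid(oracle_erode_grid(g, se), se), h, dim(grid))
}
oracle_close_grid <- function(grid, se) {
  h <- (dim(se$grid) - 1L) %/% 2L
  g <- oracle_pad(grid, h)
  oracle_crop(oracle_erode_grid(oracle_dilate_grid(g, se), se), h, dim(grid))
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = m == 1, "18" = m >= 1 & m <= 2, "26" = m >= 1)
  off[keep, , drop = FALSE]
}

# flood-fill component sizes, independent of the C++ labeler
oracle_component_sizes <- function(grid, connectivity) {
  d <- dim(grid)
  seen <- array(FALSE, d)
  offs <- neighbour_offsets(connectivity)
  sizes <- integer(0)
  fg <- which(grid)
  for (s in fg) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      k <- (v - 1L) %/% (d[1] * d[2])
      j <- ((v - 1L) %% (d[1] * d[2])) %/% d[1]
      i <- (v - 1L) %% d[1]
      nb <- sweep(offs, 2L, c(i, j, k), `+`)
      ok <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 & nb[, 2] < d[2] &
            nb[, 3] >= 0 & nb[, 3] < d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] + d[2] * nb[, 3]) + 1L
      lin <- lin[grid[lin] & !seen[lin]]
      seen[lin] <- TRUE
      queue <- c(queue, lin)
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# geodesic dilation of seeds inside reference, iterated to fixpoint
oracle_reconstruct_grid <- function(reference, seeds, connectivity) {
  cur <- seeds & reference
  box <- struct_el(array(TRUE, c(3L, 3L, 3L)))
  if (connectivity == 6L) {
    g <- array(FALSE, c(3L, 3L, 3L))
    g[2, 2, 2] <- g[1, 2, 2] <- g[3, 2, 2] <- g[2, 1, 2] <- g[2, 3, 2] <-
      g[2, 2, 1] <- g[2, 2, 3] <- TRUE
    box <- struct_el(g)
  }
  repeat {
    nxt <- oracle_dilate_grid(cur, box) & reference
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# all-pairs surface distances from first principles
oracle_surface_distances <- function(a, b) {
  surf <- function(grid) {
    d <- dim(grid)
    pts <- which(grid, arr.ind = TRUE)
    is_surf <- logical(nrow(pts))
    for (r in seq_len(nrow(pts))) {
      p <- pts[r, ]
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        q <- p; q[ax] <- q[ax] + s
        if (any(q < 1) || any(q > d) || !grid[q[1], q[2], q[3]]) is_surf[r] <- TRUE
      }
    }
    pts[is_surf, , drop = FALSE]
  }
  pa <- sweep(surf(a$grid), 2L, a$spacing, `*`)
  pb <- sweep(surf(b$grid), 2L, b$spacing, `*`)
  dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), function(i, j) {
    sqrt((pa[i, 1] - pb[j, 1])^2 + (pa[i, 2] - pb[j, 2])^2 + (pa[i, 3] - pb[j, 3])^2)
  })
  dab <- apply(dmat, 1L, min)
  dba <- apply(dmat, 2L, min)
  c(mssd = mean(c(dab, dba)), hausdorff = max(max(dab), max(dba)))
}

# phantom cohort cache shared across test files (generation is the slow part)
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(seed, ...) {
  key <- paste0("s", seed)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(phantom_spec(seed = seed, ...))
  .phantom_cache[[key]]
}
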