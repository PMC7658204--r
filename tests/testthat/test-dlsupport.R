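test_that("anti-aliasing sigmas follow the spacing-ratio formula", {
  expect_equal(resample_sigmas(3, c(1, 1, 1)), rep(2/3, 3))
  expect_equal(resample_sigmas(3, c(3, 3, 3)), rep(0, 3))
  expect_equal(resample_sigmas(3, c(5, 5, 5)), rep(0, 3))  # upsampling clamp
  expect_equal(resample_sigmas(3, c(1, 2, 6)), c(2/3, 1/6, 0))
  expect_error(resample_sigmas(-1, c(1, 1, 1)), "positive")
})

test_that("resampling to the source spacing is the identity", {
  set.seed(4)
  ct <- ct_volume(array(stats::rnorm(10 * 12 * 9), c(10, 12, 9)), c(3, 3, 3))
  out <- antialias_resample(ct, 3)
  expect_equal(dim(out$hu), dim(ct$hu))
  expect_lt(max(abs(out$hu - ct$hu)), 1e-6)
})

test_that("downsampling smooths and shrinks to the expected grid", {
  set.seed(8)
  ct <- ct_volume(array(stats::rnorm(24 * 24 * 24), c(24, 24, 24)), c(1, 1, 1))
  out <- antialias_resample(ct, 3)
  expect_equal(dim(out$hu), c(8L, 8L, 8L))
  expect_equal(out$spacing, rep(3, 3))
  expect_lt(stats::sd(out$hu), stats::sd(ct$hu))  # low-pass reduces variance
})

test_that("nearest-neighbour label upsampling preserves code support", {
  codes <- array(0L, c(4, 4, 4)); codes[2, 3, 2] <- 5L
  m <- label_map(codes, c(2, 2, 2))
  same <- nearest_upsample_labels(m, c(4, 4, 4), c(2, 2, 2))
  expect_identical(same$codes, m$codes)

  up <- nearest_upsample_labels(m, c(8, 8, 8), c(1, 1, 1))
  expect_equal(sum(up$codes == 5L), 8)          # 2x2x2 block
  expect_true(all(up$codes[3:4, 5:6, 3:4] == 5L))

  set.seed(2)
  r <- label_map(array(sample(0:6, 5 * 6 * 4, TRUE), c(5, 6, 4)), c(3, 3, 3))
  u <- nearest_upsample_labels(r, c(10, 12, 8), c(1.5, 1.5, 1.5))
  expect_setequal(unique(as.vector(u$codes)), unique(as.vector(r$codes)))
})

test_that("tile covers are minimal and cover every voxel", {
  one <- tile_cover(c(120, 120, 160))
  expect_equal(nrow(one), 1L)
  expect_equal(unname(one[1, ]), c(0L, 0L, 0L))

  two <- tile_cover(c(240, 120, 160))
  expect_equal(sort(two[, 1]), c(0L, 120L))

  g <- tile_cover(c(130, 130, 170))
  expect_equal(nrow(g), 8L)

  set.seed(6)
  for (i in 1:12) {
    vs <- sample(50:400, 3)
    ts <- c(120L, 120L, 160L)
    tl <- tile_cover(vs, ts)
    # minimal tiles per axis
    expect_equal(nrow(tl), prod(pmax(1, ceiling(vs / ts))))
    # coverage of the (possibly padded) volume
    cov <- array(FALSE, pmax(vs, ts))
    for (r in seq_len(nrow(tl))) {
      cov[tl[r, 1] + seq_len(ts[1]), tl[r, 2] + seq_len(ts[2]),
          tl[r, 3] + seq_len(ts[3])] <- TRUE
    }
    expect_true(all(cov[seq_len(vs[1]), seq_len(vs[2]), seq_len(vs[3])]))
  }
})

test_that("overlap averaging preserves per-voxel normalisation", {
  vshape <- c(6L, 4L, 4L)
  mk <- function(seed, d) {
    set.seed(seed)
    p <- array(stats::runif(prod(d) * 3), c(d, 3))
    s <- array(rep(apply(p, 1:3, sum), 3), c(d, 3))
    p / s
  }
  t1 <- list(offset = c(0L, 0L, 0L), probs = mk(1, c(4L, 4L, 4L)))
  t2 <- list(offset = c(2L, 0L, 0L), probs = mk(2, c(4L, 4L, 4L)))
  out <- average_overlaps(list(t1, t2), vshape)
  sums <- apply(out$probs, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  # overlap region is the plain mean
  expect_equal(out$probs[3, 1, 1, ], (t1$probs[3, 1, 1, ] + t2$probs[1, 1, 1, ]) / 2)
  # identical overlapping tiles average to themselves
  out2 <- average_overlaps(list(t1, list(offset = c(0L, 0L, 0L), probs = t1$probs)),
                           c(4L, 4L, 4L))
  expect_equal(out2$probs, t1$probs)
  # uncovered voxels violate the contract
  expect_error(average_overlaps(list(t1), vshape), "no tile")
})

test_that("the smooth IOU loss has its defining fixed points", {
  codes <- array(sample(0:1, 5 * 5 * 5, TRUE), c(5, 5, 5))
  y <- label_map(codes, c(1, 1, 1))
  onehot <- array(0, c(5, 5, 5, 2))
  onehot[, , , 1] <- as.numeric(codes == 0)
  onehot[, , , 2] <- as.numeric(codes == 1)
  expect_equal(as.numeric(iou_loss(prob_map(onehot), y)), 0)

  # binary disjoint prediction: loss 1 per class
  flipped <- onehot[, , , 2:1]
  l <- iou_loss(prob_map(flipped), y)
  expect_equal(unname(attr(l, "per_class")), c(1, 1))

  # uniform-half prediction on a half/half map: closed form 2/3 per class
  half <- array(0L, c(4, 4, 4)); half[1:2, , ] <- 1L
  yh <- label_map(half, c(1, 1, 1))
  p <- array(0.5, c(4, 4, 4, 2))
  n <- 64
  expected <- 1 - (0.5 * n / 2) / (0.5 * n + n / 2 - 0.5 * n / 2)
  expect_equal(as.numeric(iou_loss(prob_map(p), yh)), expected)
  expect_equal(expected, 2/3)

  # absent class contributes zero loss
  pz <- array(0, c(5, 5, 5, 2)); pz[, , , 1] <- 1
  l0 <- iou_loss(prob_map(pz, classes = c(0L, 5L)),
                 label_map(array(0L, c(5, 5, 5)), c(1, 1, 1)))
  expect_equal(unname(attr(l0, "per_class")[["5"]]), 0)
})

test_that("on binary inputs the loss equals 1 - Jaccard, consistent with Dice", {
  set.seed(3)
  for (i in 1:10) {
    ga <- array(stats::runif(6^3) < 0.4, c(6, 6, 6))
    gb <- array(stats::runif(6^3) < 0.4, c(6, 6, 6))
    if (!any(ga) && !any(gb)) next
    y <- label_map(array(as.integer(gb), c(6, 6, 6)), c(1, 1, 1))
    p <- array(0, c(6, 6, 6, 2))
    p[, , , 1] <- as.numeric(!ga)
    p[, , , 2] <- as.numeric(ga)
    lc <- attr(iou_loss(prob_map(p), y), "per_class")[["1"]]
    jac <- sum(ga & gb) / sum(ga | gb)
    expect_equal(1 - lc, jac)
    # dice = 2J / (1 + J)
    d <- dice(binary_mask(ga), binary_mask(gb))
    expect_equal(d, 2 * jac / (1 + jac))
  }
})

test_that("probability maps are validated", {
  bad <- array(0.6, c(2, 2, 2, 2))
  expect_error(prob_map(bad), "sum to 1")
  expect_error(prob_map(array(1, c(2, 2))), "4D")
})
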