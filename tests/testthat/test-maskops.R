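test_that("component labeling follows the chosen neighbourhood", {
  m <- binary_mask(array(FALSE, c(4, 4, 4)))
  m$grid[1, 1, 1] <- m$grid[4, 4, 4] <- TRUE
  cl <- label_components(m, 26)
  expect_equal(cl$sizes, c(1L, 1L))

  dg <- binary_mask(array(FALSE, c(4, 4, 4)))
  dg$grid[2, 2, 2] <- dg$grid[3, 3, 3] <- TRUE
  expect_length(label_components(dg, 26)$sizes, 1L)
  expect_length(label_components(dg, 6)$sizes, 2L)
  expect_length(label_components(dg, 18)$sizes, 2L)
  expect_error(label_components(dg, 8), "connectivity")
})

test_that("component sizes match the flood-fill oracle and are axis-invariant", {
  set.seed(5)
  for (conn in c(6L, 18L, 26L)) {
    for (i in 1:6) {
      m <- random_mask(c(9, 8, 10), p = 0.25)
      cl <- label_components(m, conn)
      expect_equal(sort(cl$sizes, decreasing = TRUE),
                   oracle_component_sizes(m$grid, conn))
      expect_equal(sum(cl$sizes), sum(m$grid))
      # labels partition the foreground exactly
      expect_identical(cl$labels > 0L, m$grid)
      # sizes invariant under axis permutation
      mp <- binary_mask(aperm(m$grid, c(3, 1, 2)))
      expect_equal(label_components(mp, conn)$sizes, cl$sizes)
    }
  }
})

test_that("largest_components keeps the k biggest, ties by smallest index", {
  m <- binary_mask(array(FALSE, c(16, 16, 16)))
  m$grid[2:4, 2:4, 2:4] <- TRUE     # 27
  m$grid[8:9, 8:9, 8:9] <- TRUE     # 8
  m$grid[14, 14, 14] <- TRUE        # 1
  top2 <- largest_components(m, 2)
  expect_equal(sum(top2$grid), 35)
  expect_false(top2$grid[14, 14, 14])
  expect_identical(largest_components(top2, 2)$grid, top2$grid)

  # tie: two equal blobs, keep the one with the smallest linear index
  t2 <- binary_mask(array(FALSE, c(8, 8, 8)))
  t2$grid[1:2, 1, 1] <- TRUE
  t2$grid[5:6, 5, 5] <- TRUE
  keep <- largest_components(t2, 1)
  expect_true(all(keep$grid[1:2, 1, 1]))
  expect_false(any(keep$grid[5:6, 5, 5]))

  err <- tryCatch(largest_components(t2, 5), condition = identity)
  expect_s3_class(err, "ctmorphseg_too_few_components")
  expect_equal(err$n_found, 2L)

  # monotone in k
  expect_true(all(largest_components(m, 3)$grid[largest_components(m, 1)$grid]))
})

test_that("boundary-connected removal uses the in-plane border only", {
  m <- binary_mask(array(FALSE, c(10, 10, 6)))
  m$grid[c(1, 10), , 3] <- TRUE   # frame touching the x border
  m$grid[, c(1, 10), 3] <- TRUE
  m$grid[5:6, 5:6, 3] <- TRUE     # interior blob
  out <- remove_boundary_connected(m)
  expect_equal(sum(out$grid), 4)
  expect_true(all(out$grid[5:6, 5:6, 3]))

  # blob touching the top z-slice interior is kept
  zt <- binary_mask(array(FALSE, c(10, 10, 6)))
  zt$grid[4:6, 4:6, 5:6] <- TRUE
  expect_identical(remove_boundary_connected(zt)$grid, zt$grid)
})

test_that("axial hole filling fills enclosed 2D holes only", {
  ring <- binary_mask(array(FALSE, c(12, 12, 3)))
  ring$grid[3:9, 3:9, 2] <- TRUE
  ring$grid[5:7, 5:7, 2] <- FALSE
  filled <- fill_holes_axial(ring)
  expect_true(all(filled$grid[3:9, 3:9, 2]))
  expect_identical(filled$grid[, , c(1, 3)], ring$grid[, , c(1, 3)])
  # idempotent and extensive
  expect_identical(fill_holes_axial(filled)$grid, filled$grid)
  expect_true(all(filled$grid[ring$grid]))

  # C-shaped ring: hole leaks to the border, unchanged
  cshape <- binary_mask(array(FALSE, c(12, 12, 1)))
  cshape$grid[3:9, 3:9, 1] <- TRUE
  cshape$grid[5:7, 5:7, 1] <- FALSE
  cshape$grid[6, 7:12, 1] <- FALSE  # corridor to the border
  expect_identical(fill_holes_axial(cshape)$grid, cshape$grid)

  solid <- binary_mask(array(TRUE, c(6, 6, 2)))
  expect_identical(fill_holes_axial(solid)$grid, solid$grid)
})

test_that("reconstruction returns exactly the seeded components", {
  ref <- binary_mask(array(FALSE, c(12, 12, 4)))
  ref$grid[2:4, 2:4, 2] <- TRUE
  ref$grid[8:10, 8:10, 2] <- TRUE
  seeds <- binary_mask(array(FALSE, c(12, 12, 4)))
  seeds$grid[3, 3, 2] <- TRUE
  rec <- reconstruct_from_seeds(ref, seeds)
  expect_true(all(rec$grid[2:4, 2:4, 2]))
  expect_false(any(rec$grid[8:10, 8:10, 2]))

  none <- binary_mask(array(FALSE, c(12, 12, 4)))
  expect_false(any(reconstruct_from_seeds(ref, none)$grid))
  # identity and subset laws
  expect_identical(reconstruct_from_seeds(ref, ref)$grid, ref$grid)
})

test_that("reconstruction matches iterated geodesic dilation on random cases", {
  set.seed(31)
  for (conn in c(6L, 26L)) {
    for (i in 1:8) {
      ref <- random_mask(c(10, 9, 8), p = 0.3)
      seeds <- random_mask(c(10, 9, 8), p = 0.05)
      got <- reconstruct_from_seeds(ref, seeds, conn)
      expect_identical(got$grid, oracle_reconstruct_grid(ref$grid, seeds$grid, conn))
      expect_true(all(ref$grid[got$grid]))
    }
  }
})
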