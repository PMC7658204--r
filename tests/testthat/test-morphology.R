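test_that("dilation of a point is the structuring element; empty stays empty", {
  m <- binary_mask(array(FALSE, c(9, 9, 9)))
  m$grid[5, 5, 5] <- TRUE
  se <- struct_el(array(TRUE, c(3, 3, 3)))
  d <- dilate(m, se)
  expect_equal(sum(d$grid), 27)
  expect_true(all(d$grid[4:6, 4:6, 4:6]))

  empty <- binary_mask(array(FALSE, c(9, 9, 9)))
  expect_false(any(dilate(empty, se)$grid))
})

test_that("erosion respects the non-eating border convention", {
  se <- struct_el(array(TRUE, c(3, 3, 3)))
  full <- binary_mask(array(TRUE, c(8, 8, 8)))
  expect_true(all(erode(full, se)$grid))

  point <- binary_mask(array(FALSE, c(8, 8, 8)))
  point$grid[4, 4, 4] <- TRUE
  expect_false(any(erode(point, se)$grid))
})

test_that("a structuring element larger than the mask is rejected", {
  m <- binary_mask(array(TRUE, c(4, 4, 4)))
  se <- struct_el(array(TRUE, c(5, 1, 1)))
  expect_error(dilate(m, se), "larger than the mask")
  expect_error(erode(m, se), "larger than the mask")
})

test_that("fft morphology matches the set-theoretic oracles on random instances", {
  set.seed(101)
  for (i in 1:40) {
    m <- random_mask(sample(6:16, 3, replace = TRUE), p = stats::runif(1, 0.05, 0.3))
    se <- random_se(5L)
    expect_identical(dilate(m, se)$grid, oracle_dilate_grid(m$grid, se))
    expect_identical(erode(m, se)$grid, oracle_erode_grid(m$grid, se))
  }
})

test_that("fft and direct back-ends agree bit-exactly", {
  set.seed(77)
  for (i in 1:20) {
    m <- random_mask(sample(6:20, 3, replace = TRUE), p = stats::runif(1, 0.05, 0.4))
    se <- random_se(7L)
    expect_identical(dilate(m, se, backend = "fft")$grid,
                     dilate(m, se, backend = "direct")$grid)
    expect_identical(erode(m, se, backend = "fft")$grid,
                     erode(m, se, backend = "direct")$grid)
  }
  expect_error(dilate(random_mask(c(5, 5, 5)), random_se(3L), backend = "nope"),
               "backend")
})

test_that("opening removes isolated voxels and closing fills narrow gaps", {
  se <- struct_el(array(TRUE, c(3, 3, 3)))
  m <- binary_mask(array(FALSE, c(16, 16, 16)))
  m$grid[3:7, 3:7, 3:7] <- TRUE   # solid block survives opening
  m$grid[12, 12, 12] <- TRUE      # isolated voxel does not
  o <- opening(m, se)
  expect_false(o$grid[12, 12, 12])
  expect_true(all(o$grid[3:7, 3:7, 3:7]))

  # two 5^3 cubes abutting across a 1-voxel gap: closing bridges the gap
  g <- binary_mask(array(FALSE, c(16, 16, 16)))
  g$grid[2:6, 6:10, 6:10] <- TRUE
  g$grid[8:12, 6:10, 6:10] <- TRUE
  cl <- closing(g, se)
  expect_identical(cl$grid, oracle_close_grid(g$grid, se))
  expect_true(all(cl$grid[7, 6:10, 6:10]))
})

test_that("morphological algebra holds on random instances", {
  set.seed(42)
  for (i in 1:25) {
    m <- random_mask(sample(8:16, 3, replace = TRUE), p = stats::runif(1, 0.05, 0.35))
    se <- random_se(5L)
    dm <- dilate(m, se); em <- erode(m, se)
    # duality (stated for symmetric elements)
    ses <- random_se(5L, symmetric = TRUE)
    expect_identical(erode(m, ses)$grid, !dilate(mask_complement(m), ses)$grid)
    # extensivity / anti-extensivity (origin is always set in random_se)
    expect_true(all(dm$grid[m$grid]))
    expect_true(all(m$grid[em$grid]))
    # idempotence of opening/closing
    om <- opening(m, se); cm <- closing(m, se)
    expect_identical(opening(om, se)$grid, om$grid)
    expect_identical(closing(cm, se)$grid, cm$grid)
    # monotonicity: m2 = m union extra
    m2 <- binary_mask(m$grid | random_mask(dim(m$grid), 0.1)$grid, m$spacing)
    expect_true(all(dilate(m2, se)$grid[dm$grid]))
  }
})

test_that("fft convolution of binary inputs is integer-valued to 1e-3", {
  set.seed(9)
  for (i in 1:10) {
    m <- random_mask(sample(8:32, 3, replace = TRUE), p = 0.2)
    se <- random_se(9L)
    conv <- ctmorphseg:::fft_conv3(array(as.numeric(m$grid), dim(m$grid)),
                                   array(as.numeric(se$grid), dim(se$grid)))
    expect_lt(max(abs(conv - round(conv))), 1e-3)
  }
})

test_that("spherical elements rasterize physical diameters with anisotropy", {
  se <- make_sphere_se(10, c(2, 2, 2))
  expect_equal(dim(se$grid), c(5L, 5L, 5L))
  expect_true(se$grid[3, 3, 3])
  expect_false(se$grid[1, 1, 1])

  expect_equal(dim(make_sphere_se(1, c(2, 2, 2))$grid), c(1L, 1L, 1L))
  expect_equal(dim(make_sphere_se(6, c(1, 1, 3))$grid), c(7L, 7L, 3L))
  expect_error(make_sphere_se(10, c(0, 1, 1)), "positive")
  expect_error(make_sphere_se(-3, c(1, 1, 1)), "positive")
})

test_that("prism elements are promoted to odd extents", {
  expect_equal(dim(make_prism_se(c(1, 5, 1))$grid), c(1L, 5L, 1L))
  expect_true(all(make_prism_se(c(1, 5, 1))$grid))
  expect_equal(dim(make_prism_se(c(1, 4, 1))$grid), c(1L, 5L, 1L))
  expect_error(make_prism_se(c(1, 0, 1)), "positive")
  # the table-puncture rule at 2 mm spacing: 10/d = 5 voxels along y
  expect_equal(as.integer(ceiling(10 / 2)), 5L)
})
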