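test_that("identical volumes self-match with zero displacement and unit quality", {
  a <- static_speckle(24)
  f <- estimate_displacement(a, a, tracking_params(stride = 2L))
  sel <- which(f$estimated)
  expect_true(all(abs(f$vectors[, , , 1][sel]) == 0))
  expect_true(all(abs(f$vectors[, , , 2][sel]) == 0))
  expect_true(all(abs(f$vectors[, , , 3][sel]) == 0))
  expect_true(all(f$quality[sel] > 0.999))
})

test_that("integer circular shifts are recovered exactly in the interior", {
  a <- static_speckle(32)
  b <- circshift3(a, 3, 1)
  f <- estimate_displacement(a, b, tracking_params(subvoxel = FALSE,
                                                   stride = 2L))
  interior <- array(FALSE, dim(a))
  interior[10:23, 10:23, 10:23] <- TRUE
  sel <- which(f$estimated & interior)
  expect_true(all(f$vectors[, , , 1][sel] == 3))
  expect_true(all(f$vectors[, , , 2][sel] == 0))
  expect_true(all(f$vectors[, , , 3][sel] == 0))
  # displacement reported in mm: scale by spacing
  f2 <- estimate_displacement(a, b, tracking_params(subvoxel = FALSE,
                                                    stride = 4L),
                              spacing = c(0.5, 0.5, 0.5))
  sel2 <- which(f2$estimated & interior)
  expect_true(all(f2$vectors[, , , 1][sel2] == 1.5))
})

test_that("subvoxel shifts are recovered within 0.2 voxel on speckle", {
  a <- static_speckle(32)
  b <- spline_shift_x(a, 0.5)
  f <- estimate_displacement(a, b, tracking_params(stride = 2L))
  interior <- array(FALSE, dim(a))
  interior[10:23, 10:23, 10:23] <- TRUE
  sel <- which(f$estimated & interior)
  err <- abs(f$vectors[, , , 1][sel] - 0.5)
  expect_lt(mean(err), 0.2)
})

test_that("input contract violations raise errors", {
  a <- static_speckle(16)
  expect_error(estimate_displacement(a, a[1:8, , ]), "shape")
  expect_error(estimate_displacement(a, a, tracking_params(block_size = 17)),
               "block larger")
  expect_error(tracking_params(block_size = 1), "block_size")
  expect_error(tracking_params(block_size = 8), "odd")
  expect_error(tracking_params(search_radius = 0), "search_radius")
})

test_that("tracking is equivariant under a common integer shift of both inputs", {
  a <- static_speckle(32, seed = 13)
  b <- spline_shift_x(a, 0.4)
  params <- tracking_params(stride = 4L)
  f1 <- estimate_displacement(a, b, params)
  f2 <- estimate_displacement(circshift3(a, 4, 2), circshift3(b, 4, 2), params)
  interior <- array(FALSE, dim(a))
  interior[12:21, 12:21, 12:21] <- TRUE
  sel <- which(f1$estimated & interior)
  shifted <- which(circshift3(f1$estimated & interior, 4, 2))
  expect_equal(f2$vectors[, , , 1][shifted], f1$vectors[, , , 1][sel],
               tolerance = 1e-12)
})

test_that("forward and backward estimates are antisymmetric on smooth motion", {
  pd <- generate_phantom(small_phantom_spec(), seed = 6)
  a <- pd$volumes$data[[3]]
  b <- pd$volumes$data[[4]]
  roi <- prmstrain:::dilate_n(pd$rest_mask, 2)
  params <- tracking_params(stride = 2L)
  fab <- estimate_displacement(a, b, params, roi = roi)
  fba <- estimate_displacement(b, a, params, roi = roi)
  sel <- which(fab$estimated & fba$estimated & pd$rest_mask)
  for (c in 1:3) {
    diff <- fab$vectors[, , , c][sel] + fba$vectors[, , , c][sel]
    expect_lt(stats::median(abs(diff)), 0.5)
  }
})

test_that("quality filter replaces low-quality vectors by neighbourhood medians", {
  dims <- c(9L, 9L, 9L)
  vec <- array(0, c(dims, 3))
  vec[, , , 1] <- 2
  f <- as_field(vec)
  f$quality[] <- 1
  params <- tracking_params(min_quality = 0.5)
  # all high quality: identity
  expect_identical(quality_filter(f, params)$vectors, f$vectors)
  # single low-quality voxel amid uniform vectors: replaced by that vector
  f2 <- f
  f2$quality[5, 5, 5] <- 0.1
  f2$vectors[5, 5, 5, ] <- c(99, 99, 99)
  out <- quality_filter(f2, params)
  expect_equal(out$vectors[5, 5, 5, ], c(2, 0, 0))
  expect_true(out$interpolated[5, 5, 5])
  expect_equal(out$quality[5, 5, 5], 0.1)  # replacement never raises quality
  # mixed neighbours: component-wise median checked by explicit sort
  f3 <- f
  set.seed(31)
  f3$vectors[, , , 1] <- array(stats::rnorm(prod(dims)), dims)
  f3$quality[4, 4, 4] <- 0
  out3 <- quality_filter(f3, params)
  nb <- expand.grid(x = 2:6, y = 2:6, z = 2:6)
  nb <- nb[!(nb$x == 4 & nb$y == 4 & nb$z == 4), ]
  vals <- sort(f3$vectors[, , , 1][as.matrix(nb)])  # 124 neighbours: even count
  expect_equal(out3$vectors[4, 4, 4, 1], (vals[62] + vals[63]) / 2)
  # no valid neighbour anywhere: vector becomes undefined
  f4 <- f
  f4$quality[] <- 0.1
  out4 <- quality_filter(f4, params)
  expect_true(all(is.na(out4$vectors[, , , 1])))
})

test_that("field smoothing preserves affine fields and NA support", {
  dims <- c(16L, 16L, 16L)
  vec <- array(0, c(dims, 3))
  vec[, , , 1] <- outer(outer(seq_len(dims[1]), rep(1, dims[2])),
                        rep(1, dims[3]))  # linear in x
  f <- as_field(vec)
  sm <- smooth_field(f, 1.2)
  interior <- 5:12
  expect_equal(sm$vectors[interior, interior, interior, 1],
               vec[interior, interior, interior, 1], tolerance = 1e-2)
  # undefined voxels stay undefined
  f$vectors[3, 3, 3, ] <- NA
  sm2 <- smooth_field(f, 1.0)
  expect_true(is.na(sm2$vectors[3, 3, 3, 1]))
})
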