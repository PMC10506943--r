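# minimal arc map over an explicit voxel set
toy_map <- function(mask, s, tangent) {
  idx <- prmstrain:::mask_which(mask)
  d <- dim(mask)
  lin <- (idx[, 3] - 1) * d[1] * d[2] + (idx[, 2] - 1) * d[1] + idx[, 1]
  structure(list(idx = idx, lin = lin, s = s,
                 tangent = tangent, distance = numeric(length(s)),
                 dims = d, total_length = max(s)),
            class = "arc_coordinate_map")
}

test_that("LSQSE recovers exact linear fields and rejects degenerate windows", {
  dims <- c(10L, 4L, 4L)
  mask <- array(TRUE, dims)
  idx <- prmstrain:::mask_which(mask)
  s <- idx[, 1] * 1.0  # arc coordinate along x, 1 mm per voxel
  map <- toy_map(mask, s, matrix(rep(c(1, 0, 0), each = nrow(idx)), ncol = 3))
  # p = 0.02 * s  ->  2.0 % everywhere defined
  st <- lsq_strain(0.02 * s, map, mask)
  expect_equal(unique(round(st[!is.na(st)], 10)), 2)
  # constant p -> 0 %
  st0 <- lsq_strain(rep(1.7, nrow(idx)), map, mask)
  expect_true(all(abs(st0[!is.na(st0)]) < 1e-9))
  # a window whose arc coordinates are constant is undefined
  map2 <- toy_map(mask, rep(5, nrow(idx)),
                  matrix(rep(c(1, 0, 0), each = nrow(idx)), ncol = 3))
  st2 <- lsq_strain(stats::rnorm(nrow(idx)), map2, mask)
  expect_true(all(is.na(st2)))
  # fewer than 4 valid members is undefined: isolated corner voxel
  m3 <- array(FALSE, dims)
  m3[1, 1, 1] <- TRUE
  m3[1, 1, 2] <- TRUE
  map3 <- toy_map(m3, c(0, 1), matrix(c(1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE))
  st3 <- lsq_strain(c(0, 0.1), map3, m3)
  expect_true(all(is.na(st3)))
})

test_that("per-window slopes match closed-form normal equations", {
  # random 2x2x2 neighbourhoods; the full window sits at voxel (1,1,1)
  set.seed(77)
  dims <- c(2L, 2L, 2L)
  mask <- array(TRUE, dims)
  tang <- matrix(rep(c(1, 0, 0), each = 8), ncol = 3)
  for (rep in 1:200) {
    s <- stats::runif(8, 0, 5)
    p <- stats::rnorm(8)
    map <- toy_map(mask, s, tang)
    st <- lsq_strain(p, map, mask)
    X <- cbind(1, s)
    beta <- solve(t(X) %*% X, t(X) %*% p)
    expect_equal(st[1, 1, 1], 100 * beta[2], tolerance = 1e-10)
  }
})

test_that("LSQSE is invariant to displacement offsets and linear in scale", {
  set.seed(5)
  dims <- c(8L, 5L, 5L)
  mask <- array(TRUE, dims)
  idx <- prmstrain:::mask_which(mask)
  s <- idx[, 1] + 0.3 * idx[, 2]
  map <- toy_map(mask, s, matrix(rep(c(1, 0, 0), each = nrow(idx)), ncol = 3))
  p <- stats::rnorm(nrow(idx), sd = 0.3)
  base <- lsq_strain(p, map, mask)
  shifted <- lsq_strain(p + 4.2, map, mask)
  scaled <- lsq_strain(3 * p, map, mask)
  expect_equal(shifted, base, tolerance = 1e-9)
  expect_equal(scaled, 3 * base, tolerance = 1e-9)
})

test_that("window strain from vectors is exactly zero under rigid translation", {
  # curved geometry: per-voxel-tangent projection would register kappa*(u.n)
  mask <- half_torus_mask(40L, 13, 3)
  cl <- extract_centerline(mask, c(1, 1, 1))
  map <- build_arc_map(mask, cl, c(1, 1, 1))
  n <- nrow(map$idx)
  disp <- matrix(rep(c(2.5, -1.0, 0.7), each = n), ncol = 3)
  st <- prmstrain:::lsq_strain_vec(disp, map, mask)
  expect_true(all(abs(st[!is.na(st)]) < 1e-9))
  # whereas the scalar per-voxel projection does not vanish (the curvature
  # artifact the window form is designed to avoid)
  p <- project_displacements(disp, map)
  st_scalar <- lsq_strain(p, map, mask)
  expect_gt(stats::median(abs(st_scalar[!is.na(st_scalar)])), 0.5)
})

test_that("strain series on a static sequence is identically zero", {
  spec <- small_phantom_spec(n_frames = 3L,
                             contraction_ramp = c(0, 0, 0), noise_level = 0)
  pd <- generate_phantom(spec, seed = 10)
  ss <- compute_strain_series(pd$volumes, pd$rest_mask, tracking_params())
  for (t in 1:3) {
    v <- ss$strain[[t]]
    expect_true(all(v[!is.na(v)] == 0))
  }
  expect_equal(ss$mode, "terminal")
})

test_that("maximum-contraction selection follows the mid-region minimum", {
  dims <- c(6L, 6L, 6L)
  mask <- array(TRUE, dims)
  idx <- prmstrain:::mask_which(mask)
  s <- idx[, 1] * 1.0
  map <- toy_map(mask, s, matrix(rep(c(1, 0, 0), each = nrow(idx)), ncol = 3))
  part <- partition_regions(mask, map)
  mk <- function(v) array(v, dims)
  # ramp up then down: the most negative mid median wins
  series <- list(mk(0), mk(-2), mk(-7), mk(-4), mk(-1))
  expect_equal(select_max_contraction(series, part), 3L)
  # monotone ramp: last frame
  expect_equal(select_max_contraction(list(mk(0), mk(-1), mk(-3)), part), 3L)
  # single frame: frame 1
  expect_equal(select_max_contraction(list(mk(0)), part), 1L)
  # ties resolve to the earliest frame
  expect_equal(select_max_contraction(list(mk(-5), mk(-5), mk(0)), part), 1L)
  # override wins
  expect_equal(select_max_contraction(series, part, override = 2L), 2L)
  # all-undefined mid region is an error
  expect_error(select_max_contraction(list(mk(NA_real_)), part), "mid")
})
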