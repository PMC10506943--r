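test_that("a solid cylinder yields its axis and axial tangents", {
  mask <- cylinder_mask()
  cl <- extract_centerline(mask, c(1, 1, 1), degree = 3L)
  cy <- (dim(mask)[2] + 1 - 1) / 2  # 0-based mm coordinate of the axis
  cz <- (dim(mask)[3] + 1 - 1) / 2
  off_axis <- sqrt((cl$points[, 2] - cy)^2 + (cl$points[, 3] - cz)^2)
  expect_lt(max(off_axis), 1)
  ang <- acos(pmin(1, abs(cl$tangents[, 1]))) * 180 / pi
  expect_lt(max(ang), 5)
  # orientation: s = 0 at the smaller-x end by default, flipped on request
  expect_lt(cl$points[1, 1], cl$points[nrow(cl$points), 1])
  clf <- extract_centerline(mask, c(1, 1, 1), degree = 3L, flip = TRUE)
  expect_gt(clf$points[1, 1], clf$points[nrow(clf$points), 1])
})

test_that("a half-torus tube yields the analytic arc within tolerance", {
  n <- 56L
  R <- 20
  mask <- half_torus_mask(n, R, 4)
  cl <- extract_centerline(mask, c(1, 1, 1))
  ctr <- (n - 1) / 2
  # distance of fitted points to the analytic circle of radius R in the
  # central plane
  rho <- sqrt((cl$points[, 1] - ctr)^2 + (cl$points[, 2] - ctr)^2)
  arc_dist <- sqrt((rho - R)^2 + (cl$points[, 3] - ctr)^2)
  s <- cl$arc_length
  L <- max(s)
  inner <- s > 0.1 * L & s < 0.9 * L
  expect_lt(max(arc_dist[inner]), 1.5)
  # tangents against analytic arc tangents away from the ends
  th <- atan2(cl$points[, 2] - ctr, cl$points[, 1] - ctr)
  tan_true <- cbind(sin(th), -cos(th), 0)
  align <- abs(rowSums(cl$tangents * tan_true))
  expect_lt(max(acos(pmin(1, align[inner])) * 180 / pi), 10)
  # arc length invariants
  expect_true(all(diff(s) > 0))
  expect_equal(sqrt(rowSums(cl$tangents^2)), rep(1, nrow(cl$tangents)),
               tolerance = 1e-6)
})

test_that("a one-voxel straight segment is its own centerline", {
  dims <- c(40L, 9L, 9L)
  mask <- array(FALSE, dims)
  mask[5:35, 5, 5] <- TRUE
  cl <- extract_centerline(mask, c(1, 1, 1), degree = 2L)
  pts <- prmstrain:::vox_to_mm(prmstrain:::mask_which(mask), c(1, 1, 1))
  for (i in seq_len(nrow(pts))) {
    d <- sqrt(rowSums(sweep(cl$points, 2, pts[i, ])^2))
    expect_lt(min(d), 0.5)
  }
})

test_that("centerline extraction rejects bad masks", {
  expect_error(extract_centerline(array(FALSE, c(8, 8, 8)), c(1, 1, 1)),
               "empty")
  two <- array(FALSE, c(20, 8, 8))
  two[2:6, 4, 4] <- TRUE
  two[14:18, 4, 4] <- TRUE
  expect_error(extract_centerline(two, c(1, 1, 1)), "2 components")
  # largest-component fallback picks the bigger fragment
  two[2:8, 4, 4] <- TRUE
  cl <- extract_centerline(two, c(1, 1, 1), degree = 1L,
                           largest_component = TRUE)
  expect_lt(max(cl$points[, 1]), 9)
})

test_that("arc map assigns the nearest sample with the smaller-s tie rule", {
  mask <- cylinder_mask(c(30L, 9L, 9L), radius = 2, len = 24L)
  cl <- extract_centerline(mask, c(1, 1, 1), degree = 1L)
  map <- build_arc_map(mask, cl, c(1, 1, 1))
  # voxels on the centerline have (near) zero distance
  on_axis <- map$distance[map$idx[, 2] == 5 & map$idx[, 3] == 5]
  expect_lt(max(on_axis), 0.3)
  # brute-force nearest-neighbour oracle over every voxel
  pts <- prmstrain:::vox_to_mm(map$idx, c(1, 1, 1))
  for (i in sample(nrow(pts), 50)) {
    d <- sqrt(rowSums(sweep(cl$points, 2, pts[i, ])^2))
    j <- which(d <= min(d) + 1e-12)[1]  # smallest s among ties
    expect_equal(map$s[i], cl$arc_length[j])
    expect_equal(map$distance[i], unname(d[j]), tolerance = 1e-9)
  }
  expect_true(all(map$s >= 0 & map$s <= map$total_length))
})

test_that("projection is the tangent dot product and bounded by the vector norm", {
  mask <- cylinder_mask(c(30L, 9L, 9L), radius = 2, len = 24L)
  cl <- extract_centerline(mask, c(1, 1, 1), degree = 1L)
  map <- build_arc_map(mask, cl, c(1, 1, 1))
  n <- nrow(map$idx)
  # tangents are ~(1,0,0): parallel, orthogonal, and mixed vectors
  par <- matrix(rep(c(2.5, 0, 0), each = n), n, 3)
  expect_equal(project_displacements(par, map), rep(2.5, n), tolerance = 1e-4)
  orth <- matrix(rep(c(0, 1.3, -0.7), each = n), n, 3)
  expect_lt(max(abs(project_displacements(orth, map))), 0.05)
  mixed <- matrix(rep(c(1, 1, 0), each = n), n, 3)
  expect_equal(project_displacements(mixed, map), rep(1, n), tolerance = 0.05)
  # Cauchy-Schwarz bound holds exactly for random vectors
  set.seed(2)
  v <- matrix(stats::rnorm(3 * n), n, 3)
  expect_true(all(abs(project_displacements(v, map)) <=
                  sqrt(rowSums(v^2)) + 1e-12))
  # NA vectors propagate
  v[7, 1] <- NA
  expect_true(is.na(project_displacements(v, map)[7]))
})

test_that("reversing orientation negates projections and mirrors arc coordinates", {
  mask <- half_torus_mask(48L, 16, 3.5)
  cl <- extract_centerline(mask, c(1, 1, 1))
  clf <- extract_centerline(mask, c(1, 1, 1), flip = TRUE)
  map <- build_arc_map(mask, cl, c(1, 1, 1))
  mapf <- build_arc_map(mask, clf, c(1, 1, 1))
  set.seed(5)
  v <- matrix(stats::rnorm(3 * nrow(map$idx)), ncol = 3)
  p <- project_displacements(v, map)
  pf <- project_displacements(v, mapf)
  # tangents at matched voxels are opposite; allow resampling tolerance
  expect_lt(stats::median(abs(p + pf)), 0.05)
  expect_lt(stats::median(abs((map$total_length - map$s) - mapf$s)), 1)
})

test_that("phantom tangential motion is recovered by projection on the true centerline", {
  spec <- small_phantom_spec()
  pd <- generate_phantom(spec, seed = 3)
  map <- build_arc_map(pd$rest_mask, pd$true_centerline, spec$spacing)
  nf <- spec$n_frames
  u <- pd$true_displacement[[nf]]
  p <- project_displacements(u, map)
  ufun <- prmstrain:::displacement_profile_full(spec)
  # compare against the generator's scalar profile, scaled by the voxel's
  # own radius (points farther from the arc center sweep a longer chord)
  ctr <- (spec$grid_shape - 1) * spec$spacing / 2
  pts <- prmstrain:::vox_to_mm(map$idx, spec$spacing)
  rho <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  expected <- ufun(map$s) * rho / spec$arc_radius
  L <- max(pd$true_centerline$arc_length)
  w <- spec$taper_frac * L
  away <- abs(map$s - L / 6) > w & abs(map$s - 5 * L / 6) > w
  expect_lt(stats::median(abs(p - expected)[away]), 0.1)
})
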