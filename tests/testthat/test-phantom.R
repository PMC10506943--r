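test_that("phantom spec invariants are enforced with informative errors", {
  expect_error(phantom_spec(arc_span = 0), "arc_span")
  expect_error(phantom_spec(arc_span = 360), "arc_span")
  expect_error(phantom_spec(tube_radius = 30, arc_radius = 20), "tube_radius")
  expect_error(phantom_spec(n_frames = 1, contraction_ramp = 0), "n_frames")
  expect_error(phantom_spec(contraction_ramp = c(0.2, 1, 1, 1, 1, 1, 1, 1)),
               "start at 0")
  expect_error(phantom_spec(contraction_ramp = c(0, 1, 0.5, 1, 1, 1, 1, 1)),
               "non-decreasing")
  expect_error(phantom_spec(peak_mid_strain = 0.1), "peak_mid_strain")
  expect_error(phantom_spec(contraction_ramp = c(0, 1)), "length")
})

test_that("zero activation and zero noise give identical frames and zero truth", {
  spec <- phantom_spec(grid_shape = c(24L, 24L, 24L), arc_radius = 7,
                       tube_radius = 2, n_frames = 3L,
                       contraction_ramp = c(0, 0, 0), noise_level = 0)
  pd <- generate_phantom(spec, seed = 4)
  expect_identical(pd$volumes$data[[2]], pd$volumes$data[[1]])
  expect_identical(pd$volumes$data[[3]], pd$volumes$data[[1]])
  for (t in 1:3) {
    expect_true(all(pd$true_displacement[[t]] == 0))
    expect_true(all(pd$true_strain[[t]][pd$rest_mask] == 0))
  }
})

test_that("generation is bit-identical for the same spec and seed", {
  spec <- phantom_spec(grid_shape = c(24L, 24L, 24L), arc_radius = 7,
                       tube_radius = 2, n_frames = 3L)
  a <- generate_phantom(spec, seed = 9)
  b <- generate_phantom(spec, seed = 9)
  expect_identical(a, b)
  c <- generate_phantom(spec, seed = 10)
  expect_false(identical(a$volumes$data[[2]], c$volumes$data[[2]]))
})

test_that("analytic strain profile has the specified section values", {
  spec <- phantom_spec()
  L <- spec$arc_radius * spec$arc_span * pi / 180
  # mid-arc point at full activation: peak_mid_strain * 100
  expect_equal(analytic_strain_profile(spec, L / 2, spec$n_frames), -10)
  # end sections carry the balancing +20% (zero net end-to-end displacement
  # with the mid section spanning 2/3 of the arc)
  expect_equal(analytic_strain_profile(spec, 0.02 * L, spec$n_frames), 20)
  expect_equal(analytic_strain_profile(spec, 0.98 * L, spec$n_frames), 20)
  # frame 1 is rest
  expect_equal(analytic_strain_profile(spec, L / 2, 1L), 0)
  expect_error(analytic_strain_profile(spec, -1, 2L), "arc_position")
  expect_error(analytic_strain_profile(spec, L + 1, 2L), "arc_position")
})

test_that("taper values match numerical differentiation of the displacement integral", {
  spec <- phantom_spec()
  L <- spec$arc_radius * spec$arc_span * pi / 180
  ufun <- prmstrain:::displacement_profile_full(spec)
  h <- 1e-4
  # points across the first taper band and inside the mid section
  for (s in c(L / 6 - 0.02 * L, L / 6, L / 6 + 0.02 * L, 0.4 * L)) {
    fd <- 100 * (ufun(s + h) - ufun(s - h)) / (2 * h)
    # the displacement integral is tabulated on a dense grid; its finite
    # difference carries the grid quantization (~0.01 percentage points)
    expect_equal(analytic_strain_profile(spec, s, spec$n_frames), fd,
                 tolerance = 0.05)
  }
})

test_that("intact phantoms are anchored at both arc endpoints at every frame", {
  spec <- phantom_spec()
  L <- spec$arc_radius * spec$arc_span * pi / 180
  ufun <- prmstrain:::displacement_profile_full(spec)
  for (act in spec$contraction_ramp) {
    expect_lt(abs(act * ufun(0)), 0.05)
    expect_lt(abs(act * ufun(L)), 0.05)
  }
  # avulsed phantoms are anchored only at the intact end
  spec_av <- phantom_spec(condition = "avulsed_right")
  ufun_av <- prmstrain:::displacement_profile_full(spec_av)
  expect_lt(abs(ufun_av(L)), 0.05)
  expect_gt(abs(ufun_av(0)), 1)
})

test_that("finite differences of true displacement along the centerline match the profile", {
  spec <- small_phantom_spec()
  pd <- generate_phantom(spec, seed = 3)
  cl <- pd$true_centerline
  L <- max(cl$arc_length)
  # tangential displacement of centerline points at full activation
  u <- prmstrain:::phantom_displacement(spec, cl$points, 1)
  p <- rowSums(u * cl$tangents)
  s <- cl$arc_length
  fd <- 100 * diff(p) / diff(s)
  smid <- (s[-1] + s[-length(s)]) / 2
  truth <- vapply(smid, function(x) analytic_strain_profile(spec, x, spec$n_frames),
                  numeric(1))
  w <- spec$taper_frac * L
  away <- abs(smid - L / 6) > w & abs(smid - 5 * L / 6) > w &
          smid > 0.02 * L & smid < 0.98 * L
  expect_lt(max(abs(fd[away] - truth[away])), 0.5)
})

test_that("monotone activation gives non-decreasing per-voxel displacement magnitude", {
  spec <- phantom_spec(grid_shape = c(32L, 32L, 32L), arc_radius = 9,
                       tube_radius = 2.5, n_frames = 4L)
  pd <- generate_phantom(spec, seed = 5)
  mag <- sapply(pd$true_displacement, function(d)
    sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)[pd$rest_mask])
  for (t in 2:4) expect_true(all(mag[, t] >= mag[, t - 1] - 1e-12))
})

test_that("cohort ratio generator matches its calibration", {
  cs <- cohort_spec(seed = 21)
  r1 <- generate_cohort_ratios(cs)
  r2 <- generate_cohort_ratios(cs)
  expect_identical(r1, r2)
  expect_length(r1$a, 8)
  expect_length(r1$b, 10)
  # degenerate spread collapses onto the medians
  r0 <- generate_cohort_ratios(cohort_spec(ratio_log_sd = c(0, 0), seed = 3))
  expect_true(all(r0$a == 0.36))
  expect_true(all(r0$b == 1.54))
  # large-sample medians within 5% of the calibrated values
  rl <- generate_cohort_ratios(cohort_spec(n_per_group = c(10000L, 10000L),
                                           seed = 7))
  expect_lt(abs(stats::median(rl$a) - 0.36) / 0.36, 0.05)
  expect_lt(abs(stats::median(rl$b) - 1.54) / 1.54, 0.05)
  expect_error(cohort_spec(n_per_group = c(1L, 5L)), "n_per_group")
  expect_error(cohort_spec(ratio_median = c(-1, 1)), "median")
})
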