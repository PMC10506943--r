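#' Specify a synthetic puborectal-muscle speckle phantom
#'
#' Describes a sling-shaped (C-shaped) muscle band embedded in a 3D speckle
#' volume, imaged over a rest-to-contraction cycle. The band is a circular
#' arc in the central axial plane, extruded as a tube; its tangential
#' contraction profile is analytic, so every phantom carries exact per-voxel
#' ground-truth displacement and strain.
#'
#' The arc-length coordinate `s` runs from the end with the smaller
#' x-coordinate (`s = 0`, labelled *right*, following the ultrasound display
#' convention that places the patient's right on the image left) to the end
#' with the larger x-coordinate (*left*). The band is divided into a right
#' end section (first 1/6 of arc length), a mid section (2/3), and a left
#' end section (last 1/6), with cosine-tapered transitions. At full
#' activation the mid section carries `peak_mid_strain`; for an intact
#' muscle both end sections carry the balancing positive strain
#' `-2 * peak_mid_strain` (forced by zero net end-to-end displacement, both
#' ends being anchored to bone), while an avulsed end carries
#' `peak_mid_strain` itself (it contracts with the sling, having lost its
#' bony anchor) and only the intact end is anchored.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param spacing mm per voxel, length-3.
#' @param n_frames number of volumes (>= 2); frame 1 is rest.
#' @param frame_interval seconds between volumes (default 1/1.5, a volume
#'   rate of 1.5 Hz).
#' @param arc_radius radius of the centerline arc, mm.
#' @param arc_span angular extent of the arc in degrees, in (0, 360).
#' @param tube_radius radius of the band tube, mm (must be < `arc_radius`).
#' @param scatterer_density scatterers per mm^3.
#' @param psf_sigma Gaussian point-spread-function sigma, mm, length-3.
#' @param noise_level additive noise standard deviation as a fraction of the
#'   mean envelope intensity.
#' @param condition `"intact"`, `"avulsed_left"` or `"avulsed_right"`.
#' @param peak_mid_strain dimensionless strain of the mid section at full
#'   activation; must be negative (contraction).
#' @param contraction_ramp per-frame activation fractions in `[0, 1]`,
#'   non-decreasing, starting at 0. Default: linear ramp 0 to 1.
#' @param taper_frac width of each cosine transition as a fraction of total
#'   arc length.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = c(1, 1, 1),
                         n_frames = 8L,
                         frame_interval = 1 / 1.5,
                         arc_radius = 20,
                         arc_span = 180,
                         tube_radius = 4,
                         scatterer_density = 1.5,
                         psf_sigma = c(1, 1, 1),
                         noise_level = 0.1,
                         condition = c("intact", "avulsed_left", "avulsed_right"),
                         peak_mid_strain = -0.10,
                         contraction_ramp = NULL,
                         taper_frac = 0.1) {
  condition <- match.arg(condition)
  if (is.null(contraction_ramp))
    contraction_ramp <- seq(0, 1, length.out = n_frames)
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         n_frames = as.integer(n_frames), frame_interval = frame_interval,
         arc_radius = arc_radius, arc_span = arc_span,
         tube_radius = tube_radius, scatterer_density = scatterer_density,
         psf_sigma = as.numeric(psf_sigma), noise_level = noise_level,
         condition = condition, peak_mid_strain = peak_mid_strain,
         contraction_ramp = as.numeric(contraction_ramp),
         taper_frac = taper_frac),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 8))
    stop("phantom spec invariant violated: grid_shape must be a triple >= 8")
  if (any(spec$spacing <= 0))
    stop("phantom spec invariant violated: spacing must be strictly positive")
  if (spec$n_frames < 2)
    stop("phantom spec invariant violated: n_frames >= 2")
  if (!(spec$arc_span > 0 && spec$arc_span < 360))
    stop("phantom spec invariant violated: arc_span in (0, 360) degrees")
  if (!(spec$tube_radius < spec$arc_radius))
    stop("phantom spec invariant violated: tube_radius < arc_radius")
  if (length(spec$contraction_ramp) != spec$n_frames)
    stop("phantom spec invariant violated: contraction_ramp length must equal n_frames")
  if (abs(spec$contraction_ramp[1]) > 0)
    stop("phantom spec invariant violated: contraction_ramp must start at 0")
  if (any(diff(spec$contraction_ramp) < 0))
    stop("phantom spec invariant violated: contraction_ramp must be non-decreasing")
  if (any(spec$contraction_ramp < 0 | spec$contraction_ramp > 1))
    stop("phantom spec invariant violated: contraction_ramp in [0, 1]")
  if (!(spec$peak_mid_strain < 0))
    stop("phantom spec invariant violated: peak_mid_strain < 0")
  if (spec$noise_level < 0)
    stop("phantom spec invariant violated: noise_level >= 0")
  invisible(spec)
}

# total arc length in mm
arc_length_mm <- function(spec) spec$arc_radius * spec$arc_span * pi / 180

# section strain levels (right, mid, left) at full activation, dimensionless
strain_levels <- function(spec) {
  em <- spec$peak_mid_strain
  ee <- -2 * em
  switch(spec$condition,
         intact        = c(right = ee, mid = em, left = ee),
         avulsed_right = c(right = em, mid = em, left = ee),
         avulsed_left  = c(right = ee, mid = em, left = em))
}

# dimensionless strain at arc position s (mm) at full activation;
# cosine-tapered piecewise-constant profile. Vectorized over s.
strain_profile_full <- function(spec, s) {
  L <- arc_length_mm(spec)
  lv <- strain_levels(spec)
  w <- spec$taper_frac * L
  b1 <- L / 6
  b2 <- 5 * L / 6
  taper <- function(x) 0.5 - 0.5 * cos(pi * pmin(pmax(x, 0), 1))
  e <- numeric(length(s))
  t1 <- taper((s - (b1 - w / 2)) / w)   # 0 on right section, 1 in mid
  t2 <- taper((s - (b2 - w / 2)) / w)   # 0 in mid, 1 on left section
  lv[["right"]] + (lv[["mid"]] - lv[["right"]]) * t1 +
    (lv[["left"]] - lv[["mid"]]) * t2
}

#' Analytic tangential strain of the phantom
#'
#' Ground-truth strain (percent) along the band's fiber direction at arc
#' position `arc_position` (mm from the right end) at the given frame.
#'
#' @param spec a [phantom_spec()].
#' @param arc_position arc-length coordinate in mm, within `[0, L]`.
#' @param frame 1-based frame index (frame 1 is rest, strain 0).
#' @return strain in percent (negative = shortening).
#' @export
analytic_strain_profile <- function(spec, arc_position, frame) {
  validate_phantom_spec(spec)
  L <- arc_length_mm(spec)
  if (any(arc_position < 0 | arc_position > L))
    stop("arc_position outside [0, ", round(L, 3), "] mm")
  if (frame < 1 || frame > spec$n_frames) stop("frame out of range")
  act <- spec$contraction_ramp[frame]
  100 * act * strain_profile_full(spec, arc_position)
}

# cumulative tangential displacement (mm) at full activation, anchored per
# condition; returns a function u(s). Dense trapezoidal integration of the
# analytic profile (the taper keeps it smooth).
displacement_profile_full <- function(spec, n_grid = 4096) {
  L <- arc_length_mm(spec)
  sg <- seq(0, L, length.out = n_grid)
  eg <- strain_profile_full(spec, sg)
  cum <- c(0, cumsum((eg[-1] + eg[-n_grid]) / 2 * diff(sg)))
  anchor_end <- switch(spec$condition,
                       intact = 0, avulsed_left = 0, avulsed_right = L)
  # u(s) = integral from the anchored end; intact integrates to ~0 at s = L
  offset <- stats::approx(sg, cum, xout = anchor_end)$y
  ufun <- stats::approxfun(sg, cum - offset, rule = 2)
  ufun
}

# map points (n x 3, mm) to band coordinates relative to the arc:
# s (arc coordinate, clamped), d (distance to the clamped arc point),
# plus the cylindrical pieces used to rotate points tangentially.
band_coords <- function(spec, pts) {
  ctr <- (spec$grid_shape - 1) * spec$spacing / 2
  dx <- pts[, 1] - ctr[1]
  dy <- pts[, 2] - ctr[2]
  dz <- pts[, 3] - ctr[3]
  rho <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  th[th < 0] <- th[th < 0] + 2 * pi
  span <- spec$arc_span * pi / 180
  # clamp the angle into the arc's angular interval [0, span]
  outside <- th > span
  thc <- th
  thc[outside] <- ifelse(th[outside] - span < 2 * pi - th[outside], span, 0)
  # s = 0 at theta = span (the smaller-x end for span in (0, 360))
  s <- spec$arc_radius * (span - thc)
  px <- ctr[1] + spec$arc_radius * cos(thc)
  py <- ctr[2] + spec$arc_radius * sin(thc)
  d <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2 + dz^2)
  list(s = s, d = d, dx = dx, dy = dy, rho = rho, theta = th, ctr = ctr,
       span = span)
}

# smooth motion weight: 1 inside the tube, cosine decay to 0 over one extra
# tube radius, 0 beyond (keeps the motion field continuous)
motion_weight <- function(d, tube_radius) {
  w <- numeric(length(d))
  w[d <= tube_radius] <- 1
  tr <- d > tube_radius & d < 2 * tube_radius
  w[tr] <- 0.5 + 0.5 * cos(pi * (d[tr] - tube_radius) / tube_radius)
  w
}

# displacement (mm, n x 3) of material points `pts` at activation `act`;
# `bc` (precomputed band coordinates) avoids recomputation across frames
phantom_displacement <- function(spec, pts, act, ufun = NULL, bc = NULL) {
  if (is.null(ufun)) ufun <- displacement_profile_full(spec)
  if (is.null(bc)) bc <- band_coords(spec, pts)
  w <- motion_weight(bc$d, spec$tube_radius)
  u <- act * w * ufun(bc$s)
  # positive u moves toward increasing s, i.e. decreasing theta
  dth <- -u / spec$arc_radius
  cs <- cos(dth); sn <- sin(dth)
  nx <- bc$dx * cs - bc$dy * sn
  ny <- bc$dx * sn + bc$dy * cs
  cbind(nx - bc$dx, ny - bc$dy, 0)
}

# trilinear splat of point amplitudes onto the voxel grid
splat_points <- function(pts_vox, amp, dims) {
  n <- prod(dims)
  acc <- numeric(n)
  x0 <- floor(pts_vox[, 1]); y0 <- floor(pts_vox[, 2]); z0 <- floor(pts_vox[, 3])
  fx <- pts_vox[, 1] - x0; fy <- pts_vox[, 2] - y0; fz <- pts_vox[, 3] - z0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    xi <- x0 + cx; yi <- y0 + cy; zi <- z0 + cz
    wgt <- (if (cx) fx else 1 - fx) * (if (cy) fy else 1 - fy) *
           (if (cz) fz else 1 - fz)
    ok <- xi >= 0 & xi < dims[1] & yi >= 0 & yi < dims[2] &
          zi >= 0 & zi < dims[3] & wgt > 0
    if (!any(ok)) next
    lin <- zi[ok] * dims[1] * dims[2] + yi[ok] * dims[1] + xi[ok] + 1
    rs <- rowsum(amp[ok] * wgt[ok], lin)
    idx <- as.integer(rownames(rs))
    acc[idx] <- acc[idx] + rs[, 1]
  }
  array(acc, dims)
}

#' Generate a synthetic speckle phantom with known ground truth
#'
#' Places random scatterers in the volume, moves the ones near the muscle
#' band with the analytic tangential contraction field, and renders each
#' frame as the absolute value of the PSF-blurred scatterer sum plus
#' additive noise. Fully deterministic given `(spec, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for scatterer placement, amplitudes and noise.
#' @return An object of class `phantom_dataset`: a list with
#'   * `volumes`: a [volume_sequence()] of rendered frames,
#'   * `rest_mask`: logical 3D band mask at frame 1,
#'   * `true_displacement`: list per frame of `[nx, ny, nz, 3]` arrays, the
#'     cumulative mm displacement of each rest-grid material point,
#'   * `true_strain`: list per frame of 3D arrays, percent tangential strain
#'     inside the band (`NA` outside),
#'   * `true_centerline`: the analytic arc (points, tangents, arc length),
#'   * `spec`, `seed`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  dims <- spec$grid_shape
  sp <- spec$spacing
  ext <- (dims - 1) * sp
  ufun <- displacement_profile_full(spec)

  with_seed(seed, {
    n_scat <- max(100L, round(spec$scatterer_density * prod(ext)))
    scat <- cbind(stats::runif(n_scat, 0, ext[1]),
                  stats::runif(n_scat, 0, ext[2]),
                  stats::runif(n_scat, 0, ext[3]))
    amp <- stats::rnorm(n_scat)

    # voxel-grid geometry (rest positions)
    idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                 z = seq_len(dims[3])))
    vpts <- vox_to_mm(idx, sp)
    vb <- band_coords(spec, vpts)
    rest_mask <- array(vb$d <= spec$tube_radius, dims)
    strain_full <- strain_profile_full(spec, vb$s)
    vmoving <- motion_weight(vb$d, spec$tube_radius) > 0
    vb_mov <- lapply(vb[c("s", "d", "dx", "dy")], `[`, vmoving)

    # scatterers outside the motion falloff are static: splat them once
    sb <- band_coords(spec, scat)
    smoving <- motion_weight(sb$d, spec$tube_radius) > 0
    sb_mov <- lapply(sb[c("s", "d", "dx", "dy")], `[`, smoving)
    base <- splat_points(sweep(scat[!smoving, , drop = FALSE], 2, sp, `/`),
                         amp[!smoving], dims)

    frames <- vector("list", spec$n_frames)
    true_disp <- vector("list", spec$n_frames)
    true_strain <- vector("list", spec$n_frames)
    sigma_vox <- spec$psf_sigma / sp

    for (t in seq_len(spec$n_frames)) {
      act <- spec$contraction_ramp[t]
      smov <- scat[smoving, , drop = FALSE]
      if (act > 0)
        smov <- smov + phantom_displacement(spec, smov, act, ufun, bc = sb_mov)
      img <- base + splat_points(sweep(smov, 2, sp, `/`), amp[smoving], dims)
      img <- abs(gauss_blur_fft(img, sigma_vox))
      if (spec$noise_level > 0) {
        noise <- array(stats::rnorm(prod(dims)), dims)
        img <- pmax(img + spec$noise_level * mean(img) * noise, 0)
      }
      frames[[t]] <- img

      dv <- matrix(0, nrow(vpts), 3)
      if (act > 0)
        dv[vmoving, ] <- phantom_displacement(
          spec, vpts[vmoving, , drop = FALSE], act, ufun, bc = vb_mov)
      true_disp[[t]] <- array(dv, c(dims, 3))
      st <- array(NA_real_, dims)
      st[rest_mask] <- 100 * act * strain_full[rest_mask]
      true_strain[[t]] <- st
    }

    # analytic centerline: s = 0 at theta = span (smaller-x end, "right")
    L <- arc_length_mm(spec)
    ns <- max(200L, ceiling(L / (0.25 * min(sp))))
    sgrid <- seq(0, L, length.out = ns)
    span <- spec$arc_span * pi / 180
    th <- span - sgrid / spec$arc_radius
    ctr <- (dims - 1) * sp / 2
    pts <- cbind(ctr[1] + spec$arc_radius * cos(th),
                 ctr[2] + spec$arc_radius * sin(th),
                 ctr[3])
    tans <- cbind(sin(th), -cos(th), 0)
    truth_cl <- structure(list(points = pts, tangents = tans,
                               arc_length = sgrid, poly_degree = NA_integer_),
                          class = "prm_centerline")

    structure(list(
      volumes = volume_sequence(frames, spacing = sp,
                                frame_interval = spec$frame_interval),
      rest_mask = rest_mask,
      true_displacement = true_disp,
      true_strain = true_strain,
      true_centerline = truth_cl,
      spec = spec, seed = as.integer(seed)), class = "phantom_dataset")
  })
}

#' Specify a synthetic cohort of normalized strain ratios
#'
#' Log-normal ratio samples for two groups (intact, unilateral avulsion),
#' calibrated by group medians. Defaults reproduce the study conditions:
#' group sizes 8 and 10 with ratio medians 0.36 and 1.54.
#'
#' @param n_per_group integer pair `(n_intact, n_avulsed)`.
#' @param ratio_median positive pair of group medians.
#' @param ratio_log_sd positive pair of log-scale standard deviations.
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_per_group = c(8L, 10L),
                        ratio_median = c(0.36, 1.54),
                        ratio_log_sd = c(0.8, 0.8),
                        seed = 1L) {
  if (any(n_per_group < 2)) stop("cohort spec: n_per_group >= 2 each")
  if (any(ratio_median <= 0)) stop("cohort spec: medians must be > 0")
  if (any(ratio_log_sd < 0)) stop("cohort spec: ratio_log_sd must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 ratio_median = ratio_median, ratio_log_sd = ratio_log_sd,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Draw cohort ratio samples
#'
#' @param cspec a [cohort_spec()].
#' @return list with positive numeric vectors `a` (intact) and `b` (avulsed).
#' @export
generate_cohort_ratios <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  with_seed(cspec$seed, {
    a <- stats::rlnorm(cspec$n_per_group[1], meanlog = log(cspec$ratio_median[1]),
                       sdlog = cspec$ratio_log_sd[1])
    b <- stats::rlnorm(cspec$n_per_group[2], meanlog = log(cspec$ratio_median[2]),
                       sdlog = cspec$ratio_log_sd[2])
    list(a = a, b = b)
  })
}
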