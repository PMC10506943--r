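# Shared fixtures, built in code. Small phantoms keep unit tests fast; the
# full-size study conditions are exercised in test-acceptance.R.

small_phantom_spec <- function(n_frames = 4L, ...) {
  phantom_spec(grid_shape = c(48L, 48L, 48L), arc_radius = 14, tube_radius = 3.5,
               n_frames = n_frames, ...)
}

# static speckle volume (no motion, light noise) for tracking fixtures
static_speckle <- function(n = 32L, seed = 11L, noise = 0.05) {
  spec <- phantom_spec(grid_shape = rep(n, 3L), arc_radius = n / 3.2,
                       tube_radius = n / 10, n_frames = 2L,
                       contraction_ramp = c(0, 0), noise_level = noise)
  generate_phantom(spec, seed = seed)$volumes$data[[1]]
}

# circular shift of a 3D array along axis 1..3 by k voxels
circshift3 <- function(a, k, axis = 1L) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  n <- d[axis]
  k <- ((k %% n) + n) %% n
  idx[[axis]] <- c((n - k + 1):n, seq_len(n - k))[seq_len(n)]
  if (k == 0) return(a)
  do.call(`[`, c(list(a), idx))
}

# subvoxel shift along the first axis via natural cubic splines (independent
# of the tracker's interpolation model)
spline_shift_x <- function(a, dx) {
  d <- dim(a)
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2]))
    out[, y, z] <- stats::spline(seq_len(d[1]), a[, y, z],
                                 xout = seq_len(d[1]) - dx,
                                 method = "natural")$y
  out
}

# wrap a full-grid [dims, 3] mm vector array as a displacement_field
as_field <- function(vec, spacing = c(1, 1, 1), quality = NULL) {
  d <- dim(vec)[1:3]
  if (is.null(quality)) {
    quality <- array(NA_real_, d)
    quality[!is.na(vec[, , , 1])] <- 1
  }
  structure(list(vectors = vec, quality = quality,
                 estimated = !is.na(vec[, , , 1]),
                 interpolated = array(FALSE, d),
                 spacing = spacing, stride = 1L, frame_pair = c(1L, 2L)),
            class = "displacement_field")
}

# uniform-translation field (mm) over the whole grid
uniform_field <- function(dims, u_mm, spacing = c(1, 1, 1)) {
  vec <- array(0, c(dims, 3))
  for (c in 1:3) vec[, , , c] <- u_mm[c]
  as_field(vec, spacing)
}

# solid axis-aligned cylinder mask along x
cylinder_mask <- function(dims = c(48L, 20L, 20L), radius = 4, len = 40L) {
  m <- array(FALSE, dims)
  cy <- (dims[2] + 1) / 2
  cz <- (dims[3] + 1) / 2
  x0 <- (dims[1] - len) %/% 2 + 1
  for (y in seq_len(dims[2])) for (z in seq_len(dims[3]))
    if ((y - cy)^2 + (z - cz)^2 <= radius^2)
      m[x0:(x0 + len - 1), y, z] <- TRUE
  m
}

# half-torus tube mask in the central z plane
half_torus_mask <- function(n = 56L, R = 20, r = 4) {
  idx <- as.matrix(expand.grid(x = 1:n, y = 1:n, z = 1:n))
  ctr <- (n + 1) / 2
  dx <- idx[, 1] - ctr
  dy <- idx[, 2] - ctr
  dz <- idx[, 3] - ctr
  rho <- sqrt(dx^2 + dy^2)
  inside <- dy >= 0 & sqrt((rho - R)^2 + dz^2) <= r
  # end caps
  inside <- inside | (sqrt((dx - R)^2 + dy^2 + dz^2) <= r & dy < 0) |
                     (sqrt((dx + R)^2 + dy^2 + dz^2) <= r & dy < 0)
  array(inside, rep(n, 3L))
}
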