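#' Construct a 3D+t volume sequence
#'
#' @param frames list of 3D arrays (equal dims) or a 4D array with frames in
#'   the fourth dimension; intensities must be non-negative.
#' @param spacing voxel spacing in mm, length-3, strictly positive.
#' @param frame_interval seconds between frames.
#' @return Object of class `volume_sequence` with elements `data` (list of
#'   3D arrays), `spacing`, `frame_interval`.
#' @export
volume_sequence <- function(frames, spacing, frame_interval = 1 / 1.5) {
  if (is.array(frames) && length(dim(frames)) == 4)
    frames <- lapply(seq_len(dim(frames)[4]), function(t) frames[, , , t])
  if (!is.list(frames) || length(frames) < 2)
    stop("volume_sequence requires at least 2 frames")
  d <- dim(frames[[1]])
  if (length(d) != 3) stop("frames must be 3D arrays")
  for (f in frames) if (!identical(dim(f), d)) stop("frames must share one grid")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be a strictly positive mm triple")
  structure(list(data = frames, spacing = as.numeric(spacing),
                 frame_interval = frame_interval),
            class = "volume_sequence")
}

#' @export
print.volume_sequence <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("volume_sequence: %d frames of %dx%dx%d voxels, spacing %s mm, dt %.3f s\n",
              length(x$data), d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = "x"), x$frame_interval))
  invisible(x)
}

n_frames <- function(vs) length(vs$data)

#' Block-matching parameters for speckle tracking
#'
#' @param block_size odd voxel triple, the matching block extent (>= 3).
#' @param search_radius voxel triple, maximum displacement searched per axis.
#' @param subvoxel logical, parabolic subvoxel refinement of the
#'   correlation peak.
#' @param min_quality correlation below which a vector is replaced by
#'   [quality_filter()].
#' @param median_filter_radius neighbourhood radius (in estimation-grid
#'   steps) used when replacing low-quality vectors.
#' @param stride estimation grid stride in voxels (1 = every voxel).
#' @param smooth_sigma Gaussian regularization of the estimated field
#'   (voxels, per component, NA-aware); 0 disables. Damps the voxel-scale
#'   estimation noise that would otherwise dominate local strain gradients.
#' @param refine_passes number of motion-compensated refinement passes: the
#'   moving volume is warped back by the current field and the residual
#'   displacement re-estimated with a small search, reducing the
#'   deformation-induced bias of a single correlation pass.
#' @export
tracking_params <- function(block_size = c(5L, 5L, 5L),
                            search_radius = c(5L, 5L, 5L),
                            subvoxel = TRUE,
                            min_quality = 0.5,
                            median_filter_radius = 2L,
                            stride = 1L,
                            smooth_sigma = 1.2,
                            refine_passes = 2L) {
  block_size <- as.integer(rep_len(block_size, 3))
  search_radius <- as.integer(rep_len(search_radius, 3))
  if (any(block_size < 3)) stop("tracking params: block_size >= 3 per axis")
  if (any(block_size %% 2 == 0)) stop("tracking params: block_size must be odd")
  if (any(search_radius < 1)) stop("tracking params: search_radius >= 1")
  if (smooth_sigma < 0) stop("tracking params: smooth_sigma >= 0")
  if (refine_passes < 0) stop("tracking params: refine_passes >= 0")
  structure(list(block_size = block_size, search_radius = search_radius,
                 subvoxel = isTRUE(subvoxel), min_quality = min_quality,
                 median_filter_radius = as.integer(median_filter_radius),
                 stride = as.integer(stride), smooth_sigma = smooth_sigma,
                 refine_passes = as.integer(refine_passes)),
            class = "tracking_params")
}

#' Estimate the dense inter-volume displacement field
#'
#' Block matching by normalized cross-correlation: for every block center
#' the displacement maximizing the NCC within the search window is kept
#' (ties resolved toward the smaller shift), optionally refined to subvoxel
#' precision by a separable parabolic fit around the integer peak. Blocks
#' are truncated at the volume border; centers whose block falls more than
#' 50% outside are undefined.
#'
#' @param vol_a,vol_b 3D arrays on the same grid (frame t and t+1).
#' @param params a [tracking_params()].
#' @param spacing voxel spacing in mm (displacements are returned in mm).
#' @param roi optional logical 3D array: estimate only at `TRUE` voxels.
#' @param support optional logical 3D array (e.g. the current muscle
#'   segmentation): block statistics are restricted to `TRUE` voxels of the
#'   reference frame, so blocks straddling the segmentation boundary are
#'   not contaminated by differently-moving surrounding texture.
#' @param frame_pair integer pair recorded as provenance.
#' @return Object of class `displacement_field`: full-grid arrays
#'   `vectors` (`[nx, ny, nz, 3]`, mm, `NA` where not estimated), `quality`
#'   (peak correlation in `[-1, 1]`), logical `estimated` (grid centers),
#'   `interpolated` (filled by [quality_filter()]), plus `spacing`,
#'   `stride` and `frame_pair`.
#' @export
estimate_displacement <- function(vol_a, vol_b, params = tracking_params(),
                                  spacing = c(1, 1, 1), roi = NULL,
                                  support = NULL, frame_pair = c(1L, 2L)) {
  if (!identical(dim(vol_a), dim(vol_b)))
    stop("input error: volumes must share shape")
  d <- dim(vol_a)
  if (length(d) != 3) stop("input error: volumes must be 3D")
  if (any(params$block_size > d))
    stop("specification error: block larger than volume")
  stride <- params$stride
  grid <- lapply(d, function(n) seq(1L, n, by = stride))
  centers <- array(FALSE, d)
  centers[grid[[1]], grid[[2]], grid[[3]]] <- TRUE
  if (!is.null(roi)) {
    if (!identical(dim(roi), d)) stop("input error: roi grid mismatch")
    centers <- centers & roi
  }
  lin0 <- which(centers) - 1L  # 0-based linear indices for C++
  if (!is.null(support)) {
    if (!identical(dim(support), d)) stop("input error: support grid mismatch")
    support <- as.double(support)
  }
  res <- .ncc_track_cpp(as.double(vol_a), as.double(vol_b), as.integer(d),
                        (params$block_size - 1L) %/% 2L,
                        params$search_radius, as.integer(lin0),
                        params$subvoxel, support)
  vec <- array(NA_real_, c(d, 3))
  qual <- array(NA_real_, d)
  ci <- which(centers)
  npl <- prod(d)
  vec[ci] <- res$dx * spacing[1]
  vec[ci + npl] <- res$dy * spacing[2]
  vec[ci + 2 * npl] <- res$dz * spacing[3]
  qual[ci] <- res$quality
  centers[ci[is.na(res$quality)]] <- FALSE  # undefined (e.g. border) centers
  structure(list(vectors = vec, quality = qual, estimated = centers,
                 interpolated = array(FALSE, d), spacing = as.numeric(spacing),
                 stride = stride, frame_pair = as.integer(frame_pair)),
            class = "displacement_field")
}

#' Replace low-quality displacement vectors
#'
#' Vectors with correlation below `params$min_quality` are replaced by the
#' component-wise median of the valid (high-quality, non-replaced) vectors
#' within `median_filter_radius` estimation-grid steps; replaced vectors are
#' flagged `interpolated` and keep their (low) quality score. A vector with
#' no valid neighbour becomes undefined.
#'
#' @param field a [estimate_displacement()] result.
#' @param params a [tracking_params()].
#' @return The filtered `displacement_field`.
#' @export
quality_filter <- function(field, params = tracking_params()) {
  stopifnot(inherits(field, "displacement_field"))
  d <- dim(field$quality)
  est <- which(field$estimated & !is.na(field$quality))
  bad <- est[field$quality[est] < params$min_quality]
  if (!length(bad)) return(field)
  good <- est[field$quality[est] >= params$min_quality]
  npl <- prod(d)
  out <- field
  if (!length(good)) {
    out$vectors[c(bad, bad + npl, bad + 2 * npl)] <- NA_real_
    out$estimated[bad] <- FALSE
    return(out)
  }
  gidx <- arrayInd(good, d)
  bidx <- arrayInd(bad, d)
  r <- params$median_filter_radius * field$stride
  for (i in seq_along(bad)) {
    db <- abs(sweep(gidx, 2, bidx[i, ], `-`))
    nb <- good[db[, 1] <= r & db[, 2] <= r & db[, 3] <= r]
    if (length(nb)) {
      out$vectors[bad[i]] <- stats::median(field$vectors[nb])
      out$vectors[bad[i] + npl] <- stats::median(field$vectors[nb + npl])
      out$vectors[bad[i] + 2 * npl] <- stats::median(field$vectors[nb + 2 * npl])
      out$interpolated[bad[i]] <- TRUE
    } else {
      out$vectors[c(bad[i], bad[i] + npl, bad[i] + 2 * npl)] <- NA_real_
      out$estimated[bad[i]] <- FALSE
    }
  }
  out
}

# warp a scalar volume backward by a displacement field (voxel units):
# out(x) = vol(x + u(x)); undefined u treated as zero
warp_volume_back <- function(vol, field) {
  d <- dim(vol)
  idx <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3]))) - 1
  u <- cbind(as.vector(field$vectors[, , , 1]),
             as.vector(field$vectors[, , , 2]),
             as.vector(field$vectors[, , , 3]))
  u[is.na(u)] <- 0
  pts <- idx + sweep(u, 2, field$spacing, `/`)
  w <- .trilinear3_cpp(vol, vol, vol, as.integer(d), pts)[, 1]
  bad <- is.na(w)
  w[bad] <- vol[bad]
  array(w, d)
}

#' Motion-compensated refinement of a displacement field
#'
#' Warps `vol_b` backward by the current field estimate and re-estimates
#' the residual displacement on the compensated pair with a small search
#' window; the returned field is the sum. Because the compensated pair is
#' nearly motion-free, the deformation-induced bias of the correlation
#' peak largely cancels.
#'
#' @param vol_a,vol_b the original frame pair.
#' @param field the current `displacement_field` estimate.
#' @param params a [tracking_params()].
#' @param roi,support as in [estimate_displacement()].
#' @return the refined `displacement_field`.
#' @export
refine_displacement <- function(vol_a, vol_b, field, params,
                                roi = NULL, support = NULL) {
  bw <- warp_volume_back(vol_b, field)
  rp <- params
  rp$search_radius <- pmin(params$search_radius, 2L)
  res <- estimate_displacement(vol_a, bw, rp, spacing = field$spacing,
                               roi = roi, support = support,
                               frame_pair = field$frame_pair)
  res <- quality_filter(res, rp)
  out <- field
  upd <- !is.na(res$vectors[, , , 1]) & !is.na(field$vectors[, , , 1])
  for (c in 1:3) {
    v <- out$vectors[, , , c]
    v[upd] <- v[upd] + res$vectors[, , , c][upd]
    out$vectors[, , , c] <- v
  }
  out$quality[upd] <- res$quality[upd]
  out
}

#' Regularize a displacement field by Gaussian smoothing
#'
#' NA-aware normalized convolution of each vector component with an
#' isotropic Gaussian: undefined voxels carry zero weight and stay
#' undefined. Constant and affine fields pass through unchanged in the
#' interior of the defined region.
#'
#' @param field a `displacement_field`.
#' @param sigma_vox Gaussian sigma in voxels.
#' @return the smoothed `displacement_field`.
#' @export
smooth_field <- function(field, sigma_vox) {
  stopifnot(inherits(field, "displacement_field"))
  if (sigma_vox <= 0) return(field)
  d <- dim(field$quality)
  def <- array(0, d)
  def[!is.na(field$vectors[, , , 1])] <- 1
  wblur <- gauss_blur_fft(def, rep(sigma_vox, 3))
  out <- field
  for (c in 1:3) {
    v <- field$vectors[, , , c]
    v[is.na(v)] <- 0
    sm <- gauss_blur_fft(v, rep(sigma_vox, 3)) / pmax(wblur, 1e-12)
    sm[def == 0] <- NA_real_
    out$vectors[, , , c] <- sm
  }
  out
}

# displacement vectors (mm) interpolated at continuous 0-based voxel
# coordinates `pts_vox` (n x 3); NA-aware trilinear with nearest fallback
interp_field_mm <- function(field, pts_vox) {
  d <- dim(field$quality)
  .trilinear3_cpp(field$vectors[, , , 1], field$vectors[, , , 2],
                  field$vectors[, , , 3], as.integer(d), pts_vox)
}
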