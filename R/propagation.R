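#' Warp a binary mask by a displacement field
#'
#' Every set voxel is moved by its local displacement (nearest-voxel
#' rounding of rest position + displacement/spacing) and splatted into the
#' output grid; a one-voxel morphological closing then removes dropout
#' holes. Set voxels without a defined vector use the nearest defined one.
#'
#' @param mask logical 3D array.
#' @param field a [estimate_displacement()] result on the same grid.
#' @return logical 3D array, the warped mask.
#' @export
warp_mask <- function(mask, field) {
  stopifnot(inherits(field, "displacement_field"))
  d <- dim(mask)
  if (!identical(d, dim(field$quality))) stop("input error: grid mismatch")
  idx <- mask_which(mask)
  if (!nrow(idx)) stop("input error: empty mask")
  pts_vox <- idx - 1  # 0-based
  u <- interp_field_mm(field, pts_vox)
  if (anyNA(u))
    stop("no defined displacement near ", sum(!stats::complete.cases(u)),
         " mask voxels")
  tgt <- round(pts_vox + sweep(u, 2, field$spacing, `/`)) + 1
  keep <- tgt[, 1] >= 1 & tgt[, 1] <= d[1] & tgt[, 2] >= 1 & tgt[, 2] <= d[2] &
          tgt[, 3] >= 1 & tgt[, 3] <= d[3]
  tgt <- tgt[keep, , drop = FALSE]
  out <- array(FALSE, d)
  out[tgt] <- TRUE
  close1(out)
}

#' Initialise Lagrangian displacement accumulation
#'
#' @param rest_mask logical 3D mask of material voxels at frame 1.
#' @param spacing mm triple.
#' @return Object of class `accumulated_displacement`: rest-voxel indices
#'   (`idx`, 1-based), per-frame list `frames` of n x 3 mm matrices
#'   (frame 1 all zero), per-frame logical `defined`, and `spacing`.
#' @export
init_accumulation <- function(rest_mask, spacing) {
  idx <- mask_which(rest_mask)
  if (!nrow(idx)) stop("input error: empty rest mask")
  structure(list(idx = idx, dims = dim(rest_mask),
                 spacing = as.numeric(spacing),
                 frames = list(matrix(0, nrow(idx), 3)),
                 defined = list(rep(TRUE, nrow(idx)))),
            class = "accumulated_displacement")
}

#' Accumulate an inter-volume displacement increment
#'
#' Lagrangian composition: a material point at rest position `x` with
#' accumulated displacement `u_t(x)` gains the increment evaluated (by
#' trilinear interpolation) at its current position `x + u_t(x)`:
#' `u_{t+1}(x) = u_t(x) + incr(x + u_t(x))`. With
#' `mode = "eulerian"` the increment is instead read at the rest position
#' (plain per-voxel summation, valid only for sub-voxel total motion).
#'
#' @param accum an [init_accumulation()] object holding frames `1..t`.
#' @param incr a `displacement_field` for the frame pair `(t, t+1)`.
#' @param mode `"lagrangian"` (default) or `"eulerian"`.
#' @return `accum` extended with frame `t+1`.
#' @export
accumulate <- function(accum, incr, mode = c("lagrangian", "eulerian")) {
  stopifnot(inherits(accum, "accumulated_displacement"),
            inherits(incr, "displacement_field"))
  mode <- match.arg(mode)
  if (!identical(accum$dims, dim(incr$quality)))
    stop("input error: grid mismatch")
  t <- length(accum$frames)
  u <- accum$frames[[t]]
  def <- accum$defined[[t]]
  query_mm <- if (mode == "lagrangian") (accum$idx - 1) * rep(accum$spacing, each = nrow(u)) + u
              else (accum$idx - 1) * rep(accum$spacing, each = nrow(u))
  query_vox <- sweep(query_mm, 2, accum$spacing, `/`)
  du <- interp_field_mm(incr, query_vox)
  ok <- def & stats::complete.cases(du)
  unew <- u
  unew[ok, ] <- u[ok, ] + du[ok, ]
  unew[!ok, ] <- NA_real_
  accum$frames[[t + 1]] <- unew
  accum$defined[[t + 1]] <- ok
  accum
}

# accumulated vectors of frame t as a full-grid [dims, 3] array (NA elsewhere)
accum_as_array <- function(accum, t) {
  arr <- array(NA_real_, c(accum$dims, 3))
  npl <- prod(accum$dims)
  lin <- (accum$idx[, 3] - 1) * accum$dims[1] * accum$dims[2] +
         (accum$idx[, 2] - 1) * accum$dims[1] + accum$idx[, 1]
  u <- accum$frames[[t]]
  arr[lin] <- u[, 1]
  arr[lin + npl] <- u[, 2]
  arr[lin + 2 * npl] <- u[, 3]
  arr
}

#' Propagate a rest mask and accumulate displacements over a sequence
#'
#' Runs block-matching tracking for every consecutive frame pair,
#' quality-filters each field, warps the mask forward and composes the
#' accumulated displacement of the rest-mask material points.
#'
#' @param volumes a [volume_sequence()].
#' @param rest_mask logical 3D mask on the frame-1 grid.
#' @param params a [tracking_params()].
#' @param roi_margin voxels of dilation around the current mask inside
#'   which displacement is estimated (tracking elsewhere is not needed).
#' @param mode accumulation mode passed to [accumulate()].
#' @param masked_tracking if `TRUE` (default) the correlation blocks of
#'   each frame pair are restricted to the current propagated mask
#'   (slightly dilated), preventing the static or slower-moving surround
#'   from biasing motion estimates at the muscle boundary.
#' @return list with `masks` (per-frame logical arrays), `accum`
#'   (accumulated displacement) and `fields` (per-pair displacement fields).
#' @export
propagate_sequence <- function(volumes, rest_mask, params = tracking_params(),
                               roi_margin = 6L, mode = "lagrangian",
                               masked_tracking = TRUE) {
  stopifnot(inherits(volumes, "volume_sequence"))
  d <- dim(volumes$data[[1]])
  if (!identical(dim(rest_mask), d)) stop("input error: mask grid mismatch")
  nf <- n_frames(volumes)
  masks <- vector("list", nf)
  fields <- vector("list", nf - 1)
  masks[[1]] <- rest_mask
  accum <- init_accumulation(rest_mask, volumes$spacing)
  for (t in seq_len(nf - 1)) {
    roi <- dilate_n(masks[[t]] | rest_mask, roi_margin)
    supp <- if (masked_tracking) dilate6(masks[[t]]) else NULL
    f <- estimate_displacement(volumes$data[[t]], volumes$data[[t + 1]],
                               params, spacing = volumes$spacing, roi = roi,
                               support = supp, frame_pair = c(t, t + 1L))
    f <- quality_filter(f, params)
    if (!is.null(params$smooth_sigma) && params$smooth_sigma > 0)
      f <- smooth_field(f, params$smooth_sigma)
    np <- if (is.null(params$refine_passes)) 0L else params$refine_passes
    for (p in seq_len(np)) {
      f <- refine_displacement(volumes$data[[t]], volumes$data[[t + 1]], f,
                               params, roi = roi, support = supp)
      if (!is.null(params$smooth_sigma) && params$smooth_sigma > 0)
        f <- smooth_field(f, params$smooth_sigma)
    }
    fields[[t]] <- f
    accum <- accumulate(accum, f, mode = mode)
    # propagate the mask from the accumulated Lagrangian field (splat of
    # rest-mask material points + closing) rather than by chaining warps,
    # which compounds rounding artifacts frame over frame
    def <- accum$defined[[t + 1]]
    pos <- (accum$idx[def, , drop = FALSE] - 1) +
      sweep(accum$frames[[t + 1]][def, , drop = FALSE], 2,
            volumes$spacing, `/`)
    tgt <- round(pos) + 1
    keep <- tgt[, 1] >= 1 & tgt[, 1] <= d[1] & tgt[, 2] >= 1 &
            tgt[, 2] <= d[2] & tgt[, 3] >= 1 & tgt[, 3] <= d[3]
    m <- array(FALSE, d)
    m[tgt[keep, , drop = FALSE]] <- TRUE
    masks[[t + 1]] <- close1(m)
  }
  list(masks = masks, accum = accum, fields = fields)
}
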