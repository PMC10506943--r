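#' Least-squares strain from projected displacements (2x2x2 LSQSE)
#'
#' For every mask voxel the 2x2x2 voxel neighbourhood (the voxel plus its
#' +1 neighbours along each axis) is collected; over the in-mask members
#' with a defined projected displacement, an ordinary least-squares line of
#' tangential displacement against arc coordinate is fitted, and the slope
#' (times 100) is the local strain in percent. A voxel is undefined when
#' fewer than 4 members are valid or the sample variance of the arc
#' coordinates is below 1e-6 mm^2.
#'
#' @param proj numeric vector of tangential displacements (mm), aligned
#'   with `map$idx` (`NA` = undefined).
#' @param map an [build_arc_map()] result.
#' @param mask logical 3D array (the strain support).
#' @return 3D array of strain in percent, `NA` where undefined.
#' @export
lsq_strain <- function(proj, map, mask) {
  stopifnot(inherits(map, "arc_coordinate_map"))
  if (length(proj) != nrow(map$idx))
    stop("input error: proj length must match map voxels")
  d <- dim(mask)
  s_arr <- array(NA_real_, d)
  p_arr <- array(NA_real_, d)
  s_arr[map$lin] <- map$s
  p_arr[map$lin] <- proj
  valid <- array(FALSE, d)
  valid[map$lin] <- !is.na(proj)
  n <- ss <- sp <- sss <- ssp <- array(0, d)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    off <- c(ox, oy, oz)
    sv <- shift_array(s_arr, -off, NA_real_)
    pv <- shift_array(p_arr, -off, NA_real_)
    vv <- shift_array(valid, -off, FALSE)
    sv[!vv] <- 0; pv[!vv] <- 0
    n <- n + vv
    ss <- ss + sv
    sp <- sp + pv
    sss <- sss + sv * sv
    ssp <- ssp + sv * pv
  }
  var_num <- sss - ss * ss / pmax(n, 1)           # (n-1) * sample variance
  ok <- array(FALSE, d)
  ok[map$lin] <- TRUE
  ok <- ok & n >= 4 & (var_num / pmax(n - 1, 1)) >= 1e-6
  out <- array(NA_real_, d)
  out[ok] <- 100 * (ssp[ok] - ss[ok] * sp[ok] / n[ok]) / var_num[ok]
  out
}

# nearest centerline sample for arbitrary mm points: tangent and arc coord
nearest_tangent <- function(cl, pts) {
  cp <- cl$points
  tang <- matrix(NA_real_, nrow(pts), 3)
  s <- rep(NA_real_, nrow(pts))
  ok <- which(stats::complete.cases(pts))
  if (!length(ok)) return(list(tangent = tang, s = s))
  chunk <- 2000L
  for (st in seq(1L, length(ok), by = chunk)) {
    en <- min(st + chunk - 1L, length(ok))
    rows <- ok[st:en]
    block <- pts[rows, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rep(1, nrow(cp))) +
          outer(rep(1, nrow(block)), rowSums(cp^2)) -
          2 * block %*% t(cp)
    nearest <- max.col(-d2, ties.method = "first")
    tang[rows, ] <- cl$tangents[nearest, , drop = FALSE]
    s[rows] <- cl$arc_length[nearest]
  }
  list(tangent = tang, s = s)
}

# Window least-squares strain from 3-vector displacements: for each mask
# voxel the 2x2x2 window members' displacement vectors are projected on the
# *window center's* tangent and regressed against the members' arc
# coordinates. Using one tangent per window makes a rigid translation
# register exactly zero strain (a per-voxel-tangent projection would pick
# up the curvature term u . dt/ds instead).
#   disp: n x 3 mm displacements aligned with map$idx
#   s, tangent: per-voxel arc coordinates (mm) / unit tangents (defaults
#     from `map`; overridable for strain increments in a moved geometry)
lsq_strain_vec <- function(disp, map, mask, s = NULL, tangent = NULL) {
  d <- dim(mask)
  if (is.null(s)) s <- map$s
  if (is.null(tangent)) tangent <- map$tangent
  s_arr <- array(NA_real_, d)
  s_arr[map$lin] <- s
  v_arr <- lapply(1:3, function(c) {
    a <- array(NA_real_, d); a[map$lin] <- disp[, c]; a
  })
  t_arr <- lapply(1:3, function(c) {
    a <- array(NA_real_, d); a[map$lin] <- tangent[, c]; a
  })
  valid <- array(FALSE, d)
  valid[map$lin] <- stats::complete.cases(disp) & !is.na(s)
  n <- ss <- sp <- sss <- ssp <- array(0, d)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    off <- c(ox, oy, oz)
    sv <- shift_array(s_arr, -off, NA_real_)
    vv <- shift_array(valid, -off, FALSE)
    pv <- shift_array(v_arr[[1]], -off, NA_real_) * t_arr[[1]] +
          shift_array(v_arr[[2]], -off, NA_real_) * t_arr[[2]] +
          shift_array(v_arr[[3]], -off, NA_real_) * t_arr[[3]]
    vv <- vv & !is.na(pv) & !is.na(sv)
    sv[!vv] <- 0; pv[!vv] <- 0
    n <- n + vv
    ss <- ss + sv
    sp <- sp + pv
    sss <- sss + sv * sv
    ssp <- ssp + sv * pv
  }
  var_num <- sss - ss * ss / pmax(n, 1)
  ok <- array(FALSE, d)
  ok[map$lin] <- TRUE
  ok <- ok & n >= 4 & (var_num / pmax(n - 1, 1)) >= 1e-6
  out <- array(NA_real_, d)
  out[ok] <- 100 * (ssp[ok] - ss[ok] * sp[ok] / n[ok]) / var_num[ok]
  out
}

#' Compute the strain series of a volume sequence
#'
#' Full per-subject strain computation: tracking of every consecutive frame
#' pair, mask propagation, Lagrangian displacement accumulation, centerline
#' projection and least-squares strain, yielding one strain field per frame
#' on the rest-frame material voxels.
#'
#' Two projection modes are provided. `"terminal"` (default) projects each
#' frame's fully accumulated 3-vector displacement onto the rest-frame
#' centerline geometry. `"incremental"` additionally corrects for the
#' change in direction of the muscle during contraction: at each frame the
#' centerline is recomputed on the propagated mask and the inter-volume
#' strain increment of every material window is evaluated with the
#' *current* local tangent, then accumulated. The correction only matters
#' once the muscle rotates substantially; recomputing centerlines on
#' propagated masks costs tangent precision, so the terminal mode is the
#' more accurate default at moderate rotations.
#'
#' @param volumes a [volume_sequence()].
#' @param rest_mask logical 3D mask of the muscle at frame 1.
#' @param params a [tracking_params()].
#' @param mode `"incremental"` or `"terminal"`.
#' @param degree centerline polynomial degree.
#' @param roi_margin tracking ROI dilation, voxels.
#' @return Object of class `strain_series`: `strain` (per-frame list of 3D
#'   percent-strain arrays; frame 1 identically 0 on the mask), `rest_mask`,
#'   `map` (rest-frame arc map), `centerline`, `masks`, `accum`, `mode`.
#' @export
compute_strain_series <- function(volumes, rest_mask,
                                  params = tracking_params(),
                                  mode = c("terminal", "incremental"),
                                  degree = 5L, roi_margin = 6L) {
  mode <- match.arg(mode)
  prop <- propagate_sequence(volumes, rest_mask, params,
                             roi_margin = roi_margin)
  cl0 <- extract_centerline(rest_mask, volumes$spacing, degree = degree)
  map0 <- build_arc_map(rest_mask, cl0, volumes$spacing)
  nf <- n_frames(volumes)
  strain <- vector("list", nf)
  zero <- array(NA_real_, dim(rest_mask))
  zero[map0$lin] <- 0
  strain[[1]] <- zero
  accum <- prop$accum
  if (mode == "terminal") {
    # project each frame's fully accumulated displacement on the rest-frame
    # centerline geometry
    for (t in 2:nf)
      strain[[t]] <- lsq_strain_vec(accum$frames[[t]], map0, rest_mask)
  } else {
    # angle-corrected: per frame, estimate the strain *increment* of each
    # material window in the current geometry (centerline recomputed on the
    # propagated mask, increments regressed against current arc
    # coordinates) and accumulate the increments per material voxel
    eps <- array(NA_real_, dim(rest_mask))
    eps[map0$lin] <- 0
    rest_mm <- vox_to_mm(map0$idx, volumes$spacing)
    for (t in 2:nf) {
      cl_t <- if (t == 2) cl0
              else extract_centerline(prop$masks[[t - 1]], volumes$spacing,
                                      degree = degree,
                                      largest_component = TRUE)
      cur <- rest_mm + accum$frames[[t - 1]]
      geo <- nearest_tangent(cl_t, cur)
      du <- accum$frames[[t]] - accum$frames[[t - 1]]
      # current tangents (the angle correction), rest-frame arc coordinates
      # (a clean Lagrangian regressor: per-frame arc parameterizations are
      # too noisy to difference against)
      inc <- lsq_strain_vec(du, map0, rest_mask, tangent = geo$tangent)
      upd <- !is.na(inc) & !is.na(eps)
      eps[upd] <- eps[upd] + inc[upd]
      strain[[t]] <- eps
    }
  }
  structure(list(strain = strain, rest_mask = rest_mask, map = map0,
                 centerline = cl0, masks = prop$masks, accum = accum,
                 mode = mode, spacing = volumes$spacing),
            class = "strain_series")
}

#' Select the maximum-contraction frame
#'
#' The frame whose mid-region median strain is most negative (strongest
#' shortening of the sling); ties resolve to the earliest frame.
#'
#' @param series a [compute_strain_series()] result, or a list of 3D strain
#'   arrays.
#' @param partition a [partition_regions()] result.
#' @param override optional integer frame index forced as the selection.
#' @return integer frame index (1-based; frame 1 is rest).
#' @export
select_max_contraction <- function(series, partition, override = NULL) {
  strain <- if (inherits(series, "strain_series")) series$strain else series
  if (!length(strain)) stop("input error: empty strain series")
  if (!is.null(override)) return(as.integer(override))
  mid_lin <- partition$lin[partition$label == "mid"]
  med <- vapply(strain, function(sf) {
    v <- sf[mid_lin]
    v <- v[!is.na(v)]
    if (!length(v)) Inf else stats::median(v)
  }, numeric(1))
  if (all(!is.finite(med)))
    stop("mid region has no defined strain in any frame")
  which.min(med)
}
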