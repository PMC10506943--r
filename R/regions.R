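#' Partition the muscle into right-end, mid and left-end regions
#'
#' Voxels are split by their arc coordinate so that each end region holds
#' `ceiling(end_fraction/2 * N)` voxels (by sorted arc coordinate, from the
#' bottom for one end and from the top for the other); the combined end
#' volume is therefore the target fraction (default one third) of the total
#' muscle volume, and the mid region holds the rest. Regions are defined on
#' the rest-frame mask and carried to later frames by material
#' correspondence.
#'
#' @param mask logical 3D array (rest-frame muscle mask).
#' @param map an [build_arc_map()] result on the same mask.
#' @param end_fraction target combined fraction of the two end regions,
#'   in (0, 1); default 1/3.
#' @param orientation `"s0_right"` (default: the `s = 0` end is labelled
#'   right) or `"s0_left"`.
#' @return Object of class `region_partition`: factor `label` per mask
#'   voxel (levels right_end, mid, left_end), `lin`, `idx`, cut coordinates
#'   `s_lo`, `s_hi`, `end_fraction`, `orientation`, `dims`.
#' @export
partition_regions <- function(mask, map, end_fraction = 1 / 3,
                              orientation = c("s0_right", "s0_left")) {
  orientation <- match.arg(orientation)
  if (!(end_fraction > 0 && end_fraction < 1))
    stop("specification error: end_fraction must lie in (0, 1)")
  stopifnot(inherits(map, "arc_coordinate_map"))
  n <- length(map$s)
  n_end <- ceiling(end_fraction / 2 * n)
  if (n_end < 1 || n - 2 * n_end < 1)
    stop("empty region after cuts (n = ", n, ", per-end = ", n_end, ")")
  ord <- order(map$s)
  lab_s <- rep("mid", n)
  lab_s[ord[seq_len(n_end)]] <- "s0_end"
  lab_s[ord[seq(n - n_end + 1, n)]] <- "s1_end"
  s_lo <- map$s[ord[n_end]]
  s_hi <- map$s[ord[n - n_end + 1]]
  if (orientation == "s0_right") {
    lab <- c(s0_end = "right_end", mid = "mid", s1_end = "left_end")[lab_s]
  } else {
    lab <- c(s0_end = "left_end", mid = "mid", s1_end = "right_end")[lab_s]
  }
  structure(list(label = factor(lab, levels = c("right_end", "mid", "left_end")),
                 lin = map$lin, idx = map$idx, s_lo = s_lo, s_hi = s_hi,
                 end_fraction = end_fraction, orientation = orientation,
                 dims = map$dims),
            class = "region_partition")
}

#' Regional strain medians
#'
#' Median percent strain over the defined voxels of each region.
#'
#' @param strain 3D percent-strain array (e.g. one frame of a
#'   [compute_strain_series()] result).
#' @param partition a [partition_regions()] result.
#' @return named numeric vector `c(eps_right, eps_left, eps_mid)`.
#' @export
region_medians <- function(strain, partition) {
  stopifnot(inherits(partition, "region_partition"))
  one <- function(region) {
    v <- strain[partition$lin[partition$label == region]]
    v <- v[!is.na(v)]
    if (!length(v)) stop("region '", region, "' has no defined strain")
    stats::median(v)
  }
  c(eps_right = one("right_end"), eps_left = one("left_end"),
    eps_mid = one("mid"))
}

#' Normalized strain ratio between the two muscle ends
#'
#' The absolute difference in median strain between the two ends,
#' normalized by the absolute difference between the mid-region median and
#' the average of the two end medians:
#' `abs(eps_right - eps_left) / abs(eps_mid - (eps_right + eps_left) / 2)`.
#' Ratios below 1 indicate symmetric end behaviour (intact muscle); ratios
#' above 1 indicate an end asymmetry as caused by unilateral avulsion.
#'
#' @param eps_right,eps_left,eps_mid regional median strains in percent.
#' @return non-negative dimensionless ratio.
#' @export
normalized_strain_ratio <- function(eps_right, eps_left, eps_mid) {
  stopifnot(is.finite(eps_right), is.finite(eps_left), is.finite(eps_mid))
  denom <- eps_mid - (eps_right + eps_left) / 2
  if (abs(denom) < 1e-9)
    stop("degenerate denominator: mid-region strain equals the end average; ",
         "the normalized strain ratio is undefined")
  abs(eps_right - eps_left) / abs(denom)
}

#' Summarize one subject's strain analysis
#'
#' @param series a [compute_strain_series()] result.
#' @param partition a [partition_regions()] result.
#' @param frame_override optional forced analysis frame.
#' @param condition_label optional annotation (e.g. "intact", "avulsed").
#' @return Object of class `subject_strain_summary`: `eps_right`,
#'   `eps_left`, `eps_mid` (percent), `ratio`, `frame`, `condition_label`.
#' @export
subject_strain_summary <- function(series, partition, frame_override = NULL,
                                   condition_label = NA_character_) {
  frame <- select_max_contraction(series, partition, override = frame_override)
  med <- region_medians(series$strain[[frame]], partition)
  ratio <- normalized_strain_ratio(med[["eps_right"]], med[["eps_left"]],
                                   med[["eps_mid"]])
  structure(list(eps_right = med[["eps_right"]], eps_left = med[["eps_left"]],
                 eps_mid = med[["eps_mid"]], ratio = ratio,
                 frame = as.integer(frame),
                 condition_label = condition_label),
            class = "subject_strain_summary")
}

#' @export
print.subject_strain_summary <- function(x, ...) {
  cat(sprintf(paste0("subject strain summary (frame %d%s):\n",
                     "  eps_right = %+.2f %%  eps_left = %+.2f %%  ",
                     "eps_mid = %+.2f %%\n  normalized strain ratio = %.3f\n"),
              x$frame,
              if (is.na(x$condition_label)) "" else paste0(", ", x$condition_label),
              x$eps_right, x$eps_left, x$eps_mid, x$ratio))
  invisible(x)
}
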