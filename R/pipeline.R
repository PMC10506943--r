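#' Build a run configuration
#'
#' A flat, serializable bundle of every tunable parameter of the
#' per-subject pipeline. Round-trips losslessly through YAML.
#'
#' @param block_size,search_radius,subvoxel,min_quality,median_filter_radius,stride
#'   tracking parameters (see [tracking_params()]).
#' @param degree centerline polynomial degree.
#' @param mode projection mode, `"incremental"` or `"terminal"`.
#' @param end_fraction combined end-region volume fraction.
#' @param orientation `"s0_right"` or `"s0_left"`.
#' @param frame_override optional forced analysis frame (`NA` = automatic
#'   maximum-contraction selection).
#' @param roi_margin tracking ROI dilation around the mask, voxels.
#' @param alpha cohort significance level.
#' @param seed integer seed recorded with the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(block_size = c(5L, 5L, 5L), search_radius = c(5L, 5L, 5L),
                       subvoxel = TRUE, min_quality = 0.5,
                       median_filter_radius = 2L, stride = 1L,
                       smooth_sigma = 1.2, refine_passes = 2L,
                       degree = 5L, mode = "terminal",
                       end_fraction = 1 / 3, orientation = "s0_right",
                       frame_override = NA_integer_, roi_margin = 6L,
                       alpha = 0.05, seed = 1L) {
  cfg <- list(block_size = as.integer(rep_len(block_size, 3)),
              search_radius = as.integer(rep_len(search_radius, 3)),
              subvoxel = isTRUE(subvoxel), min_quality = min_quality,
              median_filter_radius = as.integer(median_filter_radius),
              stride = as.integer(stride), smooth_sigma = smooth_sigma,
              refine_passes = as.integer(refine_passes),
              degree = as.integer(degree),
              mode = mode, end_fraction = end_fraction,
              orientation = orientation,
              frame_override = as.integer(frame_override),
              roi_margin = as.integer(roi_margin), alpha = alpha,
              seed = as.integer(seed))
  # constituent invariants are enforced by the constructors they feed
  tracking_params(cfg$block_size, cfg$search_radius, cfg$subvoxel,
                  cfg$min_quality, cfg$median_filter_radius, cfg$stride,
                  cfg$smooth_sigma, cfg$refine_passes)
  if (!mode %in% c("incremental", "terminal")) stop("invalid mode")
  if (!orientation %in% c("s0_right", "s0_left")) stop("invalid orientation")
  if (!(end_fraction > 0 && end_fraction < 1))
    stop("end_fraction must lie in (0, 1)")
  structure(cfg, class = "run_config")
}

#' Serialize / parse a run configuration (YAML)
#' @param cfg a [run_config()].
#' @return YAML string.
#' @export
config_to_yaml <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::as.yaml(unclass(cfg), precision = 15)
}

#' @rdname config_to_yaml
#' @param text YAML string or path to a YAML file.
#' @export
config_from_yaml <- function(text) {
  lst <- if (file.exists(text)) yaml::read_yaml(text) else yaml::yaml.load(text)
  do.call(run_config, lst)
}

cfg_tracking_params <- function(cfg) {
  tracking_params(cfg$block_size, cfg$search_radius, cfg$subvoxel,
                  cfg$min_quality, cfg$median_filter_radius, cfg$stride,
                  cfg$smooth_sigma, cfg$refine_passes)
}

#' Run the full per-subject strain pipeline
#'
#' Tracking, mask propagation, displacement accumulation, centerline
#' projection, least-squares strain, region partition and the normalized
#' strain ratio, for one subject (one volume sequence plus its rest-frame
#' muscle segmentation).
#'
#' @param volumes a [volume_sequence()] or path to a 4D NIfTI file.
#' @param mask logical 3D array or path to a 3D NIfTI mask.
#' @param config a [run_config()].
#' @param out_dir optional directory for intermediates (propagated masks,
#'   strain per frame, centerline CSV, region labels, summary JSON).
#' @param condition_label optional annotation carried into the summary.
#' @return Object of class `subject_run_record`: the
#'   [subject_strain_summary()], the `strain_series`, the
#'   `region_partition`, per-stage `timings` (seconds), input `checksums`
#'   (when paths were given), the `config` snapshot and package version.
#' @export
run_subject <- function(volumes, mask, config = run_config(), out_dir = NULL,
                        condition_label = NA_character_) {
  stopifnot(inherits(config, "run_config"))
  checksums <- list()
  if (is.character(volumes)) {
    checksums$volumes <- unname(tools::md5sum(volumes))
    volumes <- read_volume_sequence(volumes)
  }
  if (is.character(mask)) {
    checksums$mask <- unname(tools::md5sum(mask))
    mask <- read_mask(mask)
  }
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  series <- compute_strain_series(volumes, mask, cfg_tracking_params(config),
                                  mode = config$mode, degree = config$degree,
                                  roi_margin = config$roi_margin)
  timings["strain_series"] <- tic() - t0
  t0 <- tic()
  part <- partition_regions(mask, series$map,
                            end_fraction = config$end_fraction,
                            orientation = config$orientation)
  fo <- if (is.na(config$frame_override)) NULL else config$frame_override
  summary <- subject_strain_summary(series, part, frame_override = fo,
                                    condition_label = condition_label)
  timings["summary"] <- tic() - t0
  rec <- structure(list(summary = summary, series = series, partition = part,
                        timings = timings, checksums = checksums,
                        config = config,
                        version = as.character(utils::packageVersion("prmstrain"))),
                   class = "subject_run_record")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sp <- volumes$spacing
    for (t in seq_along(series$masks))
      write_mask(series$masks[[t]], sp,
                 file.path(out_dir, sprintf("mask_%03d.nii.gz", t)))
    nf <- length(series$strain)
    arr <- array(NA_real_, c(dim(mask), nf))
    for (t in seq_len(nf)) arr[, , , t] <- series$strain[[t]]
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(sp, volumes$frame_interval)
    RNifti::writeNifti(img, file.path(out_dir, "strain.nii.gz"),
                       datatype = "double")
    write_centerline(series$centerline, file.path(out_dir, "centerline.csv"))
    labmap <- array(0L, dim(mask))
    labmap[part$lin] <- as.integer(factor(part$label,
                                          levels = c("right_end", "mid",
                                                     "left_end")))
    write_mask(labmap, sp, file.path(out_dir, "regions.nii.gz"))
    jsonlite::write_json(
      list(summary = unclass(summary), timings = as.list(timings),
           checksums = checksums, config = unclass(config),
           version = rec$version),
      file.path(out_dir, "subject.json"), auto_unbox = TRUE, digits = NA)
  }
  rec
}

#' Compare two cohorts of subject runs
#'
#' @param summaries_a,summaries_b lists of [subject_strain_summary()] (or
#'   `subject_run_record`) objects, or numeric ratio vectors.
#' @param alpha significance level.
#' @param out_dir optional directory: writes `comparison.json` and a
#'   boxplot `ratios.png`.
#' @return a [compare_cohorts()] result.
#' @export
run_cohort <- function(summaries_a, summaries_b, alpha = 0.05,
                       out_dir = NULL) {
  unwrap <- function(s) {
    if (is.numeric(s)) return(s)
    lapply(s, function(x) if (inherits(x, "subject_run_record")) x$summary else x)
  }
  cmp <- compare_cohorts(unwrap(summaries_a), unwrap(summaries_b),
                         alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(cmp), file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    grDevices::png(file.path(out_dir, "ratios.png"), width = 600, height = 500)
    graphics::boxplot(list(intact = cmp$ratios_a, avulsed = cmp$ratios_b),
                      ylab = "normalized strain ratio",
                      main = sprintf("Mann-Whitney p = %.3g", cmp$p_value))
    graphics::abline(h = 1, lty = 2, col = "grey40")
    grDevices::dev.off()
  }
  cmp
}
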