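# NIfTI interchange. NIfTI is the canonical on-disk format for volume
# sequences, masks and field components; CSV/JSON carry curves, summaries
# and provenance.

nifti_spacing <- function(img, ndim_spatial = 3) {
  pd <- RNifti::pixdim(img)
  sp <- pd[seq_len(ndim_spatial)]
  if (length(sp) < ndim_spatial || any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in NIfTI header (pixdim = ",
         paste(signif(pd, 4), collapse = ", "), "); refusing to guess")
  sp
}

#' Read a 3D+t volume sequence from a 4D NIfTI file
#'
#' @param path NIfTI file (.nii or .nii.gz), 4D with frames in the fourth
#'   dimension. Voxel spacing must be present in the header; there is no
#'   silent default.
#' @param frame_interval optional override of the frame interval (seconds);
#'   by default the fourth pixdim entry is used when positive.
#' @return a [volume_sequence()].
#' @export
read_volume_sequence <- function(path, frame_interval = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4D NIfTI volume sequence, got ",
                           length(d), "D")
  sp <- nifti_spacing(img)
  if (is.null(frame_interval)) {
    pd <- RNifti::pixdim(img)
    frame_interval <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0)
      pd[4] else 1 / 1.5
  }
  arr <- array(as.numeric(img), d)
  volume_sequence(arr, spacing = sp, frame_interval = frame_interval)
}

#' Write a volume sequence as 4D NIfTI
#'
#' @param vs a [volume_sequence()].
#' @param path output file (.nii or .nii.gz).
#' @export
write_volume_sequence <- function(vs, path) {
  stopifnot(inherits(vs, "volume_sequence"))
  d <- dim(vs$data[[1]])
  arr <- array(0, c(d, length(vs$data)))
  for (t in seq_along(vs$data)) arr[, , , t] <- vs$data[[t]]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vs$spacing, vs$frame_interval)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a binary mask from NIfTI
#' @param path NIfTI file with a 3D (0/1) mask.
#' @return logical 3D array with attribute `spacing`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop("expected a 3D NIfTI mask, got ", length(d), "D")
  sp <- nifti_spacing(img)
  m <- array(as.numeric(img) > 0.5, d)
  attr(m, "spacing") <- sp
  m
}

#' Write a binary mask (or integer label map) as NIfTI
#' @param mask logical or integer 3D array.
#' @param spacing mm triple.
#' @param path output file.
#' @export
write_mask <- function(mask, spacing, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Write a displacement field as per-component NIfTI plus JSON metadata
#' @param field a `displacement_field`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz` (4D, 3
#'   components) and `<prefix>.json`.
#' @export
write_displacement_field <- function(field, prefix) {
  stopifnot(inherits(field, "displacement_field"))
  img <- RNifti::asNifti(field$vectors)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"), datatype = "double")
  meta <- list(frame_pair = field$frame_pair, stride = field$stride,
               spacing = field$spacing, units = "mm")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Write a centerline as CSV (s, x, y, z, tx, ty, tz)
#' @param cl a `prm_centerline`.
#' @param path output CSV path.
#' @export
write_centerline <- function(cl, path) {
  stopifnot(inherits(cl, "prm_centerline"))
  df <- data.frame(s = cl$arc_length,
                   x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
                   tx = cl$tangents[, 1], ty = cl$tangents[, 2],
                   tz = cl$tangents[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a phantom dataset to a directory
#'
#' Volumes and rest mask as NIfTI, ground-truth displacement (one 4D file
#' per component) and strain as NIfTI, the analytic centerline as CSV, and
#' a JSON sidecar with the spec and seed.
#'
#' @param pd a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @export
write_phantom <- function(pd, dir) {
  stopifnot(inherits(pd, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume_sequence(pd$volumes, file.path(dir, "volumes.nii.gz"))
  write_mask(pd$rest_mask, pd$spec$spacing, file.path(dir, "rest_mask.nii.gz"))
  nf <- length(pd$true_displacement)
  d <- dim(pd$rest_mask)
  for (c in 1:3) {
    arr <- array(0, c(d, nf))
    for (t in seq_len(nf)) arr[, , , t] <- pd$true_displacement[[t]][, , , c]
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(pd$spec$spacing, pd$spec$frame_interval)
    RNifti::writeNifti(img, file.path(dir, sprintf("true_disp_%s.nii.gz",
                                                   c("x", "y", "z")[c])),
                       datatype = "double")
  }
  arr <- array(NA_real_, c(d, nf))
  for (t in seq_len(nf)) arr[, , , t] <- pd$true_strain[[t]]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(pd$spec$spacing, pd$spec$frame_interval)
  RNifti::writeNifti(img, file.path(dir, "true_strain.nii.gz"),
                     datatype = "double")
  write_centerline(pd$true_centerline, file.path(dir, "true_centerline.csv"))
  side <- pd$spec
  class(side) <- NULL
  jsonlite::write_json(list(spec = side, seed = pd$seed),
                       file.path(dir, "phantom.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
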