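# File-format plumbing: NIfTI for volumes/projections, CSV for TACs and
# polar maps, JSON for fits and calibration models.

#' Write / read a volume as NIfTI
#'
#' @param volume `activity_volume`, `recon_volume` or 3D array.
#' @param path output `.nii`/`.nii.gz` path.
#' @param voxel_mm isotropic voxel size recorded in the header.
#' @return `path` (write) or a 3D array with `voxel_mm` attribute (read).
#' @export
write_volume_nifti <- function(volume, path, voxel_mm = 3.3) {
  vox <- if (is.list(volume)) volume$voxels else volume
  if (is.list(volume) && !is.null(volume$voxel_mm))
    voxel_mm <- volume$voxel_mm
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[1]
  out
}

#' Write / read a projection set as NIfTI
#'
#' Views are stored as a bin x slice x view 3D stack; the uniform angular
#' step over 360 degrees is reconstructed on read.
#'
#' @param projections a `projection_set`.
#' @param path output path.
#' @return `path` (write) or a `projection_set` (read).
#' @export
write_projections_nifti <- function(projections, path) {
  stk <- aperm(projections$views, c(2, 3, 1))
  RNifti::writeNifti(RNifti::asNifti(stk), path)
  invisible(path)
}

#' @rdname write_projections_nifti
#' @export
read_projections_nifti <- function(path) {
  stk <- RNifti::readNifti(path)
  views <- aperm(array(as.numeric(stk), dim = dim(stk)), c(3, 1, 2))
  n_views <- dim(views)[1]
  structure(list(views = views,
                 angles_deg = (seq_len(n_views) - 1) * 360 / n_views,
                 time_per_view_s = 20),
            class = "projection_set")
}

#' Write / read a time-activity curve as CSV
#'
#' Two columns: `t` (s) and `counts`.
#' @param tac a `tac`.
#' @param path output path.
#' @return `path` (write) or a `tac` (read).
#' @export
write_tac_csv <- function(tac, path) {
  utils::write.csv(data.frame(t = tac$times, counts = tac$counts), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(times = df$t, counts = df$counts), class = "tac")
}

#' Export a gamma-variate fit as JSON
#'
#' @param fit a `gamma_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a polar map as CSV (ring, sector, value)
#'
#' @param polar_map a `polar_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polar_map_csv <- function(polar_map, path) {
  df <- data.frame(ring = rep(seq_len(polar_map$rings), polar_map$sectors),
                   sector = rep(seq_len(polar_map$sectors),
                                each = polar_map$rings),
                   value = as.vector(polar_map$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
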