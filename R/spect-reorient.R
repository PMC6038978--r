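# Trilinear interpolation of a 3D array at fractional voxel coordinates.
# Coordinates outside the grid return `fill`.
interp3 <- function(vox, x, y, z, fill = 0) {
  d <- dim(vox)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- rep(fill, length(x))
  ok <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2] &
        z0 >= 1 & z0 + 1 <= d[3]
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  at <- function(dx, dy, dz)
    vox[cbind(x0 + dx, y0 + dy, z0 + dz)]
  v <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out[ok] <- v
  out
}

# Resample: out(p) = vox(R (p - c) + c), trilinear, isotropic target grid of
# the same size.
resample_rotated <- function(vox, R, center) {
  d <- dim(vox)
  gx <- rep(seq_len(d[1]), times = d[2] * d[3])
  gy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  gz <- rep(seq_len(d[3]), each = d[1] * d[2])
  P <- rbind(gx - center[1], gy - center[2], gz - center[3])
  S <- R %*% P
  array(interp3(vox, S[1, ] + center[1], S[2, ] + center[2],
                S[3, ] + center[3]),
        dim = d)
}

#' Rotate a volume's content about its center
#'
#' Rotates the volume content by `Rz(phi) Ry(theta)`: a feature aligned with
#' the z axis ends up along the axis with azimuth `phi` and tilt `theta`.
#' Used to build obliquely oriented phantoms and to test reorientation.
#'
#' @param volume 3D array or `activity_volume`/`recon_volume`.
#' @param phi_deg azimuthal (transaxial) angle, degrees.
#' @param theta_deg tilt from the z axis, degrees.
#' @return 3D array.
#' @export
rotate_volume <- function(volume, phi_deg, theta_deg) {
  vox <- if (is.list(volume)) volume$voxels else volume
  R <- rot_z(phi_deg) %*% rot_y(theta_deg)
  resample_rotated(vox, t(R), (dim(vox) + 1) / 2)
}

#' Reorient a reconstructed volume to short-axis geometry
#'
#' Estimates the left-ventricular long axis as the intensity-weighted
#' principal axis of voxels above `threshold` of the volume maximum and
#' resamples the volume (trilinear, isotropic at the original voxel size) so
#' slices are perpendicular to that axis, apex-to-base along z. If the
#' thresholded mask is empty or isotropic the supplied template geometry is
#' used instead and the result is flagged virtual; with no template the
#' reorientation fails.
#'
#' @param volume a `recon_volume`, `activity_volume` or 3D array.
#' @param geometry optional known `short_axis_geometry` (angles are applied
#'   as given, no estimation).
#' @param template optional fallback `short_axis_geometry` for low-uptake
#'   volumes.
#' @param threshold mask threshold as a fraction of the maximum.
#' @param min_anisotropy smallest leading-eigenvalue ratio accepted as a
#'   determinate axis.
#' @return list with `volume` (reoriented array) and `geometry` (class
#'   `short_axis_geometry`: `center`, `angles_deg` = c(phi, theta),
#'   `slice_range`, `virtual`).
#' @export
reorient_short_axis <- function(volume, geometry = NULL, template = NULL,
                                threshold = 0.5, min_anisotropy = 1.15) {
  vox <- if (is.list(volume)) volume$voxels else volume
  d <- dim(vox)
  virtual <- FALSE
  if (is.null(geometry)) {
    est <- tryCatch(estimate_long_axis(vox, threshold, min_anisotropy),
                    mibg_error = function(e) e)
    if (inherits(est, "error")) {
      if (is.null(template)) stop(est)
      geometry <- template
      virtual <- TRUE
    } else geometry <- est
  }
  ang <- geometry$angles_deg
  R <- rot_z(ang[["phi"]]) %*% rot_y(ang[["theta"]])
  ctr <- if (!is.null(geometry$center)) geometry$center else (d + 1) / 2
  out <- resample_rotated(vox, R, ctr)

  mask <- out >= threshold * max(out)
  # apex-to-base extent: slices whose in-plane mask area reaches at least
  # 10% of the largest slice, so near-empty cap slices do not form rings
  area <- apply(mask, 3, sum)
  zr <- if (any(area > 0)) range(which(area >= 0.1 * max(area)))
        else c(1L, d[3])
  slice_range <- if (!is.null(geometry$slice_range)) geometry$slice_range
                 else zr
  in_plane <- if (any(mask)) {
    w <- out * mask
    ix <- slice.index(out, 1); iy <- slice.index(out, 2)
    c(sum(ix * w), sum(iy * w)) / sum(w)
  } else ctr[1:2]
  geom <- structure(list(center = c(in_plane, mean(slice_range)),
                         angles_deg = c(phi = unname(ang[["phi"]]),
                                        theta = unname(ang[["theta"]])),
                         slice_range = as.integer(round(slice_range)),
                         virtual = virtual),
                    class = "short_axis_geometry")
  list(volume = out, geometry = geom)
}

estimate_long_axis <- function(vox, threshold, min_anisotropy) {
  mx <- max(vox)
  mask <- vox >= threshold * mx
  if (mx <= 0 || !any(mask))
    mibg_error("AxisUndetermined", "thresholded myocardial mask is empty")
  w <- vox[mask]
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colSums(idx * w) / sum(w)
  Xc <- sweep(idx, 2, ctr)
  C <- crossprod(Xc * sqrt(w / sum(w)))
  e <- eigen(C, symmetric = TRUE)
  if (e$values[1] < min_anisotropy * e$values[2])
    mibg_error("AxisUndetermined",
               "intensity distribution is isotropic; no long axis")
  u <- e$vectors[, 1]
  if (u[3] < 0) u <- -u
  phi <- atan2(u[2], u[1]) * 180 / pi
  theta <- atan2(sqrt(u[1]^2 + u[2]^2), u[3]) * 180 / pi
  if (theta < 1e-6) phi <- 0
  structure(list(center = ctr,
                 angles_deg = c(phi = phi, theta = theta),
                 slice_range = NULL, virtual = FALSE),
            class = "short_axis_geometry")
}
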