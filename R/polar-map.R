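#' Sector value from a radial count profile
#'
#' The per-sector sampling rule: the maximum over radius of the running mean
#' of three consecutive samples. A profile crossing the myocardial wall
#' therefore reads the wall counts while staying robust to single-sample
#' noise.
#'
#' @param profile numeric vector of radial samples (1-voxel steps).
#' @return maximum 3-sample running mean.
#' @export
sector_max3 <- function(profile) {
  n <- length(profile)
  if (n < 3) mibg_error("EmptySlice", "radial profile shorter than 3 samples")
  m <- (profile[1:(n - 2)] + profile[2:(n - 1)] + profile[3:n]) / 3
  max(m)
}

#' Build a myocardial polar map from a short-axis volume
#'
#' Maps apex-to-base short-axis slices onto concentric rings (contiguous
#' slice groups, apex first) and divides each ring into equal angular
#' sectors. For every slice and sector, counts are sampled by bilinear
#' interpolation along the radial ray from the myocardial center at 1-voxel
#' steps; the sector value is [sector_max3()] of that profile, averaged over
#' the ring's slices. The map's `mean_counts` (and its `total_counts`) is
#' the output function of the SPECT uptake index.
#'
#' @param sa_volume short-axis volume (array, `recon_volume`, or the list
#'   returned by [reorient_short_axis()]).
#' @param geometry a `short_axis_geometry` (taken from `sa_volume` when it
#'   carries one).
#' @param rings number of rings (default 10).
#' @param sectors sectors per ring (default 36).
#' @return object of class `polar_map`: list with `values`
#'   (rings x sectors matrix), `mean_counts`, `total_counts`, `rings`,
#'   `sectors`.
#' @export
build_polar_map <- function(sa_volume, geometry = NULL, rings = 10L,
                            sectors = 36L) {
  if (is.list(sa_volume) && !is.null(sa_volume$geometry)) {
    if (is.null(geometry)) geometry <- sa_volume$geometry
    sa_volume <- sa_volume$volume
  }
  vox <- if (is.list(sa_volume)) sa_volume$voxels else sa_volume
  stopifnot(!is.null(geometry))
  d <- dim(vox)
  zr <- geometry$slice_range
  slices <- seq(zr[1], zr[2])
  if (length(slices) < rings)
    mibg_error("EmptySlice",
               sprintf("slice range (%d slices) shorter than %d rings",
                       length(slices), rings))
  ring_of <- as.integer(cut(seq_along(slices), rings))
  cx <- geometry$center[1]; cy <- geometry$center[2]
  r_max <- floor(min(cx - 1, d[1] - cx, cy - 1, d[2] - cy))
  if (r_max < 3)
    mibg_error("EmptySlice", "myocardial center too close to the grid edge")
  radii <- 0:r_max
  ang <- (seq_len(sectors) - 0.5) * 2 * pi / sectors

  values <- matrix(0, rings, sectors)
  for (ring in seq_len(rings)) {
    zs <- slices[ring_of == ring]
    acc <- matrix(0, length(zs), sectors)
    for (i in seq_along(zs)) {
      plane <- vox[, , zs[i]]
      for (j in seq_len(sectors)) {
        xs <- cx + radii * cos(ang[j])
        ys <- cy + radii * sin(ang[j])
        prof <- interp2(plane, xs, ys)
        acc[i, j] <- sector_max3(prof)
      }
    }
    values[ring, ] <- colMeans(acc)
  }
  structure(list(values = values, mean_counts = mean(values),
                 total_counts = sum(values),
                 rings = rings, sectors = sectors),
            class = "polar_map")
}

interp2 <- function(plane, x, y) {
  d <- dim(plane)
  x0 <- floor(x); y0 <- floor(y)
  ok <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2]
  x <- x[ok]; y <- y[ok]; x0 <- x0[ok]; y0 <- y0[ok]
  fx <- x - x0; fy <- y - y0
  plane[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    plane[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    plane[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    plane[cbind(x0 + 1, y0 + 1)] * fx * fy
}
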