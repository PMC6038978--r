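#' Digital-phantom configuration
#'
#' Bundles the acquisition geometry, bolus kinetics and organ layout used by
#' all phantom generators. Defaults mirror a routine 111 MBq MIBG protocol:
#' a 2-min dynamic chest acquisition (120 frames of 1 s, 128x128 matrix,
#' 3.3 mm pixels), a 5-min static planar image (256x256) and a 60-view/360
#' degree SPECT acquisition on a 64x64 matrix.
#'
#' Organ layout is deliberately geometric (2D ellipses, 3D ellipsoids) rather
#' than anthropomorphic: positions and sizes are stored in normalized image
#' fractions so the same config drives the 128x128 dynamic and 256x256
#' static grids, and tests can substitute degenerate shapes.
#'
#' @param dynamic_size dynamic matrix side (pixels).
#' @param planar_size static planar matrix side (pixels).
#' @param volume_size SPECT voxel grid side (isotropic cube).
#' @param pixel_mm pixel/voxel spacing in mm.
#' @param frame_s dynamic frame duration, seconds.
#' @param n_frames number of dynamic frames.
#' @param planar_duration_s static planar acquisition time, seconds.
#' @param dose injected-dose scale (arbitrary activity units; 1 corresponds
#'   to the nominal 111 MBq injection).
#' @param bolus list of first-pass bolus parameters: amplitude `K`
#'   (counts/pixel/frame at unit dose), shape `alpha`, time scale `beta` (s),
#'   arrival `t0` (s), recirculation fraction `kappa` in `[0,1)` and
#'   recirculation delay `delay` (s).
#' @param organs named list of organ geometries; see
#'   [default_organ_layout()]. Values are additive activity contributions on
#'   top of the soft-tissue background except the pulmonary-artery disk,
#'   which carries the pure bolus curve.
#' @param counts_scale list of per-channel count scales: `planar`
#'   (counts/pixel per unit concentration for the full static acquisition)
#'   and `spect` (counts/bin per unit line integral per view).
#' @param noise logical; apply Poisson counting noise in the generators.
#' @param seed default random seed for the generators.
#' @return an object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(dynamic_size = 128L,
                           planar_size = 256L,
                           volume_size = 64L,
                           pixel_mm = 3.3,
                           frame_s = 1,
                           n_frames = 120L,
                           planar_duration_s = 300,
                           dose = 1,
                           bolus = list(K = 13, alpha = 3, beta = 1.5,
                                        t0 = 8, kappa = 0.3, delay = 12),
                           organs = default_organ_layout(),
                           counts_scale = list(planar = 150, spect = 30),
                           noise = TRUE,
                           seed = 1L) {
  sizes <- c(dynamic_size, planar_size, volume_size, pixel_mm, frame_s,
             n_frames, planar_duration_s)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    mibg_error("InvalidConfig", "all sizes and durations must be positive")
  if (dose < 0)
    mibg_error("InvalidConfig", "dose must be nonnegative")
  stopifnot(is.list(bolus), is.list(organs))
  if (bolus$kappa < 0 || bolus$kappa >= 1)
    mibg_error("InvalidConfig", "recirculation fraction must lie in [0, 1)")
  ratios <- vapply(organs, function(o) o$value, numeric(1))
  if (any(ratios < 0))
    mibg_error("InvalidConfig", "organ concentration ratios must be >= 0")
  structure(list(
    dynamic_size = as.integer(dynamic_size),
    planar_size = as.integer(planar_size),
    volume_size = as.integer(volume_size),
    pixel_mm = pixel_mm, frame_s = frame_s,
    n_frames = as.integer(n_frames),
    planar_duration_s = planar_duration_s,
    dose = dose, bolus = bolus, organs = organs,
    counts_scale = counts_scale, noise = isTRUE(noise),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Default organ layout for the chest phantom
#'
#' Anterior-view 2D layout (fractions of the image: `fx` across columns from
#' the image left, `fy` down rows) plus the 3D myocardial shell for the SPECT
#' channel. The heart sits left of the patient's midline, i.e. right of the
#' image midline in the anterior view. `value` is the organ's activity
#' contribution relative to the soft-tissue background (1.0); the myocardial
#' contribution is multiplied by the per-subject myocardial concentration.
#'
#' @return named list of organ descriptors.
#' @export
default_organ_layout <- function() {
  list(
    body = list(shape = "ellipse", cx = 0.50, cy = 0.55,
                rx = 0.45, ry = 0.42, value = 1.0),
    lung_right = list(shape = "ellipse", cx = 0.32, cy = 0.42,
                      rx = 0.15, ry = 0.22, value = 0.2),
    lung_left = list(shape = "ellipse", cx = 0.70, cy = 0.42,
                     rx = 0.14, ry = 0.22, value = 0.2),
    pulmonary_artery = list(shape = "disk", cx = 0.55, cy = 0.38,
                            r = 0.025, value = 1.0),
    mediastinum = list(shape = "rect", cx = 0.50, cy = 0.22,
                       hw = 0.04, hh = 0.10, value = 0.0),
    heart = list(shape = "disk", cx = 0.62, cy = 0.56,
                 r = 0.085, value = 1.0),
    liver = list(shape = "ellipse", cx = 0.35, cy = 0.80,
                 rx = 0.20, ry = 0.11, value = 1.2),
    # 3D myocardial shell: semi-axes in voxel-fraction units, long axis z.
    myo3d = list(center = c(0.5, 0.5, 0.5),
                 outer = c(0.18, 0.18, 0.26),
                 inner = c(0.11, 0.11, 0.19),
                 angles_deg = c(phi = 0, theta = 0),
                 value = 1.0),
    body3d = list(center = c(0.5, 0.5, 0.5),
                  radii = c(0.40, 0.40, 0.46), value = 0.05)
  )
}

# Pixel-center fractional coordinate grids for an n x n image.
frac_grid <- function(n) {
  f <- (seq_len(n) - 0.5) / n
  list(fx = matrix(f, n, n, byrow = TRUE), fy = matrix(f, n, n))
}

# Logical mask of a 2D organ on an n x n grid.
organ_mask_2d <- function(organ, n) {
  g <- frac_grid(n)
  switch(organ$shape,
    ellipse = ((g$fx - organ$cx) / organ$rx)^2 +
              ((g$fy - organ$cy) / organ$ry)^2 <= 1,
    disk = (g$fx - organ$cx)^2 + (g$fy - organ$cy)^2 <= organ$r^2,
    rect = abs(g$fx - organ$cx) <= organ$hw &
           abs(g$fy - organ$cy) <= organ$hh,
    mibg_error("InvalidConfig", paste("unknown organ shape:", organ$shape))
  )
}
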