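# Shared fixture builders. Everything is generated in code; configs are the
# protocol defaults unless a test needs a degenerate layout.

noiseless_config <- function(...) phantom_config(noise = FALSE, ...)

# Layout with lungs/liver switched off and the mediastinum left at pure
# background, so planar region means are exactly by-construction:
# heart pixel = 1 + concentration, mediastinum pixel = 1.
clean_planar_config <- function() {
  org <- default_organ_layout()
  org$lung_right$value <- 0
  org$lung_left$value <- 0
  org$liver$value <- 0
  phantom_config(noise = FALSE, organs = org)
}

# Ground-truth heart ROI fully interior to the heart disk.
gt_heart_rois <- function(config, radius_px = 16) {
  ctr <- mibguptake:::heart_center_px(config)
  n <- config$planar_size
  structure(list(
    heart = list(center = ctr, radius_px = radius_px),
    mediastinum = list(rows = round(0.15 * n):round(0.25 * n),
                       cols = round(0.46 * n):round(0.54 * n)),
    virtual = FALSE), class = "planar_roi_set")
}

# Bare planar_image from a count matrix.
as_planar <- function(counts) {
  structure(list(counts = counts, pixel_mm = 3.3, duration_s = 300),
            class = "planar_image")
}

# Bare dynamic_series from a time x row x col array.
as_series <- function(frames, frame_s = 1) {
  structure(list(frames = frames, frame_s = frame_s, pixel_mm = 3.3,
                 times = (seq_len(dim(frames)[1]) - 0.5) * frame_s,
                 start_s = 0), class = "dynamic_series")
}

# Bare TAC.
as_tac <- function(times, counts) {
  structure(list(times = times, counts = counts), class = "tac")
}

# Uniform solid cylinder (in-plane radius r_frac, full z extent margin 4).
cylinder_volume <- function(n = 64, r_frac = 0.3, value = 1) {
  f <- seq_len(n) - (n + 1) / 2
  d2 <- outer(f^2, f^2, "+")
  plane <- d2 <= (r_frac * n)^2
  vox <- array(0, c(n, n, n))
  for (k in 5:(n - 4)) vox[, , k] <- plane * value
  vox
}

# Smooth random volume supported inside the field-of-view cylinder.
random_fov_volume <- function(n = 64, seed = 1) {
  set.seed(seed)
  vox <- array(stats::runif(n^3), c(n, n, n))
  # cheap smoothing by averaging shifted copies
  for (s in 1:2) {
    vox <- (vox +
      vox[c(2:n, n), , ] + vox[c(1, 1:(n - 1)), , ] +
      vox[, c(2:n, n), ] + vox[, c(1, 1:(n - 1)), ] +
      vox[, , c(2:n, n)] + vox[, , c(1, 1:(n - 1))]) / 7
  }
  f <- seq_len(n) - (n + 1) / 2
  d2 <- outer(f^2, f^2, "+")
  keep <- d2 <= (0.42 * n)^2
  for (k in seq_len(n)) vox[, , k] <- vox[, , k] * keep
  vox
}

expect_mibg_error <- function(expr, class) {
  expect_error(expr, class = class)
}
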