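#' Simulate a first-pass dynamic chest series
#'
#' Builds the 2-min anterior dynamic acquisition: the pulmonary-artery disk
#' carries the pure bolus curve (gamma variate plus a delayed, scaled
#' recirculation copy); lungs, myocardium, liver and soft tissue follow
#' slower uptake curves added on top of the body background. All organ
#' curves are zero before bolus arrival, so pre-bolus frames are true
#' baseline. Poisson noise is applied per pixel and frame when the config's
#' noise flag is set.
#'
#' @param config a [phantom_config()].
#' @param seed random seed for the noise stage (defaults to the config's).
#' @param myocardial_concentration per-subject myocardial concentration in
#'   the same arbitrary units used across all of that subject's channels.
#' @return object of class `dynamic_series`: list with `frames`
#'   (time x row x col array of counts), `frame_s`, `pixel_mm`, `times`
#'   (frame midpoints, s).
#' @export
make_dynamic_series <- function(config, seed = config$seed,
                                myocardial_concentration = 1) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$dynamic_size
  nt <- config$n_frames
  t_mid <- (seq_len(nt) - 0.5) * config$frame_s
  b <- config$bolus
  org <- config$organs
  dose <- config$dose

  # Slow post-bolus organ kinetics (counts/pixel/frame at unit dose).
  after <- pmax(t_mid - b$t0, 0)
  ramp <- function(tau) (1 - exp(-after / tau)) * (after > 0)
  curves <- list(
    body = 6 * org$body$value * ramp(40),
    lung_right = 30 * org$lung_right$value *
      gamma_variate(t_mid, 1, 3, 5, b$t0 + 2) / (15^3 * exp(-3)),
    lung_left = 30 * org$lung_left$value *
      gamma_variate(t_mid, 1, 3, 5, b$t0 + 2) / (15^3 * exp(-3)),
    mediastinum = 2 * ramp(40),
    heart = 8 * org$heart$value * myocardial_concentration * ramp(60),
    liver = 6 * org$liver$value * ramp(60)
  )
  pa_curve <- bolus_curve(t_mid, b)

  flat <- matrix(0, nt, n * n)
  for (name in names(curves)) {
    m <- organ_mask_2d(org[[name]], n)
    flat[, m] <- flat[, m] + curves[[name]]
  }
  pa_mask <- organ_mask_2d(org$pulmonary_artery, n)
  flat[, pa_mask] <- pa_curve          # blood pool dominates: pure bolus
  flat <- flat * dose

  if (config$noise) {
    set.seed(seed)
    flat[] <- stats::rpois(length(flat), flat)
  }
  frames <- array(flat, dim = c(nt, n, n))
  structure(list(frames = frames, frame_s = config$frame_s,
                 pixel_mm = config$pixel_mm, times = t_mid,
                 start_s = 0),
            class = "dynamic_series")
}

#' Simulate the static planar chest image
#'
#' The 5-min anterior planar image acquired after the dynamic series. Organ
#' contributions are additive over the soft-tissue background (the planar
#' image is a projection), so the heart region reads
#' `background + myocardial_concentration` in relative units; the
#' mediastinal window is pure background, giving a noiseless
#' heart/mediastinum mean-count ratio of `1 + myocardial_concentration`.
#'
#' @inheritParams make_dynamic_series
#' @param myocardial_concentration myocardial concentration (>= 0).
#' @return object of class `planar_image`: list with `counts`
#'   (row x col matrix), `pixel_mm`, `duration_s`.
#' @export
make_planar_image <- function(config, myocardial_concentration = 1,
                              seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.finite(myocardial_concentration) || myocardial_concentration < 0)
    mibg_error("InvalidConfig", "myocardial concentration must be >= 0")
  n <- config$planar_size
  org <- config$organs
  img <- matrix(0, n, n)
  add <- function(organ, value) {
    m <- organ_mask_2d(organ, n)
    img[m] <<- img[m] + value
  }
  add(org$body, org$body$value)
  add(org$lung_right, org$lung_right$value)
  add(org$lung_left, org$lung_left$value)
  add(org$mediastinum, org$mediastinum$value)
  add(org$heart, org$heart$value * myocardial_concentration)
  add(org$liver, org$liver$value)
  img <- img * config$dose * config$counts_scale$planar *
    config$planar_duration_s / 300
  if (config$noise) {
    set.seed(seed)
    img[] <- stats::rpois(length(img), img)
  }
  structure(list(counts = img, pixel_mm = config$pixel_mm,
                 duration_s = config$planar_duration_s),
            class = "planar_image")
}

#' Build the ground-truth myocardial activity volume
#'
#' An ellipsoidal myocardial shell (long axis along z by default, tiltable
#' via the config's `myo3d$angles_deg`) at the requested concentration over
#' a faint body background, on an isotropic voxel cube. An optional angular
#' defect scales shell voxels within the given azimuthal wedge by
#' `(1 - depth)`.
#'
#' @inheritParams make_planar_image
#' @param defect_spec optional list with `center_deg`, `extent_deg` in
#'   `[0, 360]` and `depth` in `[0, 1]`.
#' @return object of class `activity_volume`: list with `voxels`
#'   (x,y,z array, activity/mL), `voxel_mm`, `myo_mask` (logical array),
#'   `myo_concentration`.
#' @export
make_myocardial_volume <- function(config, myocardial_concentration = 1,
                                   defect_spec = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.finite(myocardial_concentration) || myocardial_concentration < 0)
    mibg_error("InvalidConfig", "myocardial concentration must be >= 0")
  n <- config$volume_size
  f <- (seq_len(n) - 0.5) / n
  X <- array(rep(f, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(f, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(f, each = n * n), dim = c(n, n, n))

  myo <- config$organs$myo3d
  ang <- myo$angles_deg
  ctr <- myo$center
  # rotate coordinates into the shell frame: axis = Rz(phi) Ry(theta) e_z
  R <- rot_z(ang[["phi"]]) %*% rot_y(ang[["theta"]])
  P <- rbind(as.vector(X) - ctr[1], as.vector(Y) - ctr[2],
             as.vector(Z) - ctr[3])
  Q <- t(R) %*% P
  inside <- function(radii)
    (Q[1, ] / radii[1])^2 + (Q[2, ] / radii[2])^2 +
    (Q[3, ] / radii[3])^2 <= 1
  shell <- inside(myo$outer) & !inside(myo$inner)
  mask <- array(shell, dim = c(n, n, n))

  vox <- array(0, dim = c(n, n, n))
  body <- config$organs$body3d
  bmask <- ((X - body$center[1]) / body$radii[1])^2 +
           ((Y - body$center[2]) / body$radii[2])^2 +
           ((Z - body$center[3]) / body$radii[3])^2 <= 1
  vox[bmask] <- body$value
  vox[mask] <- myo$value * myocardial_concentration

  if (!is.null(defect_spec)) {
    if (defect_spec$extent_deg < 0 || defect_spec$extent_deg > 360)
      mibg_error("InvalidConfig",
                 "defect angular extent must lie in [0, 360] degrees")
    if (defect_spec$depth < 0 || defect_spec$depth > 1)
      mibg_error("InvalidConfig", "defect depth must lie in [0, 1]")
    az <- (atan2(Q[2, ], Q[1, ]) * 180 / pi) %% 360
    d <- pmin(abs(az - defect_spec$center_deg),
              360 - abs(az - defect_spec$center_deg))
    hit <- shell & d <= defect_spec$extent_deg / 2
    vox[array(hit, dim = c(n, n, n))] <-
      vox[array(hit, dim = c(n, n, n))] * (1 - defect_spec$depth)
  }
  structure(list(voxels = vox, voxel_mm = config$pixel_mm,
                 myo_mask = mask,
                 myo_concentration = myo$value * myocardial_concentration),
            class = "activity_volume")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Parallel-beam forward projection of an activity volume
#'
#' Idealized emission acquisition: each view is the parallel line integral of
#' the volume rotated about the z (slice) axis, computed with bilinear
#' in-plane interpolation — no attenuation, scatter or depth-dependent blur.
#' Counts are the line integrals scaled by the config-level SPECT count
#' scale; Poisson noise is drawn iff a seed is given.
#'
#' Count conservation holds for activity inside the inscribed field-of-view
#' cylinder (the standard tomographic support assumption); mass rotated
#' outside the grid is clipped.
#'
#' @param volume an `activity_volume` (or bare 3D array).
#' @param n_views number of views, uniformly covering `[0, 360)` degrees.
#' @param seed optional seed; when given, Poisson noise is applied.
#' @param counts_scale counts per unit line integral per view.
#' @return object of class `projection_set`: list with `views`
#'   (view x bin x slice array), `angles_deg`, `time_per_view_s`.
#' @export
forward_project <- function(volume, n_views = 60L, seed = NULL,
                            counts_scale = 1) {
  vox <- if (inherits(volume, "activity_volume")) volume$voxels else volume
  stopifnot(length(dim(vox)) == 3)
  if (n_views < 1) mibg_error("InvalidConfig", "n_views must be >= 1")
  n <- dim(vox)[1]
  angles <- (seq_len(n_views) - 1) * 360 / n_views
  A <- projector_matrix(n, angles)
  X <- matrix(vox, n * n, dim(vox)[3])          # in-plane voxels x slices
  P <- as.matrix(A %*% X) * counts_scale        # (view*bin) x slice
  views <- array(P, dim = c(n, n_views, dim(vox)[3]))  # bin, view, slice
  views <- aperm(views, c(2, 1, 3))
  if (!is.null(seed)) {
    set.seed(seed)
    views[] <- stats::rpois(length(views), views)
  }
  structure(list(views = views, angles_deg = angles,
                 time_per_view_s = 20),
            class = "projection_set")
}

# Sparse projection operator for one in-plane slice: rows are (bin within
# view, view), columns in-plane voxels. Bilinear rotate-and-sum; cached per
# (n, angles) in the package environment.
.proj_cache <- new.env(parent = emptyenv())

projector_matrix <- function(n, angles_deg) {
  key <- paste0(n, ":", paste(round(angles_deg, 6), collapse = ","))
  if (!is.null(.proj_cache[[key]])) return(.proj_cache[[key]])
  ctr <- (n + 1) / 2
  gx <- rep(seq_len(n), times = n)   # column index of target grid
  gy <- rep(seq_len(n), each = n)    # row index
  blocks <- vector("list", length(angles_deg))
  for (k in seq_along(angles_deg)) {
    a <- angles_deg[k] * pi / 180
    # source coords: rotate target grid by -a about the center
    xs <- cos(a) * (gx - ctr) + sin(a) * (gy - ctr) + ctr
    ys <- -sin(a) * (gx - ctr) + cos(a) * (gy - ctr) + ctr
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0;  fy <- ys - y0
    tgt_bin <- gx                     # integrate along rows -> bins = columns
    ii <- integer(0); jj <- integer(0); ww <- numeric(0)
    for (corner in 1:4) {
      cx <- x0 + (corner == 2 | corner == 4)
      cy <- y0 + (corner >= 3)
      wx <- if (corner == 2 || corner == 4) fx else 1 - fx
      wy <- if (corner >= 3) fy else 1 - fy
      w <- wx * wy
      ok <- cx >= 1 & cx <= n & cy >= 1 & cy <= n & w > 0
      ii <- c(ii, tgt_bin[ok])
      jj <- c(jj, (cx[ok] - 1) * n + cy[ok])
      ww <- c(ww, w[ok])
    }
    blocks[[k]] <- Matrix::sparseMatrix(i = ii, j = jj, x = ww,
                                        dims = c(n, n * n))
  }
  A <- do.call(rbind, blocks)
  .proj_cache[[key]] <- A
  A
}

#' Generate one complete subject phantom
#'
#' Produces the dynamic series, static planar image, ground-truth volume and
#' SPECT projections for one subject from a single injected-dose scale and
#' myocardial concentration, so uptake indices computed from different
#' channels are comparable.
#'
#' @inheritParams make_planar_image
#' @param id subject identifier.
#' @param group `"LBD"` or `"non-LBD"`.
#' @param concentration true myocardial concentration.
#' @param defect_spec optional defect passed to [make_myocardial_volume()].
#' @return object of class `subject_phantom`.
#' @export
make_subject_phantom <- function(config, id, group, concentration,
                                 seed = config$seed, defect_spec = NULL) {
  if (!group %in% c("LBD", "non-LBD"))
    mibg_error("InvalidConfig", "group must be 'LBD' or 'non-LBD'")
  vol <- make_myocardial_volume(config, concentration, defect_spec)
  proj <- forward_project(vol, 60L,
                          seed = if (config$noise) seed + 1L else NULL,
                          counts_scale = config$counts_scale$spect *
                            config$dose)
  structure(list(
    id = id, group = group, true_concentration = concentration,
    dynamic = make_dynamic_series(config, seed = seed,
                                  myocardial_concentration = concentration),
    planar = make_planar_image(config, concentration, seed = seed + 2L),
    projections = proj,
    truth = list(
      pa_center = pa_center_px(config),
      heart_center = heart_center_px(config),
      myo_angles_deg = config$organs$myo3d$angles_deg
    )
  ), class = "subject_phantom")
}

pa_center_px <- function(config) {
  o <- config$organs$pulmonary_artery
  c(row = o$cy * config$dynamic_size + 0.5,
    col = o$cx * config$dynamic_size + 0.5)
}
heart_center_px <- function(config) {
  o <- config$organs$heart
  c(row = o$cy * config$planar_size + 0.5,
    col = o$cx * config$planar_size + 0.5)
}

#' Draw per-group true myocardial concentrations
#'
#' Log-normal law matched to a group's reported median and interquartile
#' range: `mu = log(median)`, `sigma = log(q3/q1) / (2 * qnorm(0.75))`.
#'
#' @param n number of draws.
#' @param median group median.
#' @param iqr length-2 numeric `(q1, q3)`.
#' @return numeric vector of positive concentrations.
#' @export
draw_concentrations <- function(n, median, iqr) {
  if (median <= 0 || any(iqr <= 0) || iqr[2] <= iqr[1])
    mibg_error("InvalidConfig", "distribution scale must be positive")
  sigma <- log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))
  stats::rlnorm(n, meanlog = log(median), sdlog = sigma)
}

#' Default group distribution parameters
#'
#' Median and IQR of the true SPECT uptake scale for the two diagnostic
#' groups: LBD median 0.63 (IQR 0.52-0.82), non-LBD median 1.70
#' (IQR 1.53-2.03).
#' @return named list with `lbd` and `nonlbd` components.
#' @export
default_group_params <- function() {
  list(lbd = list(median = 0.63, iqr = c(0.52, 0.82)),
       nonlbd = list(median = 1.70, iqr = c(1.53, 2.03)))
}

#' Generate a labelled phantom cohort
#'
#' Draws each subject's true myocardial concentration from its group's
#' log-normal law and generates the full image set per subject. With the
#' default sizes (37 LBD / 40 non-LBD) this is the package's standard
#' simulated study.
#'
#' @param n_lbd,n_nonlbd group sizes.
#' @param config a [phantom_config()].
#' @param group_params list as returned by [default_group_params()].
#' @param seed base seed; subject `i` uses `seed + 100 * i` internally.
#' @return list of `subject_phantom` objects.
#' @export
make_cohort <- function(n_lbd = 37L, n_nonlbd = 40L,
                        config = phantom_config(),
                        group_params = default_group_params(),
                        seed = 1L) {
  conc <- cohort_concentrations(n_lbd, n_nonlbd, group_params, seed)
  lapply(seq_len(nrow(conc)), function(i)
    make_subject_phantom(config, id = conc$id[i], group = conc$group[i],
                         concentration = conc$concentration[i],
                         seed = seed + 100L * i))
}

# Deterministic per-cohort concentration table (used by make_cohort and the
# streaming cohort runner).
cohort_concentrations <- function(n_lbd, n_nonlbd, group_params, seed) {
  stopifnot(n_lbd >= 0, n_nonlbd >= 0)
  set.seed(seed)
  c_lbd <- if (n_lbd > 0)
    draw_concentrations(n_lbd, group_params$lbd$median,
                        group_params$lbd$iqr) else numeric(0)
  c_non <- if (n_nonlbd > 0)
    draw_concentrations(n_nonlbd, group_params$nonlbd$median,
                        group_params$nonlbd$iqr) else numeric(0)
  data.frame(
    id = sprintf("S%03d", seq_len(n_lbd + n_nonlbd)),
    group = c(rep("LBD", n_lbd), rep("non-LBD", n_nonlbd)),
    concentration = c(c_lbd, c_non),
    stringsAsFactors = FALSE
  )
}
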