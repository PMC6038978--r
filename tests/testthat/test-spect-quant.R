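test_that("OSEM handles degenerate projections and subset mismatch", {
  zero <- structure(list(views = array(0, c(60, 32, 32)),
                         angles_deg = (0:59) * 6, time_per_view_s = 20),
                    class = "projection_set")
  rec <- osem_reconstruct(zero, 4, 2)
  expect_true(all(rec$voxels == 0))
  expect_mibg_error(osem_reconstruct(zero, subsets = 7), "IndivisibleSubsets")
})

test_that("OSEM converges monotonically and reprojects consistent data", {
  vox <- cylinder_volume(64, 0.25, value = 2)
  proj <- forward_project(vox, 60)
  nrmse <- numeric(0)
  rec <- osem_reconstruct(proj, 4, 10, callback = function(v, it)
    nrmse[it] <<- sqrt(mean((v - vox)^2)) / mean(vox))
  expect_true(all(diff(nrmse) < 0))
  expect_true(all(rec$voxels >= 0))
  rec30 <- osem_reconstruct(proj, 4, 30)
  reproj <- forward_project(rec30$voxels, 60)
  expect_lt(abs(sum(reproj$views) / sum(proj$views) - 1), 0.01)
})

test_that("OSEM data likelihood is non-decreasing on noiseless data", {
  vox <- cylinder_volume(32, 0.3, value = 1)[, , 1:8]
  proj <- forward_project(vox, 12)
  ll <- numeric(0)
  osem_reconstruct(proj, 4, 8, callback = function(v, it)
    ll[it] <<- mibguptake:::projection_loglik(proj, v))
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
})

test_that("short-axis reorientation recovers known orientations", {
  cfg <- noiseless_config()
  vol <- make_myocardial_volume(cfg, 1)
  # identity geometry leaves the volume unchanged
  geom <- structure(list(center = c(32.5, 32.5, 32.5),
                         angles_deg = c(phi = 0, theta = 0),
                         slice_range = NULL, virtual = FALSE),
                    class = "short_axis_geometry")
  out <- reorient_short_axis(vol, geometry = geom)
  expect_lt(max(abs(out$volume - vol$voxels)), 1e-6 * max(vol$voxels))
  # known (20, 10) rotation is recovered within 5 degrees
  rot <- rotate_volume(vol, 20, 10)
  est <- reorient_short_axis(rot)$geometry$angles_deg
  expect_lt(abs(est[["phi"]] - 20), 5)
  expect_lt(abs(est[["theta"]] - 10), 5)
  # isotropic source without template is undetermined
  f <- (1:64) - 32.5
  S <- sqrt(outer(outer(f^2, f^2, "+"), f^2, "+"))
  sphere <- array(as.numeric(S >= 8 & S <= 12), c(64, 64, 64))
  expect_mibg_error(reorient_short_axis(sphere), "AxisUndetermined")
  # ... but a template makes it a virtual reorientation
  tmpl <- mibguptake:::default_sa_template(64, cfg$organs$myo3d)
  vr <- reorient_short_axis(sphere, template = tmpl)
  expect_true(vr$geometry$virtual)
})

test_that("sector rule is the maximum 3-sample running mean", {
  expect_equal(sector_max3(c(0, 10, 20, 10, 0)), 40 / 3)
  expect_equal(sector_max3(c(1, 1, 1)), 1)
  expect_mibg_error(sector_max3(c(1, 2)), "EmptySlice")
})

test_that("polar map of a uniform shell is uniform and linear in dose", {
  cfg <- noiseless_config()
  sa <- reorient_short_axis(make_myocardial_volume(cfg, 1))
  pm <- build_polar_map(sa)
  expect_equal(dim(pm$values), c(10, 36))
  expect_lt(stats::sd(pm$values) / mean(pm$values), 0.02)
  expect_equal(pm$mean_counts, mean(pm$values))
  expect_equal(pm$total_counts, sum(pm$values))
  # polar-map mean is linear in shell concentration
  concs <- c(0.5, 1, 2, 3)
  means <- vapply(concs, function(cc)
    build_polar_map(reorient_short_axis(
      make_myocardial_volume(cfg, cc)))$mean_counts, numeric(1))
  expect_gt(stats::cor(means, concs), 0.999)
})

test_that("polar map recovers an angular defect's depth", {
  cfg <- noiseless_config()
  vol <- make_myocardial_volume(cfg, 1,
                                defect_spec = list(center_deg = 90,
                                                   extent_deg = 90,
                                                   depth = 0.25))
  pm <- build_polar_map(reorient_short_axis(vol))
  sec_ang <- (seq_len(36) - 0.5) * 10
  inside <- abs(sec_ang - 90) <= 30       # fully inside the defect
  remote <- abs(sec_ang - 90) > 60
  mid <- 3:8                               # rings away from apex/base caps
  ratio <- mean(pm$values[mid, inside]) / mean(pm$values[mid, remote])
  expect_lt(abs(ratio - 0.75), 0.05 * 0.75)
})

test_that("polar map rejects an insufficient slice range", {
  vol <- array(1, c(16, 16, 16))
  geom <- structure(list(center = c(8.5, 8.5, 8.5),
                         angles_deg = c(phi = 0, theta = 0),
                         slice_range = c(7, 9), virtual = FALSE),
                    class = "short_axis_geometry")
  expect_mibg_error(build_polar_map(vol, geom, rings = 10), "EmptySlice")
})

test_that("CF calibration fits the through-origin slope", {
  x <- c(10, 20, 30, 40, 50)
  cal <- calibrate_cf(x, 1.7 * x)
  expect_equal(cal$cf, 1.7)
  expect_equal(cal$r, 1.0)
  set.seed(12)
  x <- runif(50, 50, 500)
  y <- 2 * x * (1 + rnorm(50, 0, 0.05))
  cal <- calibrate_cf(x, y)
  expect_gt(cal$cf, 1.9); expect_lt(cal$cf, 2.1)
  expect_mibg_error(calibrate_cf(c(1, 2), c(2, 4)), "TooFewPairs")
  expect_mibg_error(calibrate_cf(c(0, 0, 0), c(1, 2, 3)), "DegenerateX")
})

test_that("SPECT uptake index applies the conversion and AUC", {
  pm <- structure(list(values = matrix(5000, 1, 1), mean_counts = 5000,
                       total_counts = 5000, rings = 1, sectors = 1),
                  class = "polar_map")
  # effective conversion 1/cf = 0.8
  res <- spect_uptake_index(pm, calibration = 1.25, input_auc = 4000,
                            scale = 1)
  expect_equal(res$index, 1.0)
  expect_mibg_error(spect_uptake_index(pm, 0, 4000), "InvalidCalibration")
  expect_mibg_error(spect_uptake_index(pm, 1.25, 0), "ZeroAuc")
})
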