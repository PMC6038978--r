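test_that("zero injected dose gives identically zero dynamic frames", {
  cfg <- phantom_config(dose = 0, noise = FALSE)
  ds <- make_dynamic_series(cfg)
  expect_true(all(ds$frames == 0))
})

test_that("noiseless pulmonary-artery pixels follow the bolus model exactly", {
  cfg <- noiseless_config()
  ds <- make_dynamic_series(cfg)
  ctr <- round(mibguptake:::pa_center_px(cfg))
  trace <- ds$frames[, ctr[["row"]], ctr[["col"]]]
  b <- cfg$bolus
  expected <- gamma_variate(ds$times, b$K, b$alpha, b$beta, b$t0) +
    b$kappa * gamma_variate(ds$times, b$K, b$alpha, b$beta, b$t0 + b$delay)
  expect_equal(trace, expected, tolerance = 1e-12)
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- phantom_config(noise = TRUE)
  expect_identical(make_dynamic_series(cfg, seed = 42)$frames,
                   make_dynamic_series(cfg, seed = 42)$frames)
  expect_identical(make_planar_image(cfg, 1.3, seed = 42)$counts,
                   make_planar_image(cfg, 1.3, seed = 42)$counts)
  p1 <- forward_project(make_myocardial_volume(cfg, 1), seed = 42)
  p2 <- forward_project(make_myocardial_volume(cfg, 1), seed = 42)
  expect_identical(p1$views, p2$views)
})

test_that("all generator outputs are nonnegative", {
  cfg <- phantom_config(noise = TRUE)
  expect_true(all(make_dynamic_series(cfg, seed = 3)$frames >= 0))
  expect_true(all(make_planar_image(cfg, 0.7, seed = 3)$counts >= 0))
  vol <- make_myocardial_volume(cfg, 0.7)
  expect_true(all(vol$voxels >= 0))
  expect_true(all(forward_project(vol, seed = 3)$views >= 0))
})

test_that("planar heart/mediastinum contrast is by construction", {
  cfg <- clean_planar_config()
  img <- make_planar_image(cfg, 1)          # heart = 2 x background
  rois <- gt_heart_rois(cfg)
  expect_equal(hm_ratio(img, rois), 2.0, tolerance = 1e-12)
  img0 <- make_planar_image(cfg, 0)
  m <- mibguptake:::planar_means(img0, rois)
  expect_equal(m$heart, m$mediastinum, tolerance = 1e-12)
})

test_that("Poisson noise stage is unbiased at lambda 100", {
  # constant-100 image through the generator's noise path
  org <- default_organ_layout()
  for (nm in setdiff(names(org), c("body", "myo3d", "body3d")))
    org[[nm]]$value <- 0
  org$body <- list(shape = "rect", cx = 0.5, cy = 0.5, hw = 0.5, hh = 0.5,
                   value = 1)
  cfg <- phantom_config(organs = org, noise = TRUE,
                        counts_scale = list(planar = 100, spect = 30))
  img <- make_planar_image(cfg, 0, seed = 11)
  expect_equal(mean(img$counts), 100, tolerance = 0.01)
})

test_that("myocardial volume has exact shell values and total activity", {
  org <- default_organ_layout()
  org$body3d$value <- 0
  cfg <- phantom_config(noise = FALSE, organs = org)
  conc <- 1.4
  vol <- make_myocardial_volume(cfg, conc)
  expect_true(all(vol$voxels[vol$myo_mask] == conc))
  expect_equal(sum(vol$voxels), conc * sum(vol$myo_mask))
  # angular defect scales shell voxels by (1 - depth)
  vd <- make_myocardial_volume(cfg, conc,
                               defect_spec = list(center_deg = 90,
                                                  extent_deg = 90,
                                                  depth = 0.25))
  vals <- vd$voxels[vd$myo_mask]
  expect_setequal(round(unique(vals), 10), round(c(conc, 0.75 * conc), 10))
  expect_mibg_error(
    make_myocardial_volume(cfg, 1, list(center_deg = 0, extent_deg = 400,
                                        depth = 0.1)),
    "InvalidConfig")
})

test_that("noiseless projector conserves counts and respects symmetry", {
  vox <- random_fov_volume(64, seed = 5)
  proj <- forward_project(vox, 60)
  view_sums <- apply(proj$views, 1, sum)
  expect_true(all(abs(view_sums / sum(vox) - 1) < 0.005))
  # centered point source (tight Gaussian blob) projects identically in
  # every view
  f <- seq_len(64) - 32.5
  blob <- exp(-outer(f^2, f^2, "+") / (2 * 1.5^2))
  pt <- array(0, c(64, 64, 64)); pt[, , 32] <- blob
  pp <- forward_project(pt, 60)
  per_view <- apply(pp$views, 1, sum)
  expect_true(max(abs(per_view / mean(per_view) - 1)) < 0.005)
  # zero volume -> zero projections
  expect_true(all(forward_project(array(0, c(64, 64, 64)), 60)$views == 0))
})

test_that("cohort generation matches requested sizes and group law", {
  conc <- mibguptake:::cohort_concentrations(37, 40,
                                             default_group_params(), 7)
  expect_equal(nrow(conc), 77)
  expect_equal(sum(conc$group == "LBD"), 37)
  expect_equal(sum(conc$group == "non-LBD"), 40)
  expect_identical(conc,
                   mibguptake:::cohort_concentrations(37, 40,
                                                      default_group_params(),
                                                      7))
  # large-n sample medians within 3% of the configured medians
  set.seed(1)
  gp <- default_group_params()
  m_lbd <- median(draw_concentrations(2000, gp$lbd$median, gp$lbd$iqr))
  m_non <- median(draw_concentrations(2000, gp$nonlbd$median,
                                      gp$nonlbd$iqr))
  expect_lt(abs(m_lbd / gp$lbd$median - 1), 0.03)
  expect_lt(abs(m_non / gp$nonlbd$median - 1), 0.03)
  expect_mibg_error(draw_concentrations(5, -1, c(1, 2)), "InvalidConfig")
})

test_that("invalid phantom configs are rejected", {
  expect_mibg_error(phantom_config(dynamic_size = -1), "InvalidConfig")
  expect_mibg_error(phantom_config(bolus = list(K = 1, alpha = 1, beta = 1,
                                                t0 = 0, kappa = 1.2,
                                                delay = 5)),
                    "InvalidConfig")
  expect_mibg_error(make_planar_image(noiseless_config(), -0.5),
                    "InvalidConfig")
})
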