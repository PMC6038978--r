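#' Analysis configuration for the quantification pipeline
#'
#' @param scale display scale applied to both uptake indices.
#' @param rings,sectors polar-map dimensions.
#' @param subsets,iterations OSEM parameters.
#' @param cf fixed conversion factor (a `calibration_model` or positive
#'   number); `NULL` until calibrated.
#' @param n_calibration size of the separate noiseless calibration cohort
#'   used when `calibration = "separate"` in [run_cohort()].
#' @return object of class `run_config`.
#' @export
run_config <- function(scale = 10, rings = 10L, sectors = 36L,
                       subsets = 4L, iterations = 30L, cf = NULL,
                       n_calibration = 8L) {
  structure(list(scale = scale, rings = rings, sectors = sectors,
                 subsets = subsets, iterations = iterations, cf = cf,
                 n_calibration = n_calibration),
            class = "run_config")
}

default_sa_template <- function(n, myo3d) {
  z0 <- max(2L, floor(n * (myo3d$center[3] - myo3d$outer[3])) + 1L)
  z1 <- min(n - 1L, ceiling(n * (myo3d$center[3] + myo3d$outer[3])))
  structure(list(center = rep((n + 1) / 2, 3),
                 angles_deg = c(phi = 0, theta = 0),
                 slice_range = c(z0, z1), virtual = TRUE),
            class = "short_axis_geometry")
}

#' Quantify one subject
#'
#' Runs the full chain on one subject phantom (or partial bundle): bolus ROI
#' detection, TAC extraction, gamma-variate fit and AUC; then the planar
#' chain (heart/mediastinum ROIs, H/M, planar uptake index) and the SPECT
#' chain (OSEM, short-axis reorientation with virtual-template fallback,
#' polar map, SPECT uptake index) for whichever images are present. A
#' missing modality yields `NA` fields, never fabricated values. The SPECT
#' index is only computed when a conversion factor is available in `config`;
#' the polar-map mean is always reported so a cohort-level calibration can
#' be applied afterwards.
#'
#' @param subject a `subject_phantom` (fields `dynamic`, `planar`,
#'   `projections` may individually be `NULL`).
#' @param config a [run_config()].
#' @param phantom_cfg the [phantom_config()] used to build the subject;
#'   supplies the virtual-template geometry.
#' @return object of class `uptake_result`: list with `id`, `group`, `hm`,
#'   `planar_index`, `spect_index`, `auc`, `heart_mean`, `polar_mean`,
#'   `virtual_planar`, `virtual_spect`, `provenance`.
#' @export
run_subject <- function(subject, config = run_config(),
                        phantom_cfg = phantom_config()) {
  if (is.null(subject$dynamic))
    mibg_error("InvalidConfig", "subject has no dynamic series")
  fit <- tryCatch({
    roi <- detect_pa_roi(subject$dynamic)
    fit_gamma_variate(extract_tac(subject$dynamic, roi))
  }, mibg_error = function(e) {
    mibg_error(class(e)[1],
               sprintf("subject %s: %s", subject$id, conditionMessage(e)))
  })
  auc <- gamma_auc(fit)

  hm <- planar_index <- heart_mean <- NA_real_
  virtual_planar <- NA
  if (!is.null(subject$planar)) {
    rois <- place_heart_roi(subject$planar)
    pq <- planar_uptake_index(subject$planar, rois, auc,
                              scale = config$scale)
    hm <- pq$hm; planar_index <- pq$index
    heart_mean <- pq$heart_mean; virtual_planar <- pq$virtual
  }

  spect_index <- polar_mean <- NA_real_
  virtual_spect <- NA
  if (!is.null(subject$projections)) {
    recon <- osem_reconstruct(subject$projections,
                              subsets = config$subsets,
                              iterations = config$iterations)
    tmpl <- default_sa_template(dim(recon$voxels)[1],
                                phantom_cfg$organs$myo3d)
    sa <- reorient_short_axis(recon, template = tmpl)
    pm <- build_polar_map(sa, rings = config$rings,
                          sectors = config$sectors)
    polar_mean <- pm$mean_counts
    virtual_spect <- sa$geometry$virtual
    if (!is.null(config$cf)) {
      sq <- spect_uptake_index(pm, config$cf, auc, scale = config$scale,
                               virtual = virtual_spect)
      spect_index <- sq$index
    }
  }
  structure(list(
    id = subject$id, group = subject$group, hm = hm,
    planar_index = planar_index, spect_index = spect_index,
    auc = auc, heart_mean = heart_mean, polar_mean = polar_mean,
    virtual_planar = virtual_planar, virtual_spect = virtual_spect,
    provenance = list(
      cf = if (inherits(config$cf, "calibration_model")) config$cf$cf
           else config$cf,
      scale = config$scale,
      osem = c(subsets = config$subsets, iterations = config$iterations),
      version = as.character(utils::packageVersion("mibguptake")))
  ), class = "uptake_result")
}

#' Calibrate the conversion factor on dedicated phantoms
#'
#' Builds `n` noiseless phantoms with myocardial concentrations spread over
#' the clinical index range, quantifies the planar heart mean and polar-map
#' mean of each, and fits the through-origin slope. Keeping calibration
#' subjects separate from analysis subjects avoids leakage in simulation
#' studies; [run_cohort()]'s `calibration = "pooled"` flag reproduces the
#' pooled single-cohort behaviour instead.
#'
#' @param config a [phantom_config()] (noise is disabled internally).
#' @param run_cfg a [run_config()].
#' @param n number of calibration phantoms.
#' @param conc_range concentration range spanned.
#' @return a `calibration_model`.
#' @export
calibrate_on_phantoms <- function(config = phantom_config(),
                                  run_cfg = run_config(), n = 8L,
                                  conc_range = c(0.4, 2.8)) {
  cfg <- config
  cfg$noise <- FALSE
  conc <- seq(conc_range[1], conc_range[2], length.out = n)
  planar_counts <- numeric(n); spect_counts <- numeric(n)
  for (i in seq_len(n)) {
    img <- make_planar_image(cfg, conc[i])
    rois <- place_heart_roi(img)
    planar_counts[i] <- disk_mean(img$counts, rois$heart$center,
                                  rois$heart$radius_px)
    vol <- make_myocardial_volume(cfg, conc[i])
    proj <- forward_project(vol, 60L,
                            counts_scale = cfg$counts_scale$spect * cfg$dose)
    recon <- osem_reconstruct(proj, run_cfg$subsets, run_cfg$iterations)
    tmpl <- default_sa_template(dim(recon$voxels)[1], cfg$organs$myo3d)
    sa <- reorient_short_axis(recon, template = tmpl)
    pm <- build_polar_map(sa, rings = run_cfg$rings,
                          sectors = run_cfg$sectors)
    spect_counts[i] <- pm$mean_counts
  }
  calibrate_cf(planar_counts, spect_counts)
}

#' Run a full simulated cohort study
#'
#' Generates the labelled phantom cohort subject by subject (images are
#' discarded once quantified), calibrates the 2D-3D conversion factor
#' (separately by default, or pooled over the analysis subjects), computes
#' the three indices per subject, and assembles group summaries, overlap
#' intervals, ROC/Youden analysis and diagnostic accuracy for each method.
#' Subjects whose gamma-variate fit fails are excluded from diagnostics and
#' listed in the report.
#'
#' @param n_lbd,n_nonlbd group sizes (defaults 37 / 40).
#' @param config a [phantom_config()].
#' @param run_cfg a [run_config()].
#' @param group_params group distribution parameters, see
#'   [default_group_params()].
#' @param seed base seed for the whole study.
#' @param calibration `"separate"` (dedicated noiseless phantoms) or
#'   `"pooled"` (slope over the analysis subjects themselves).
#' @param out_dir optional directory; when given, the cohort table, ROC
#'   points and report are written as CSV/JSON.
#' @param progress print per-subject progress to stderr.
#' @return list with `table` (data.frame), `report`
#'   (class `diagnostic_report`), `calibration`, `failed` (ids), `seed`.
#' @export
run_cohort <- function(n_lbd = 37L, n_nonlbd = 40L,
                       config = phantom_config(),
                       run_cfg = run_config(),
                       group_params = default_group_params(),
                       seed = 1L,
                       calibration = c("separate", "pooled"),
                       out_dir = NULL, progress = FALSE) {
  calibration <- match.arg(calibration)
  conc <- cohort_concentrations(n_lbd, n_nonlbd, group_params, seed)
  rows <- vector("list", nrow(conc))
  failed <- character(0)
  for (i in seq_len(nrow(conc))) {
    subj <- make_subject_phantom(config, id = conc$id[i],
                                 group = conc$group[i],
                                 concentration = conc$concentration[i],
                                 seed = seed + 100L * i)
    res <- tryCatch(run_subject(subj, run_cfg, config),
                    mibg_error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, conc$id[i])
      if (progress) message("  ", conc$id[i], " FAILED: ",
                            conditionMessage(res))
      next
    }
    rows[[i]] <- data.frame(
      id = res$id, group = res$group,
      true_concentration = conc$concentration[i],
      hm = res$hm, planar_index = res$planar_index,
      auc = res$auc, heart_mean = res$heart_mean,
      polar_mean = res$polar_mean,
      virtual_planar = res$virtual_planar,
      virtual_spect = res$virtual_spect,
      stringsAsFactors = FALSE)
    if (progress) message("  ", conc$id[i], " done")
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 4)
    mibg_error("InvalidConfig", "too few successfully quantified subjects")

  cal <- if (!is.null(run_cfg$cf)) {
    if (inherits(run_cfg$cf, "calibration_model")) run_cfg$cf
    else structure(list(cf = run_cfg$cf, r = NA_real_, n = 0L),
                   class = "calibration_model")
  } else if (calibration == "separate") {
    calibrate_on_phantoms(config, run_cfg, n = run_cfg$n_calibration)
  } else {
    calibrate_cf(tab$heart_mean, tab$polar_mean)
  }
  tab$spect_index <- run_cfg$scale * tab$polar_mean / (cal$cf * tab$auc)

  report <- diagnostic_report(tab)
  report$calibration <- list(cf = cal$cf, r = cal$r, n = cal$n,
                             mode = calibration)
  report$failed_subjects <- failed
  report$seed <- seed
  if (!is.null(out_dir)) write_cohort_outputs(tab, report, out_dir)
  list(table = tab, report = report, calibration = cal,
       failed = failed, seed = seed)
}

#' Diagnostic-accuracy report over a cohort table
#'
#' For each method (H/M, planar uptake index, SPECT uptake index): group
#' summaries, overlap interval, empirical ROC AUC, Youden criterion
#' threshold and the five accuracy metrics at that threshold, plus
#' Mann-Whitney group comparisons and paired AUC comparisons between
#' methods.
#'
#' @param tab data.frame with columns `group`, `hm`, `planar_index`,
#'   `spect_index`.
#' @return object of class `diagnostic_report`.
#' @export
diagnostic_report <- function(tab) {
  methods <- c(hm = "hm", planar = "planar_index", spect = "spect_index")
  out <- list(methods = list())
  for (m in names(methods)) {
    v <- tab[[methods[[m]]]]
    keep <- is.finite(v)
    scores <- v[keep]; labels <- tab$group[keep]
    roc <- empirical_roc(scores, labels)
    yj <- youden_criterion(roc)
    met <- diagnostic_metrics(scores, labels, yj$threshold)
    lbd <- scores[labels == "LBD"]; non <- scores[labels != "LBD"]
    out$methods[[m]] <- list(
      auc = roc$auc, criterion = yj$threshold, youden_j = yj$J,
      sensitivity = met$sensitivity, specificity = met$specificity,
      ppv = met$ppv, npv = met$npv, accuracy = met$accuracy,
      lbd_summary = unclass(group_summary(lbd)),
      nonlbd_summary = unclass(group_summary(non)),
      overlap = overlap_range(lbd, non),
      mann_whitney_p = mann_whitney_u(lbd, non)$p_value,
      roc_points = roc$points)
  }
  pairs <- list(c("spect", "hm"), c("spect", "planar"), c("planar", "hm"))
  out$auc_comparisons <- lapply(pairs, function(pr) {
    keep <- is.finite(tab[[methods[[pr[1]]]]]) &
            is.finite(tab[[methods[[pr[2]]]]])
    ct <- compare_auc(tab[[methods[[pr[1]]]]][keep],
                      tab[[methods[[pr[2]]]]][keep], tab$group[keep])
    list(methods = pr, auc_difference = ct$statistic, p_value = ct$p_value)
  })
  structure(out, class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic accuracy (positive call: index below criterion)\n")
  hdr <- sprintf("%-8s %5s %9s %11s %11s %5s %5s %8s\n", "method", "AUC",
                 "criterion", "sensitivity", "specificity", "PPV", "NPV",
                 "accuracy")
  cat(hdr)
  for (m in names(x$methods)) {
    r <- x$methods[[m]]
    cat(sprintf("%-8s %5.3f %9.3f %11.2f %11.2f %5.2f %5.2f %8.2f\n",
                m, r$auc, r$criterion, r$sensitivity, r$specificity,
                r$ppv, r$npv, r$accuracy))
  }
  invisible(x)
}

write_cohort_outputs <- function(tab, report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  rows <- do.call(rbind, lapply(names(report$methods), function(m) {
    r <- report$methods[[m]]
    data.frame(method = m, auc = r$auc, sensitivity = r$sensitivity,
               specificity = r$specificity, criterion = r$criterion,
               ppv = r$ppv, npv = r$npv, accuracy = r$accuracy)
  }))
  utils::write.csv(rows, file.path(out_dir, "accuracy.csv"),
                   row.names = FALSE)
  for (m in names(report$methods))
    utils::write.csv(report$methods[[m]]$roc_points,
                     file.path(out_dir, paste0("roc_", m, ".csv")),
                     row.names = FALSE)
  slim <- report
  for (m in names(slim$methods)) slim$methods[[m]]$roc_points <- NULL
  jsonlite::write_json(unclass(slim),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
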