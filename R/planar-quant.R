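#' Place heart and mediastinum ROIs on a planar image
#'
#' Detects the cardiac uptake blob as the smoothed local maximum inside the
#' cardiac search window (the patient's left mid-chest). If the mean count
#' inside the candidate heart disk is at least `contrast_gate` times the
#' body background (median of in-body counts outside the window), the ROI is
#' anchored on the detected blob; otherwise a fixed-size template ROI is
#' placed at the default anatomical position and the result is flagged
#' *virtual* — the fallback used for low-uptake studies. The mediastinal ROI
#' is always a fixed upper-midline rectangle spanning 10% of the image
#' height.
#'
#' @param image a `planar_image`.
#' @param template optional list with `center` (row, col) and `radius_px`
#'   overriding the default template position.
#' @param contrast_gate heart/background mean-count gate (default 1.5).
#' @param search_window cardiac window as fractions
#'   `c(row_min, row_max, col_min, col_max)`.
#' @return object of class `planar_roi_set`: list with `heart`
#'   (center, radius_px), `mediastinum` (row/col ranges), `virtual` flag.
#' @export
place_heart_roi <- function(image, template = NULL, contrast_gate = 1.5,
                            search_window = c(0.40, 0.68, 0.50, 0.80)) {
  stopifnot(inherits(image, "planar_image"))
  img <- image$counts
  n_r <- nrow(img); n_c <- ncol(img)
  radius <- if (!is.null(template$radius_px)) template$radius_px
            else round(0.085 * n_c)
  default_center <- if (!is.null(template$center)) template$center
                    else c(row = 0.56 * n_r, col = 0.62 * n_c)

  sm <- box_smooth(img, 5L)
  rows <- round(search_window[1] * n_r):round(search_window[2] * n_r)
  cols <- round(search_window[3] * n_c):round(search_window[4] * n_c)
  sub <- sm[rows, cols]

  bg_mask <- img > 0
  bg_mask[rows, cols] <- FALSE
  background <- stats::median(img[bg_mask])
  if (!is.finite(background) || background <= 0) background <- Inf

  # blob center: intensity-weighted centroid of window pixels within 25%
  # of the smoothed peak (above background), not the bare argmax
  pk <- max(sub)
  bg0 <- if (is.finite(background)) background else 0
  blob <- sub - bg0 >= 0.75 * (pk - bg0) & sub > bg0
  if (any(blob)) {
    w <- (sub - bg0)[blob]
    idx <- which(blob, arr.ind = TRUE)
    cand <- c(row = rows[1] - 1 + sum(idx[, 1] * w) / sum(w),
              col = cols[1] - 1 + sum(idx[, 2] * w) / sum(w))
  } else {
    imax <- arrayInd(which.max(sub), dim(sub))
    cand <- c(row = rows[imax[1]], col = cols[imax[2]])
  }

  cand_mean <- disk_mean(img, cand, radius)
  if (is.finite(background) && cand_mean >= contrast_gate * background) {
    center <- cand; virtual <- FALSE
  } else {
    center <- default_center; virtual <- TRUE
  }
  med <- list(rows = round(0.15 * n_r):round(0.25 * n_r),
              cols = round(0.46 * n_c):round(0.54 * n_c))
  structure(list(
    heart = list(center = center, radius_px = radius),
    mediastinum = med, virtual = virtual
  ), class = "planar_roi_set")
}

box_smooth <- function(img, k) {
  # k x k box filter with replicated edges
  half <- k %/% 2
  n_r <- nrow(img); n_c <- ncol(img)
  clip <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, n_r, n_c)
  for (dr in -half:half)
    for (dc in -half:half)
      out <- out + img[clip(seq_len(n_r) + dr, n_r),
                       clip(seq_len(n_c) + dc, n_c)]
  out / k^2
}

disk_mask <- function(dim_rc, center, radius) {
  r <- matrix(seq_len(dim_rc[1]), dim_rc[1], dim_rc[2])
  c_ <- matrix(seq_len(dim_rc[2]), dim_rc[1], dim_rc[2], byrow = TRUE)
  (r - center[["row"]])^2 + (c_ - center[["col"]])^2 <= radius^2
}

disk_mean <- function(img, center, radius) {
  mean(img[disk_mask(dim(img), center, radius)])
}

#' Heart-to-mediastinum mean-count ratio
#'
#' The conventional planar MIBG metric: mean counts per pixel in the heart
#' ROI divided by mean counts per pixel in the upper-mediastinal ROI.
#'
#' @param image a `planar_image`.
#' @param rois a `planar_roi_set`.
#' @return H/M ratio (dimensionless).
#' @export
hm_ratio <- function(image, rois) {
  m <- planar_means(image, rois)
  if (m$mediastinum <= 0)
    mibg_error("ZeroMediastinum", "mediastinal mean count is zero")
  m$heart / m$mediastinum
}

planar_means <- function(image, rois) {
  img <- image$counts
  heart <- disk_mean(img, rois$heart$center, rois$heart$radius_px)
  med <- mean(img[rois$mediastinum$rows, rois$mediastinum$cols])
  list(heart = heart, mediastinum = med)
}

#' Planar uptake index
#'
#' The two-dimensional uptake index: mean heart counts per pixel divided by
#' the first-pass input AUC, times a fixed scale. Because heart counts and
#' the AUC both scale with the administered dose, the index is
#' dose-invariant and proportional to myocardial concentration.
#'
#' @param image a `planar_image`.
#' @param rois a `planar_roi_set`.
#' @param input_auc input-function AUC (counts x s), from [gamma_auc()].
#' @param scale dimensionless display scale (default 10).
#' @return object of class `planar_quant_result`: list with `heart_mean`,
#'   `mediastinum_mean`, `hm`, `index`, `virtual`.
#' @export
planar_uptake_index <- function(image, rois, input_auc, scale = 10) {
  if (!is.finite(input_auc) || input_auc <= 0)
    mibg_error("ZeroAuc", "input AUC must be positive")
  m <- planar_means(image, rois)
  hm <- if (m$mediastinum > 0) m$heart / m$mediastinum else NA_real_
  structure(list(heart_mean = m$heart, mediastinum_mean = m$mediastinum,
                 hm = hm, index = scale * m$heart / input_auc,
                 virtual = rois$virtual),
            class = "planar_quant_result")
}
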