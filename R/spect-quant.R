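#' Calibrate the 2D-3D count-conversion factor
#'
#' The conversion factor linking planar and SPECT count scales is the
#' least-squares slope, through the origin, of polar-map SPECT counts on
#' planar heart counts over a calibration cohort (proportionality is the
#' model's premise; an intercept fit is available behind a flag). The
#' Pearson correlation of the pairs is reported alongside.
#'
#' @param planar_counts mean heart counts/pixel per calibration subject.
#' @param spect_counts polar-map mean counts per calibration subject.
#' @param intercept fit with an intercept instead of through the origin
#'   (the slope is still the reported factor).
#' @return object of class `calibration_model`: list with `cf` (slope),
#'   `r` (Pearson correlation), `n`.
#' @export
calibrate_cf <- function(planar_counts, spect_counts, intercept = FALSE) {
  if (length(planar_counts) != length(spect_counts))
    mibg_error("LengthMismatch", "count vectors differ in length")
  n <- length(planar_counts)
  if (n < 3) mibg_error("TooFewPairs", "need at least 3 calibration pairs")
  if (all(planar_counts == 0))
    mibg_error("DegenerateX", "all planar counts are zero")
  cf <- if (intercept)
    stats::coef(stats::lm(spect_counts ~ planar_counts))[["planar_counts"]]
  else
    sum(planar_counts * spect_counts) / sum(planar_counts^2)
  r <- stats::cor(planar_counts, spect_counts)
  structure(list(cf = cf, r = r, n = n), class = "calibration_model")
}

#' SPECT uptake index
#'
#' The three-dimensional uptake index: the polar-map output function brought
#' onto the planar count scale by the calibration factor, divided by the
#' first-pass input AUC, times a fixed display scale:
#' `index = scale * Cmyo / (cf * AUC)`. Both `Cmyo` and `AUC` scale with the
#' administered dose while `cf` does not, so the index is dose-invariant and
#' proportional to true myocardial concentration.
#'
#' @param polar_map a `polar_map`.
#' @param calibration a `calibration_model` or a bare positive slope.
#' @param input_auc input-function AUC (counts x s).
#' @param scale dimensionless display scale (default 10).
#' @param output use the polar map's `"mean"` (default) or `"total"` counts
#'   as the output function.
#' @param virtual logical; carried through from the ROI/reorientation stage.
#' @return object of class `spect_quant_result`: list with `mean_counts`,
#'   `cf`, `auc`, `index`, `virtual`.
#' @export
spect_uptake_index <- function(polar_map, calibration, input_auc,
                               scale = 10, output = c("mean", "total"),
                               virtual = FALSE) {
  output <- match.arg(output)
  cf <- if (inherits(calibration, "calibration_model")) calibration$cf
        else as.numeric(calibration)
  if (!is.finite(cf) || cf <= 0)
    mibg_error("InvalidCalibration", "conversion factor must be positive")
  if (!is.finite(input_auc) || input_auc <= 0)
    mibg_error("ZeroAuc", "input AUC must be positive")
  cmyo <- if (output == "mean") polar_map$mean_counts
          else polar_map$total_counts
  structure(list(mean_counts = polar_map$mean_counts, cf = cf,
                 auc = input_auc,
                 index = scale * cmyo / (cf * input_auc),
                 virtual = virtual),
            class = "spect_quant_result")
}
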