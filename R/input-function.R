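#' Detect the pulmonary-artery ROI on a dynamic series
#'
#' Automatic localisation of the first-pass bolus focus. Candidate pixels
#' must exceed an amplitude gate (peak minus pre-bolus baseline above
#' `gate` times the baseline, with a one-count Poisson floor) inside the
#' upper-central chest window; among candidates the cluster with the
#' earliest time-to-peak (within `ttp_tol_frames` of the minimum) is taken
#' and its amplitude-weighted centroid becomes the ROI center. The ROI
#' diameter is fixed at 3 pixels, the protocol's standard.
#'
#' @param series a `dynamic_series`.
#' @param gate amplitude gate as a multiple of baseline (default 5).
#' @param region chest search window as fractions
#'   `c(row_min, row_max, col_min, col_max)`.
#' @param ttp_tol_frames cluster tolerance on time-to-peak, frames.
#' @return object of class `circular_roi`: list with `center`
#'   (row, col), `diameter_px` (3).
#' @export
detect_pa_roi <- function(series, gate = 5,
                          region = c(0.15, 0.55, 0.25, 0.75),
                          ttp_tol_frames = 2) {
  stopifnot(inherits(series, "dynamic_series"))
  fr <- series$frames
  nt <- dim(fr)[1]
  if (nt < 30) mibg_error("InvalidConfig", "need at least 30 frames")
  n_r <- dim(fr)[2]; n_c <- dim(fr)[3]
  flat <- matrix(fr, nt, n_r * n_c)
  n_base <- max(3L, floor(nt / 24))          # pre-bolus frames
  baseline <- colMeans(flat[seq_len(n_base), , drop = FALSE])
  peak <- apply(flat, 2, max)
  amp <- peak - baseline
  ok <- amp > gate * pmax(baseline, 1)

  rows <- rep(seq_len(n_r), times = n_c)
  cols <- rep(seq_len(n_c), each = n_r)
  in_region <- rows >= region[1] * n_r & rows <= region[2] * n_r &
               cols >= region[3] * n_c & cols <= region[4] * n_c
  cand <- which(ok & in_region)
  if (length(cand) == 0)
    mibg_error("NoBolusDetected",
               "no pixel exceeds the bolus amplitude gate")
  ttp <- apply(flat[, cand, drop = FALSE], 2, which.max)
  sel <- cand[ttp <= min(ttp) + ttp_tol_frames]
  w <- amp[sel]
  center <- c(row = sum(rows[sel] * w) / sum(w),
              col = sum(cols[sel] * w) / sum(w))
  structure(list(center = center, diameter_px = 3),
            class = "circular_roi")
}

# The 9 pixels whose centers lie within radius 1.5 px of the ROI center.
roi_pixels <- function(roi, n_r, n_c) {
  r0 <- round(roi$center[["row"]]); c0 <- round(roi$center[["col"]])
  rad <- roi$diameter_px / 2
  off <- expand.grid(dr = -2:2, dc = -2:2)
  keep <- sqrt((off$dr + r0 - roi$center[["row"]])^2 +
               (off$dc + c0 - roi$center[["col"]])^2) <= rad
  px <- cbind(row = r0 + off$dr[keep], col = c0 + off$dc[keep])
  if (any(px < 1) || any(px[, "row"] > n_r) || any(px[, "col"] > n_c))
    mibg_error("RoiOutOfBounds", "ROI extends outside the image grid")
  px
}

#' Extract the ROI time-activity curve
#'
#' Per-frame value is the sum of counts over the pixels inside the circular
#' ROI (9 pixels at the standard 3-pixel diameter); sample times are frame
#' midpoints.
#'
#' @param series a `dynamic_series`.
#' @param roi a `circular_roi` from [detect_pa_roi()].
#' @return object of class `tac`: list with `times` (s) and `counts`.
#' @export
extract_tac <- function(series, roi) {
  stopifnot(inherits(series, "dynamic_series"))
  fr <- series$frames
  px <- roi_pixels(roi, dim(fr)[2], dim(fr)[3])
  counts <- vapply(seq_len(dim(fr)[1]), function(t)
    sum(fr[cbind(t, px[, "row"], px[, "col"])]), numeric(1))
  structure(list(times = series$times, counts = counts), class = "tac")
}

#' Fit a gamma-variate to the first peak of a TAC
#'
#' Identifies the first-pass window (from the last pre-peak sample below
#' `up_frac` of the peak to the first post-peak sample below `down_frac` of
#' the peak, or the first post-peak rise, whichever comes first), subtracts
#' the pre-bolus baseline, and fits
#' `C(t) = K (t - t0)^alpha exp(-(t - t0)/beta)` by Levenberg-Marquardt
#' nonlinear least squares. Starting values come from the log-linearisation
#' `ln C = ln K + alpha ln(t - t0) - (t - t0)/beta` evaluated over a grid of
#' candidate `t0` (every 0.5 s from 0 to the peak time); the candidate with
#' the smallest windowed squared error seeds the nonlinear fit.
#'
#' @param tac a `tac`.
#' @param up_frac rising-edge window threshold (fraction of peak).
#' @param down_frac falling-edge window threshold (fraction of peak).
#' @param gate peak-to-baseline detectability gate.
#' @return object of class `gamma_fit`: list with `K`, `alpha`, `beta`,
#'   `t0`, `window` (start/end indices), `rmse`, `auc` (closed form),
#'   `baseline`.
#' @export
fit_gamma_variate <- function(tac, up_frac = 0.10, down_frac = 0.30,
                              gate = 5) {
  stopifnot(inherits(tac, "tac"))
  t <- tac$times; y <- tac$counts
  n <- length(y)
  n_base <- max(3L, floor(n / 24))
  baseline <- mean(y[seq_len(n_base)])
  yb <- pmax(y - baseline, 0)
  ipk <- which.max(yb)
  pk <- yb[ipk]
  if (pk <= gate * max(baseline, 1) || pk <= 0)
    mibg_error("FitFailed", "no detectable bolus peak above baseline")
  if (ipk >= n)
    mibg_error("FitFailed", "TAC has no downslope after its maximum")

  pre <- which(yb[seq_len(ipk)] < up_frac * pk)
  i0 <- if (length(pre)) max(pre) else 1L
  post <- seq(ipk + 1L, n)
  below <- post[yb[post] < down_frac * pk]
  rises <- post[c(diff(yb[post]) > 0, FALSE)]
  i1 <- min(c(below, rises + 0L, n))
  if (i1 <= ipk + 1L) i1 <- min(ipk + 2L, n)
  win <- i0:i1
  if (length(win) < 5)
    mibg_error("FitFailed", "first-pass window too short to fit")

  tw <- t[win]; yw <- yb[win]
  fit <- best_gamma_fit(tw, yw, t_peak = t[ipk])
  if (is.null(fit))
    mibg_error("FitFailed", "gamma-variate fit did not converge")
  structure(list(K = fit$K, alpha = fit$alpha, beta = fit$beta,
                 t0 = fit$t0, window = c(start = i0, end = i1),
                 rmse = fit$rmse,
                 auc = fit$K * fit$beta^(fit$alpha + 1) *
                   gamma(fit$alpha + 1),
                 baseline = baseline),
            class = "gamma_fit")
}

# Grid of t0 candidates -> log-linear least squares -> one LM refinement
# from the best seed (falling back through seeds on failure).
best_gamma_fit <- function(tw, yw, t_peak) {
  t0_grid <- seq(0, max(t_peak - 1e-3, 0), by = 0.5)
  t0_grid <- t0_grid[t0_grid < min(tw[yw > 0]) - 1e-9]
  if (!length(t0_grid)) t0_grid <- max(min(tw) - 1, 0)
  seeds <- list()
  for (t0 in t0_grid) {
    pos <- yw > 0 & tw > t0
    if (sum(pos) < 4) next
    tt <- tw[pos] - t0
    co <- tryCatch(stats::lm.fit(cbind(1, log(tt), tt), log(yw[pos]))$coefficients,
                   error = function(e) NULL)
    if (is.null(co) || anyNA(co) || co[2] <= 0 || co[3] >= 0) next
    par <- c(K = exp(co[1]), alpha = unname(co[2]),
             beta = unname(-1 / co[3]), t0 = t0)
    sse <- sum((gamma_variate(tw, par[1], par[2], par[3], par[4]) - yw)^2)
    seeds[[length(seeds) + 1]] <- list(par = par, sse = sse)
  }
  if (!length(seeds)) return(NULL)
  seeds <- seeds[order(vapply(seeds, `[[`, numeric(1), "sse"))]
  t0_max <- min(tw[yw > 0]) - 1e-6
  for (s in seeds[seq_len(min(3, length(seeds)))]) {
    df <- data.frame(t = tw, y = yw)
    res <- tryCatch(
      minpack.lm::nlsLM(
        y ~ gamma_variate(t, K, alpha, beta, t0),
        data = df, start = as.list(s$par),
        lower = c(K = 1e-12, alpha = 1e-6, beta = 1e-6, t0 = 0),
        upper = c(K = Inf, alpha = Inf, beta = Inf, t0 = t0_max),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(res)) {
      p <- stats::coef(res)
      return(list(K = p[["K"]], alpha = p[["alpha"]], beta = p[["beta"]],
                  t0 = p[["t0"]],
                  rmse = sqrt(mean(stats::resid(res)^2))))
    }
  }
  NULL
}

#' Closed-form area under a fitted gamma variate
#'
#' `AUC = K beta^(alpha+1) Gamma(alpha+1)`, the integral of the fitted
#' first-pass curve over `[t0, Inf)` — the input function of the uptake
#' index.
#'
#' @param fit a `gamma_fit`, or a list with `K`, `alpha`, `beta`.
#' @return AUC in counts times seconds.
#' @export
gamma_auc <- function(fit) {
  fit$K * fit$beta^(fit$alpha + 1) * gamma(fit$alpha + 1)
}
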