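#' Summary statistics for one diagnostic group
#'
#' Median and quartiles by the linear-interpolation convention, sample
#' variance (n - 1 denominator), and a distribution-free 95% confidence
#' interval of the median from binomial order statistics.
#'
#' @param values numeric vector, n >= 2.
#' @param conf confidence level for the median CI.
#' @return object of class `group_summary`: list with `n`, `min`, `max`,
#'   `median`, `q1`, `q3`, `variance`, `ci_median` (length 2).
#' @export
group_summary <- function(values, conf = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) mibg_error("TooFewValues", "need at least 2 values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  s <- sort(values)
  alpha <- (1 - conf) / 2
  k <- stats::qbinom(alpha, n, 0.5)
  while (k > 0 && stats::pbinom(k - 1, n, 0.5) > alpha) k <- k - 1
  if (k < 1) { lo <- s[1]; hi <- s[n] } else { lo <- s[k]; hi <- s[n - k + 1] }
  structure(list(n = n, min = min(values), max = max(values),
                 median = q[2], q1 = q[1], q3 = q[3],
                 variance = stats::var(values),
                 ci_median = c(lo, hi)),
            class = "group_summary")
}

#' Overlap interval between the two diagnostic groups
#'
#' LBD indices are expected lower; the overlap is
#' `[min(non-LBD), max(LBD)]` when the groups overlap, and empty
#' (`numeric(0)`) when the highest LBD value stays below the lowest non-LBD
#' value — the separation the 3D method is designed to achieve.
#'
#' @param lbd_values,nonlbd_values numeric vectors.
#' @return numeric of length 2 (lo, hi) or `numeric(0)`.
#' @export
overlap_range <- function(lbd_values, nonlbd_values) {
  if (!length(lbd_values) || !length(nonlbd_values))
    mibg_error("EmptyGroup", "both groups must be non-empty")
  hi <- max(lbd_values); lo <- min(nonlbd_values)
  if (hi >= lo) c(lo, hi) else numeric(0)
}

check_labels <- function(labels) {
  pos <- labels == "LBD"
  if (!any(pos) || all(pos))
    mibg_error("OneClassOnly", "need both LBD and non-LBD labels")
  pos
}

#' Empirical ROC curve for a disease-negative-high index
#'
#' Disease-positive (LBD) subjects are expected to score LOWER, so a
#' positive call is a score below threshold. Operating points sweep the
#' midpoints between adjacent distinct scores (plus both extremes); the
#' area under the curve is the Mann-Whitney probability that a random
#' non-LBD score exceeds a random LBD score, ties counted one half.
#'
#' @param scores numeric index values.
#' @param labels character vector, `"LBD"` or `"non-LBD"`.
#' @return object of class `roc_result`: list with `points` (data.frame of
#'   threshold, sensitivity, specificity) and `auc`.
#' @export
empirical_roc <- function(scores, labels) {
  pos <- check_labels(labels)
  x <- scores[pos]; y <- scores[!pos]     # x: LBD (low), y: non-LBD (high)
  cmp <- outer(y, x, `-`)
  auc <- mean((cmp > 0) + 0.5 * (cmp == 0))
  s <- sort(unique(scores))
  thr <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
           s[length(s)] + 1)
  pts <- t(vapply(thr, function(t0) {
    call_pos <- scores < t0
    c(threshold = t0,
      sensitivity = mean(call_pos[pos]),
      specificity = mean(!call_pos[!pos]))
  }, numeric(3)))
  structure(list(points = as.data.frame(pts), auc = auc),
            class = "roc_result")
}

#' Youden criterion from a ROC curve
#'
#' The decision threshold maximizing `J = sensitivity + specificity - 1`.
#' Candidate thresholds are midpoints between adjacent distinct scores, so
#' the winning cut is reported as the midpoint bracketing it; the first
#' (lowest) threshold is kept among exact ties.
#'
#' @param roc a `roc_result`.
#' @return list with `threshold` and `J`.
#' @export
youden_criterion <- function(roc) {
  J <- roc$points$sensitivity + roc$points$specificity - 1
  i <- which.max(J)
  list(threshold = roc$points$threshold[i], J = J[i])
}

#' Diagnostic accuracy at a fixed threshold
#'
#' Standard 2x2 metrics with the positive call defined as a score below
#' threshold (LBD call). A predictive value whose denominator is zero is
#' returned as `NA` and named in the `undefined` field rather than being
#' silently zeroed.
#'
#' @param scores numeric index values.
#' @param labels `"LBD"` / `"non-LBD"` vector.
#' @param threshold decision threshold.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, `table` (2x2), `undefined` (character).
#' @export
diagnostic_metrics <- function(scores, labels, threshold) {
  pos <- check_labels(labels)
  call_pos <- scores < threshold
  tp <- sum(call_pos & pos);  fn <- sum(!call_pos & pos)
  fp <- sum(call_pos & !pos); tn <- sum(!call_pos & !pos)
  undefined <- character(0)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else { undefined <- c(undefined, "ppv"); NA_real_ }
  npv <- if (tn + fn > 0) tn / (tn + fn) else { undefined <- c(undefined, "npv"); NA_real_ }
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = ppv, npv = npv,
       accuracy = (tp + tn) / length(scores),
       table = matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(call = c("positive", "negative"),
                                      truth = c("LBD", "non-LBD"))),
       undefined = undefined)
}

#' Mann-Whitney U test
#'
#' Reports `U = min(U1, U2)`. The two-sided p-value is exact by full
#' enumeration of all rank splits (mid-ranks for ties) when the combined
#' sample size is at most 20, and a tie-corrected normal approximation with
#' continuity correction otherwise:
#' `p = min(1, 2 min(P(U1 <= u), P(U1 >= u)))`.
#'
#' @param x,y numeric samples.
#' @return object of class `stat_test`: list with `statistic`, `p_value`,
#'   `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y))
    mibg_error("EmptySample", "both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u2 <- nx * ny - u1
  if (nx + ny <= 20) {
    splits <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[splits], nrow = nx)) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u1), mean(u_all >= u1)))
    method <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    t_adj <- table(r)
    sig2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(t_adj^3 - t_adj) / ((nx + ny) * (nx + ny - 1)))
    z <- (abs(u1 - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation, tie-corrected"
  }
  structure(list(statistic = min(u1, u2), p_value = p,
                 method = paste("Mann-Whitney U,", method)),
            class = "stat_test")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the probability of
#' the observed table.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return a `stat_test` (statistic = observed table probability).
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  stopifnot(all(dim(tb) == 2))
  if (any(tb < 0) || any(tb != round(tb)))
    mibg_error("NegativeCount", "counts must be nonnegative integers")
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  a_obs <- tb[1, 1]
  a_all <- max(0, k - n):min(k, m)
  p_all <- stats::dhyper(a_all, m, n, k)
  p_obs <- stats::dhyper(a_obs, m, n, k)
  p <- sum(p_all[p_all <= p_obs * (1 + 1e-7)])
  structure(list(statistic = p_obs, p_value = min(1, p),
                 method = "Fisher exact, two-sided"),
            class = "stat_test")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, two-sided p-value by the
#' t-approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return a `stat_test` with the correlation as `statistic`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    mibg_error("LengthMismatch", "x and y differ in length")
  n <- length(x)
  if (n < 3) mibg_error("TooFewValues", "need n >= 3")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  structure(list(statistic = rho, p_value = p,
                 method = "Spearman rank correlation, t approximation"),
            class = "stat_test")
}

#' Paired comparison of two ROC AUCs
#'
#' DeLong-style paired test on structural components: both indices are
#' scored on the same subjects, the AUC difference is normalized by the
#' variance of the paired placement values, and a two-sided normal p-value
#' is reported. Identical scores give a zero difference and p = 1.
#'
#' @param scores_a,scores_b two index vectors on the same subjects.
#' @param labels `"LBD"` / `"non-LBD"` vector.
#' @return a `stat_test` with the AUC difference as `statistic` plus
#'   `auc_a`, `auc_b` fields.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    mibg_error("LengthMismatch", "score and label vectors differ in length")
  pos <- check_labels(labels)
  placements <- function(s) {
    x <- s[pos]; y <- s[!pos]           # LBD low = positive orientation
    vx <- vapply(x, function(xi) mean((y > xi) + 0.5 * (y == xi)),
                 numeric(1))
    vy <- vapply(y, function(yi) mean((yi > x) + 0.5 * (yi == x)),
                 numeric(1))
    list(auc = mean(vx), vx = vx, vy = vy)
  }
  a <- placements(scores_a); b <- placements(scores_b)
  m <- sum(pos); n <- sum(!pos)
  sx <- stats::var(a$vx - b$vx); sy <- stats::var(a$vy - b$vy)
  v <- sx / m + sy / n
  diff <- a$auc - b$auc
  p <- if (v <= 0 || abs(diff) < 1e-15) {
    if (abs(diff) < 1e-15) 1 else 0
  } else 2 * stats::pnorm(-abs(diff) / sqrt(v))
  structure(list(statistic = diff, p_value = p,
                 auc_a = a$auc, auc_b = b$auc,
                 method = "paired structural-components AUC comparison"),
            class = "stat_test")
}
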