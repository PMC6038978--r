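#' Evaluate a gamma-variate bolus curve
#'
#' The first-pass bolus model `g(t) = K (t - t0)^alpha exp(-(t - t0)/beta)`
#' for `t > t0` and 0 otherwise. Its maximum is at `t0 + alpha * beta` and
#' its integral over `[t0, Inf)` is `K beta^(alpha+1) Gamma(alpha+1)`.
#'
#' @param t time(s), seconds.
#' @param K amplitude (> 0 for a physical bolus).
#' @param alpha dimensionless shape (> 0).
#' @param beta time scale, seconds (> 0).
#' @param t0 bolus arrival time, seconds.
#' @return numeric vector of curve values.
#' @export
gamma_variate <- function(t, K, alpha, beta, t0 = 0) {
  tt <- t - t0
  out <- numeric(length(t))
  pos <- which(tt > 0)
  out[pos] <- K * tt[pos]^alpha * exp(-tt[pos] / beta)
  out
}

# Bolus + delayed recirculation copy, the pulmonary-artery model curve.
bolus_curve <- function(t, bolus) {
  gamma_variate(t, bolus$K, bolus$alpha, bolus$beta, bolus$t0) +
    bolus$kappa *
      gamma_variate(t, bolus$K, bolus$alpha, bolus$beta,
                    bolus$t0 + bolus$delay)
}
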