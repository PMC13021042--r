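#' Minimal sample size for a one-sample t test
#'
#' Smallest n whose two-sided one-sample t test at effect size d reaches
#' the target power, computed from the noncentral t distribution with
#' df = n - 1 and noncentrality d * sqrt(n).
#'
#' @param d standardized effect size (Cohen's d), > 0.
#' @param power target power in (0, 1).
#' @param alpha significance level.
#' @param n_max search ceiling.
#' @return minimal integer n.
#' @examples
#' required_n_one_sample_t(0.8, power = 0.8)   # 15
#' required_n_one_sample_t(0.73, power = 0.9)  # 22
#' @export
required_n_one_sample_t <- function(d, power, alpha = 0.05, n_max = 1e5) {
  stopifnot(d > 0, power > 0, power < 1)
  for (n in 2:n_max) {
    if (power_one_sample_t(n, d, alpha) >= power) return(n)
  }
  stop("invalid-request: power unreachable within n_max", call. = FALSE)
}

#' Power of a two-sided one-sample t test
#'
#' @param n sample size.
#' @param d effect size.
#' @param alpha significance level.
#' @return achieved power.
#' @export
power_one_sample_t <- function(n, d, alpha = 0.05) {
  df <- n - 1
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
}

#' Minimal sample size for detecting a correlation
#'
#' Smallest n at which a two-sided test of H0: rho = 0 reaches the
#' target power under the Fisher z approximation:
#' power = Phi(|atanh(rho)| * sqrt(n - 3) - z_(1 - alpha/2)).
#'
#' @param rho population correlation, 0 < |rho| < 1.
#' @param power target power.
#' @param alpha significance level.
#' @param n_max search ceiling.
#' @return minimal integer n.
#' @examples
#' required_n_correlation(0.32, power = 0.9)  # 99
#' @export
required_n_correlation <- function(rho, power, alpha = 0.05, n_max = 1e6) {
  stopifnot(abs(rho) > 0, abs(rho) < 1, power > 0, power < 1)
  for (n in 4:n_max) {
    pw <- stats::pnorm(abs(atanh(rho)) * sqrt(n - 3) -
                         stats::qnorm(1 - alpha / 2))
    if (pw >= power) return(n)
  }
  stop("invalid-request: power unreachable within n_max", call. = FALSE)
}
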