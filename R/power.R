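# Sample-size machinery for the two-sided two-sample t-test, using the
# noncentral t distribution (the G*Power "means: difference between two
# independent means" computation).

#' Cohen's d
#'
#' @param mean_diff group mean difference (outcome units).
#' @param pooled_sd pooled standard deviation (> 0).
#' @return standardized effect size.
#' @examples
#' cohens_d(0.58, 1)
#' @export
cohens_d <- function(mean_diff, pooled_sd) {
  if (any(pooled_sd <= 0)) stop_config("pooled_sd must be positive")
  mean_diff / pooled_sd
}

# Power of the two-sided two-sample t-test at equal per-group n.
.t_power <- function(n_per_group, d, alpha) {
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  tc <- qt(1 - alpha / 2, df)
  1 - pt(tc, df, ncp = ncp) + pt(-tc, df, ncp = ncp)
}

#' Total sample size for a two-sample t-test
#'
#' Smallest equal per-group n such that the noncentral-t power of the
#' two-sided two-sample t-test at level `alpha` reaches `power`; returns
#' the total N over both groups. The search starts from the
#' normal-approximation lower bound and increments n, guaranteeing the
#' minimal-n contract.
#'
#' @param d Cohen's d (> 0).
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level in (0, 1).
#' @param max_n search cap on per-group n.
#' @return total N (both groups); attribute `n_per_group` and
#'   `achieved_power`.
#' @examples
#' sample_size_two_sample_t(0.62)  # 84
#' sample_size_two_sample_t(0.70)  # 68
#' sample_size_two_sample_t(0.78)  # 54
#' @export
sample_size_two_sample_t <- function(d, power = 0.80, alpha = 0.05,
                                     max_n = 1e6) {
  if (d <= 0) stop_config("d must be positive")
  if (power <= 0 || power >= 1) stop_config("power must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  n0 <- 2 * ((qnorm(1 - alpha / 2) + qnorm(power)) / d)^2
  n <- max(2L, floor(n0) - 2L)
  while (.t_power(n, d, alpha) < power) {
    n <- n + 1L
    if (n > max_n)
      stop_config("target power %.2f unattainable within max_n = %g", power, max_n)
  }
  # step back in case the lower bound overshot the minimum
  while (n > 2L && .t_power(n - 1L, d, alpha) >= power) n <- n - 1L
  structure(2L * n, n_per_group = n,
            achieved_power = .t_power(n, d, alpha))
}
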