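#' Storey q-values
#'
#' Positive-FDR q-values with the null proportion pi0 estimated by the
#' smoother method: `pi0_hat(lambda) = #\{p > lambda\} / (m (1 - lambda))`
#' over `lambda = 0.05, 0.10, ..., 0.95`, cubic-spline smoothed and
#' evaluated at the largest lambda, clipped to (0, 1]. Q-values are the
#' step-up minima `q(p_(i)) = min_{j >= i} pi0 m p_(j) / j`, so with
#' `pi0 = 1` they reduce exactly to Benjamini-Hochberg adjusted p-values.
#' Ties in p share a q-value and q is monotone in p.
#'
#' @param p p-values in \[0, 1\].
#' @param lambda grid for the pi0 smoother.
#' @param pi0 optional fixed null proportion (e.g. `1` for BH).
#' @return numeric q-values, same order as `p`; attribute `pi0`.
#' @examples
#' storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)  # all 0.04
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_config("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    if (m < 2 * length(lambda) || all(pi0_l == 0)) {
      pi0 <- min(1, max(pi0_l, 0))
      if (pi0 <= 0) pi0 <- 1
    } else {
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  } else {
    if (pi0 <= 0 || pi0 > 1) stop_config("pi0 must be in (0, 1]")
  }
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  res <- numeric(m)
  res[o] <- q
  attr(res, "pi0") <- pi0
  res
}

#' Graded evidence scale
#'
#' Maps a p-value (or FDR value) to the graded scale: `p < 0.01` strong,
#' `0.01 <= p < 0.05` moderate, `0.05 <= p < 0.1` weak, `p >= 0.1` little.
#'
#' @param p numeric in \[0, 1\]; vectorized.
#' @return factor with levels strong, moderate, weak, little.
#' @examples
#' evidence_grade(c(0.005, 0.05, 0.5))
#' @export
evidence_grade <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_config("p must lie in [0, 1]")
  cut(p, breaks = c(-Inf, 0.01, 0.05, 0.1, Inf), right = FALSE,
      labels = c("strong", "moderate", "weak", "little"))
}

#' Median split
#'
#' Binary indicator of values strictly above the median; ties at the median
#' go to the lower group. Missing values are excluded from the median and
#' preserved as `NA` in the indicator; their count is attached.
#'
#' @param values numeric with >= 2 non-missing entries.
#' @return integer 0/1 vector with attributes `median` and `n_missing`.
#' @examples
#' median_split(c(1, 2, 2, 3))  # ties (the 2s) in the lower group
#' @export
median_split <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L)
    stop_config("median split needs at least 2 non-missing values")
  med <- median(values[ok])
  out <- ifelse(is.na(values), NA_integer_, as.integer(values > med))
  attr(out, "median") <- med
  attr(out, "n_missing") <- sum(!ok)
  out
}
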