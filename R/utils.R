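# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every simulator is a pure function of (inputs, seed) through this helper.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-entity child seed, kept inside 32-bit integer range.
child_seed <- function(seed, i, salt = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 9973 +
                as.double(salt) * 377) %% 2147483587) + 1L
}

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Log-normal draw parameterised by its median (exp(meanlog)).
rlnorm_med <- function(n, median, sdlog) {
  rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# Sample from a log-normal truncated to (lower, upper], with meanlog
# calibrated so that the *truncated* median equals `median`. Used for the
# liver-lipid intervals so that group medians land on their targets without
# the truncation dragging them off.
rtrunc_lnorm_med <- function(n, median, sdlog, lower, upper) {
  stopifnot(lower < median, median < upper)
  obj <- function(mu) {
    a <- pnorm((log(lower) - mu) / sdlog)
    b <- pnorm((log(upper) - mu) / sdlog)
    (log(median) - mu) / sdlog - qnorm(a + 0.5 * (b - a))
  }
  mu <- stats::uniroot(obj, interval = log(median) + c(-4, 4) * sdlog)$root
  a <- pnorm((log(lower) - mu) / sdlog)
  b <- pnorm((log(upper) - mu) / sdlog)
  u <- runif(n, a, b)
  exp(mu + sdlog * qnorm(u))
}

# Moment-based skewness (used by the transform registry).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Blom rank-based normal scores.
rank_normal <- function(x) {
  r <- rank(x, ties.method = "average")
  qnorm((r - 0.375) / (length(x) + 0.25))
}

#' Unit conversions for insulin and glucose
#'
#' Insulin is carried in pmol/L throughout the package; HOMA-IR and the
#' classic (mg/dL) Matsuda convention need uU/mL. The conversion factor is
#' configurable because immunoassay calibrations differ; 6.00 pmol/L per
#' uU/mL is the conventional default. Glucose mmol/L to mg/dL uses the
#' molar mass of glucose (18.016 mg per mmol per dL scaling).
#'
#' @param x numeric vector of concentrations.
#' @param factor pmol/L per uU/mL conversion factor (default 6).
#' @return numeric vector in the target unit.
#' @examples
#' insulin_pmol_to_uu(27)  # 4.5 uU/mL
#' insulin_uu_to_pmol(4.5)
#' @export
insulin_pmol_to_uu <- function(x, factor = 6) x / factor

#' @rdname insulin_pmol_to_uu
#' @export
insulin_uu_to_pmol <- function(x, factor = 6) x * factor

#' @rdname insulin_pmol_to_uu
#' @export
glucose_mmol_to_mgdl <- function(x) x * 18.016

#' @rdname insulin_pmol_to_uu
#' @export
glucose_mgdl_to_mmol <- function(x) x / 18.016
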