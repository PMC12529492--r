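# Parametric plasma input function and the irreversible two-tissue
# compartment model that underlies Patlak graphical analysis.

#' Parametric FDG plasma input function
#'
#' Smooth bolus-plus-washout input function built from a tri-exponential
#' washout minus a fast rise term, so that Cp(0) = 0 and the area under the
#' curve from 0 to infinity is exactly `total_auc`. The closed form makes
#' exact AUC oracles available for testing the trapezoid-plus-tail AUC used
#' in the rate-of-disappearance estimator.
#'
#' @param total_auc area under Cp from 0 to infinity (kBq*min/mL).
#' @param weights relative AUC weights of the three washout components.
#' @param decays washout rate constants (1/min), slow tail last.
#' @param rise bolus rise rate constant (1/min).
#' @return Object of class `input_function`: a table of exponential terms
#'   `A * exp(-lambda * t)` plus evaluation helpers via [input_eval()],
#'   [input_integral()] and [input_auc()].
#' @examples
#' f <- input_function(total_auc = 3000)
#' input_eval(f, c(1, 10, 60))
#' input_auc(f)
#' @export
input_function <- function(total_auc = 1,
                           weights = c(0.55, 0.30, 0.15),
                           decays = c(0.35, 0.08, 0.01),
                           rise = 1.5) {
  if (total_auc <= 0) stop_config("total_auc must be positive")
  if (length(weights) != length(decays))
    stop_config("weights and decays must have equal length")
  if (any(weights <= 0) || any(decays <= 0) || rise <= max(decays))
    stop_config("weights/decays must be positive and rise > max(decays)")
  w <- weights / sum(weights)
  s <- sum(w * decays)
  auc_raw <- 1 - s / rise
  scale <- total_auc / auc_raw
  structure(list(A = scale * c(w * decays, -s),
                 lambda = c(decays, rise)),
            class = "input_function")
}

#' @rdname input_function
#' @param f an `input_function`.
#' @param t times (min).
#' @export
input_eval <- function(f, t) {
  drop(exp(-outer(t, f$lambda)) %*% f$A)
}

#' @rdname input_function
#' @export
input_integral <- function(f, t) {
  drop((1 - exp(-outer(t, f$lambda))) %*% (f$A / f$lambda))
}

#' @rdname input_function
#' @export
input_auc <- function(f) sum(f$A / f$lambda)

# conv(lambda, beta, t) = int_0^t exp(-lambda s) exp(-beta (t-s)) ds
.exp_conv <- function(lambda, beta, t) {
  if (abs(beta - lambda) < 1e-12) return(t * exp(-beta * t))
  (exp(-lambda * t) - exp(-beta * t)) / (beta - lambda)
}

# int_0^t conv(lambda, beta, s) ds
.exp_conv_int <- function(lambda, beta, t) {
  if (abs(beta - lambda) < 1e-12)
    return((1 - (1 + beta * t) * exp(-beta * t)) / beta^2)
  if (abs(lambda) < 1e-12)
    return((t - (1 - exp(-beta * t)) / beta) / beta)
  ((1 - exp(-lambda * t)) / lambda - (1 - exp(-beta * t)) / beta) /
    (beta - lambda)
}

# Exact tissue curve of the irreversible 2TC model for an exponential-sum
# input: C1 = K1 Cp (x) exp(-(k2+k3) t); Ct = C1 + k3 int_0^t C1.
tissue_curve_exact <- function(params, f, t) {
  K1 <- params[["K1"]]; k2 <- params[["k2"]]; k3 <- params[["k3"]]
  beta <- k2 + k3
  stopifnot(beta > 0)
  ct <- numeric(length(t))
  for (j in seq_along(f$A)) {
    conv_j <- .exp_conv(f$lambda[j], beta, t)
    iconv_j <- .exp_conv_int(f$lambda[j], beta, t)
    ct <- ct + f$A[j] * (conv_j + k3 * iconv_j)
  }
  K1 * ct
}

#' Forward solution of the irreversible two-tissue compartment model
#'
#' Numerically convolves a sampled plasma curve with the model
#' `dC1/dt = K1 Cp - (k2 + k3) C1`, `dC2/dt = k3 C1`, returning the total
#' tissue activity `Ct = C1 + C2` at the requested times. Integration uses an
#' exponential-integrator step on a fine uniform grid, which is exact for
#' piecewise-linear plasma input. This routine is the independent forward
#' oracle against which the Patlak estimator is validated: its late-time
#' slope relative to the input tends to `Ki = K1 k3 / (k2 + k3)`.
#'
#' @param params named numeric: `K1` (mL/min/mL), `k2`, `k3` (1/min), all
#'   >= 0 with `k2 + k3 > 0`.
#' @param plasma a [tac()] for plasma; a zero sample at t = 0 is implied when
#'   the first sample is later than 0.
#' @param eval_times times (min) at which to return Ct; must lie within the
#'   plasma support.
#' @param dt fine-grid step (min).
#' @return A [tac()] labelled `"tissue"`.
#' @examples
#' f <- input_function(total_auc = 3000)
#' tt <- seq(0.5, 90, by = 0.5)
#' pl <- tac(tt, input_eval(f, tt), "plasma")
#' solve_irreversible_2tc(c(K1 = 0.1, k2 = 0.15, k3 = 0.05), pl, c(20, 60))
#' @export
solve_irreversible_2tc <- function(params, plasma, eval_times, dt = 0.05) {
  stopifnot(inherits(plasma, "tac"))
  params <- unlist(params)[c("K1", "k2", "k3")]
  if (any(is.na(params)) || any(params < 0))
    stop_config("params must be named non-negative K1, k2, k3")
  if (params[["k2"]] + params[["k3"]] <= 0)
    stop_config("k2 + k3 must be positive")
  if (any(eval_times > max(plasma$times) + 1e-9) || any(eval_times < 0))
    stop_config("eval_times extend beyond the plasma support [0, %.2f] min",
                max(plasma$times))
  tp <- plasma$times; ap <- plasma$activities
  if (tp[1] > 0) { tp <- c(0, tp); ap <- c(0, ap) }
  grid <- seq(0, max(eval_times), by = dt)
  cp <- approx(tp, ap, xout = grid, rule = 2)$y
  beta <- params[["k2"]] + params[["k3"]]
  K1 <- params[["K1"]]
  decay <- exp(-beta * dt)
  c1 <- numeric(length(grid))
  for (i in seq_along(grid)[-1]) {
    # trapezoid-in-step exponential integrator
    c1[i] <- c1[i - 1] * decay +
      K1 * dt * 0.5 * (cp[i] + cp[i - 1] * decay)
  }
  c2 <- params[["k3"]] * pracma::cumtrapz(grid, c1)[, 1]
  ct <- approx(grid, c1 + c2, xout = eval_times, rule = 2)$y
  ts <- eval_times
  if (length(ts) < 3L) { # tac requires >= 3 samples; pad via the grid
    return(structure(list(times = ts, activities = ct, label = "tissue"),
                     class = "tac"))
  }
  tac(ts, ct, "tissue")
}
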