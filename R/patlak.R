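#' Gjedde-Patlak graphical analysis
#'
#' Estimates the fractional uptake rate constant Ki of an irreversibly
#' trapped tracer from a tissue and a plasma time-activity curve. The
#' normalized time axis is `x(t) = int_0^t Cp / Cp(t)` (trapezoidal
#' integration on the plasma grid, with an implied zero sample at t = 0 when
#' the plasma curve starts later) and the ordinate `y(t) = Ct(t) / Cp(t)`;
#' ordinary least squares of y on x over `t >= t_star` gives Ki (slope) and
#' the initial distribution volume (intercept).
#'
#' @param tissue tissue [tac()].
#' @param plasma plasma [tac()], covering the tissue times.
#' @param t_star start of the linear window (min). The default 20 min lies
#'   beyond free-compartment equilibration (about `3 / (k2 + k3)`) for
#'   typical clamp-state FDG rate constants.
#' @return object of class `patlak_fit`: `ki` (mL/min/mL), `intercept`
#'   (mL/mL), `t_star`, `r_squared`, `n_points`.
#' @examples
#' f <- input_function(total_auc = 3000)
#' tt <- .default_fdg_times
#' pl <- tac(tt, input_eval(f, tt), "plasma")
#' ti <- tac(tt, fdgclamp:::tissue_curve_exact(
#'   c(K1 = 0.1, k2 = 0.15, k3 = 0.05), f, tt), "muscle")
#' patlak_ki(ti, pl)  # ki near 0.1 * 0.05 / 0.2 = 0.025
#' @export
patlak_ki <- function(tissue, plasma, t_star = 20) {
  stopifnot(inherits(tissue, "tac"), inherits(plasma, "tac"))
  if (max(plasma$times) < max(tissue$times) - 1e-9)
    stop_config("plasma curve must cover the tissue times (plasma ends %.1f, tissue %.1f min)",
                max(plasma$times), max(tissue$times))
  tp <- plasma$times; ap <- plasma$activities
  if (tp[1] > 0) { tp <- c(0, tp); ap <- c(0, ap) }
  cum <- pracma::cumtrapz(tp, ap)[, 1]
  keep <- tissue$times >= t_star
  if (sum(keep) < 2L)
    stop_config("fewer than 2 tissue samples at or after t_star = %.1f min", t_star)
  tt <- tissue$times[keep]
  cp_t <- approx(tp, ap, xout = tt)$y
  if (any(cp_t <= 0))
    stop_config("non-positive plasma activity inside the Patlak window")
  x <- approx(tp, cum, xout = tt)$y / cp_t
  y <- tissue$activities[keep] / cp_t
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  r2 <- min(max(r2, 0), 1)
  structure(list(ki = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 t_star = t_star,
                 r_squared = r2,
                 n_points = length(x)),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit: Ki = %.4g mL/min/mL, Vd = %.3g mL/mL, t* = %.0f min, R2 = %.3f, n = %d>\n",
              x$ki, x$intercept, x$t_star, x$r_squared, x$n_points))
  invisible(x)
}

# Default tissue densities (kg/L); the lumped constant corrects for kinetic
# differences between FDG and glucose.
.region_density <- c(muscle = 1.04, liver = 1.05, asat = 0.92)
.region_lumped_constant <- c(muscle = 1.2, liver = 1.0, asat = 1.14)

#' Tissue glucose uptake from a Patlak fit
#'
#' `GU = Ki * glucose / (density * LC)` with glucose converted from mmol/L
#' to umol/L, yielding umol per kg tissue per min. Lumped constants default
#' to 1.2 (skeletal muscle), 1.0 (liver) and 1.14 (adipose tissue).
#'
#' @param fit a `patlak_fit`, or a bare Ki value (1/min).
#' @param plasma_glucose plasma glucose (mmol/L, > 0).
#' @param region `"muscle"`, `"liver"` or `"asat"`.
#' @param density tissue density (kg/L); per-region default.
#' @param lumped_constant override of the region's lumped constant.
#' @return glucose uptake in umol/(kg tissue)/min.
#' @examples
#' tissue_glucose_uptake(0.012, 5, "muscle", density = 1)  # 50
#' @export
tissue_glucose_uptake <- function(fit, plasma_glucose,
                                  region = c("muscle", "liver", "asat"),
                                  density = NULL, lumped_constant = NULL) {
  region <- match.arg(region)
  ki <- if (inherits(fit, "patlak_fit")) fit$ki else fit
  if (!is.finite(ki)) stop_config("ki must be finite")
  if (plasma_glucose <= 0) stop_config("plasma_glucose must be positive")
  density <- density %||% .region_density[[region]]
  lc <- lumped_constant %||% .region_lumped_constant[[region]]
  ki * plasma_glucose * 1000 / (density * lc)
}
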