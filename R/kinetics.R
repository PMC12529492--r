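# Whole-body quantities from clamp and tracer records: the clamp M-value,
# the glucose rate of disappearance (Rd) from FDG plasma clearance, and
# endogenous glucose production (EGP) as their difference.

#' Clamp M-value
#'
#' Whole-body glucose uptake during the clamp: the mean of three consecutive
#' 20-min interval means of the glucose infusion rate, starting at the first
#' glucose sample within `tolerance` of the 5 mmol/L target with at least
#' 60 min of GIR trace remaining. Interval means are time-weighted
#' (trapezoidal) over the GIR trace.
#'
#' @param clamp a [simulate_clamp()] record (or compatible list).
#' @param target glucose target (mmol/L).
#' @param tolerance steady-state detection tolerance (mmol/L).
#' @return object of class `m_value`: `m` (umol/kg/min), `interval_means`,
#'   `t_steady` (min), `tolerance`.
#' @examples
#' cl <- simulate_clamp(subject_profile(), seed = NULL)
#' m_value(cl)
#' @export
m_value <- function(clamp, target = 5.0, tolerance = 0.3) {
  s <- clamp$samples
  g <- clamp$gir
  t_end <- max(g$time_min)
  # the t = 0 sample precedes insulin action and can never mark steady state
  ok <- s$time_min > 0 &
    abs(s$glucose_mmol_l - target) <= tolerance &
    s$time_min + 60 <= t_end + 1e-9
  if (!any(ok))
    stop_config("steady state never reached: no glucose sample within %.1f mmol/L of %.1f with 60 min of GIR trace remaining",
                tolerance, target)
  t0 <- min(s$time_min[ok])
  interval_mean <- function(a, b) {
    tt <- sort(unique(c(a, b, g$time_min[g$time_min > a & g$time_min < b])))
    vv <- approx(g$time_min, g$gir_umol_kg_min, xout = tt, rule = 2)$y
    pracma::trapz(tt, vv) / (b - a)
  }
  ivm <- vapply(0:2, function(i)
    interval_mean(t0 + i * 20, t0 + (i + 1) * 20), numeric(1))
  structure(list(m = mean(ivm), interval_means = ivm,
                 t_steady = t0, tolerance = tolerance),
            class = "m_value")
}

#' @export
print.m_value <- function(x, ...) {
  cat(sprintf("<m_value: M = %.2f umol/kg/min (intervals %s) from t = %.0f min, tol %.2f mmol/L>\n",
              x$m, paste(sprintf("%.1f", x$interval_means), collapse = ", "),
              x$t_steady, x$tolerance))
  invisible(x)
}

# Plasma AUC by trapezoid (implied zero at t = 0) plus a mono-exponential
# tail fitted to the last `tail_points` samples.
plasma_auc <- function(plasma, tail_points = 3) {
  tp <- plasma$times; ap <- plasma$activities
  if (any(ap <= 0)) stop_config("plasma activities must be positive for AUC")
  if (tp[1] > 0) { tp <- c(0, tp); ap <- c(0, ap) }
  auc_obs <- pracma::trapz(tp, ap)
  n <- length(plasma$times)
  idx <- seq(n - tail_points + 1L, n)
  fit <- lm(log(plasma$activities[idx]) ~ plasma$times[idx])
  lambda <- -coef(fit)[[2]]
  if (!is.finite(lambda) || lambda <= 0)
    stop_config("plasma tail is not decaying; cannot extrapolate AUC")
  auc_obs + plasma$activities[n] / lambda
}

#' Glucose rate of disappearance from FDG plasma clearance
#'
#' `Rd = clearance * glucose / weight`, where clearance is
#' `(dose - urine) / AUC(plasma)`. The plasma AUC uses trapezoidal
#' integration (with an implied zero at injection) extrapolated beyond the
#' last sample by a mono-exponential fitted to the last `tail_points`
#' samples. Units: dose and urine in MBq, plasma in kBq/mL, glucose in
#' mmol/L (= umol/mL), weight in kg; the result is umol/kg/min.
#'
#' @param dose_mbq injected FDG dose (MBq).
#' @param urine_mbq FDG activity lost to urine (MBq), `< dose_mbq`.
#' @param plasma plasma [tac()].
#' @param avg_glucose average plasma glucose during the study (mmol/L).
#' @param weight body weight (kg).
#' @param tail_points samples in the tail fit.
#' @return Rd in umol/kg/min.
#' @examples
#' tt <- seq(1, 90, by = 1)
#' pl <- tac(tt, 40 * exp(-0.02 * tt), "plasma")
#' rate_of_disappearance(150, 15, pl, avg_glucose = 5, weight = 70)
#' @export
rate_of_disappearance <- function(dose_mbq, urine_mbq, plasma,
                                  avg_glucose, weight, tail_points = 3) {
  if (urine_mbq < 0 || urine_mbq >= dose_mbq)
    stop_config("urine activity must satisfy 0 <= urine < dose")
  if (weight <= 0) stop_config("weight must be positive")
  auc <- plasma_auc(plasma, tail_points)
  if (auc <= 0) stop_config("non-positive plasma AUC")
  clearance_ml_min <- (dose_mbq - urine_mbq) * 1000 / auc
  clearance_ml_min * avg_glucose / weight  # mL/min * umol/mL / kg
}

#' Endogenous glucose production
#'
#' `EGP = Rd - GIR` at clamp steady state. Negative values are legal and
#' preserved: measurement noise in Rd can push estimates below zero when
#' hepatic output is fully suppressed.
#'
#' @param rd glucose rate of disappearance (umol/kg/min).
#' @param gir_steady steady-state glucose infusion rate, usually the
#'   M-value (umol/kg/min).
#' @return object of class `egp_result`: `rd`, `gir_steady`, `egp` with
#'   `egp == rd - gir_steady` exactly.
#' @examples
#' endogenous_glucose_production(10, 8)$egp  # 2
#' @export
endogenous_glucose_production <- function(rd, gir_steady) {
  rd <- if (inherits(rd, "m_value")) rd$m else rd
  gir_steady <- if (inherits(gir_steady, "m_value")) gir_steady$m else gir_steady
  if (!is.finite(rd) || !is.finite(gir_steady))
    stop_config("rd and gir_steady must be finite")
  structure(list(rd = rd, gir_steady = gir_steady, egp = rd - gir_steady),
            class = "egp_result")
}

#' Quantify one subject's clamp + FDG study
#'
#' Runs the full per-subject quantification: Patlak Ki and glucose uptake
#' per region, M-value, Rd and EGP.
#'
#' @param fdg a [simulate_fdg_study()] result.
#' @param clamp a [simulate_clamp()] record.
#' @param weight body weight (kg).
#' @param t_star Patlak window start (min).
#' @param target,tolerance steady-state detection, see [m_value()].
#' @return one-row data.frame of unit-suffixed quantities.
#' @examples
#' pr <- subject_profile()
#' cl <- simulate_clamp(pr, seed = NULL)
#' st <- simulate_fdg_study(pr, cl)
#' quantify_subject(st, cl, weight = pr$weight_kg)
#' @export
quantify_subject <- function(fdg, clamp, weight, t_star = 20,
                             target = 5.0, tolerance = 0.3) {
  mv <- m_value(clamp, target = target, tolerance = tolerance)
  rd <- rate_of_disappearance(fdg$injected_dose_mbq, fdg$urine_activity_mbq,
                              fdg$plasma, fdg$avg_glucose_mmol_l, weight)
  egp <- endogenous_glucose_production(rd, mv$m)
  out <- data.frame(subject_id = fdg$subject_id,
                    m_value_umol_kg_min = mv$m,
                    t_steady_min = mv$t_steady,
                    rd_umol_kg_min = rd,
                    egp_umol_kg_min = egp$egp,
                    avg_glucose_mmol_l = fdg$avg_glucose_mmol_l,
                    stringsAsFactors = FALSE)
  for (r in names(fdg$tissues)) {
    fit <- patlak_ki(fdg$tissues[[r]], fdg$plasma, t_star = t_star)
    out[[sprintf("ki_%s_ml_min_ml", r)]] <- fit$ki
    out[[sprintf("r2_%s", r)]] <- fit$r_squared
    out[[sprintf("gu_%s_umol_kg_min", r)]] <-
      tissue_glucose_uptake(fit, fdg$avg_glucose_mmol_l, r)
  }
  out
}
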