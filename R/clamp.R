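# Hyperinsulinaemic-euglycaemic clamp simulator. Insulin is infused at a
# fixed 40 mU/m2/min; a discrete proportional-integral controller servos the
# glucose infusion rate (GIR) so that plasma glucose settles at the 5 mmol/L
# target. At steady state mass balance gives GIR = whole-body disposal -
# suppressed EGP, exactly in noiseless mode.

#' Minimal subject profile for direct simulator calls
#'
#' Builds a one-row profile with sensible defaults; any field of the cohort
#' table can be overridden. [generate_cohort()] is the usual source of
#' profiles, this constructor mainly serves examples and small experiments.
#'
#' @param ... named overrides of cohort columns, e.g.
#'   `disposal_umol_kg_min = 30`.
#' @return one-row data.frame.
#' @examples
#' subject_profile(disposal_umol_kg_min = 30, egp_suppression_frac = 1)
#' @export
subject_profile <- function(...) {
  base <- generate_cohort(cohort_config(n_per_group = 2, seed = 1L))[1, ]
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop_config("unknown profile field(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

#' Simulate a hyperinsulinaemic-euglycaemic clamp
#'
#' Forward-simulates plasma glucose under ramping insulin action (disposal
#' activates and EGP suppresses with first-order kinetics) while a discrete
#' PI controller, updated every `control_interval` minutes and primed with a
#' feed-forward ramp, adjusts GIR towards the euglycaemic target. Glucose
#' and insulin samples are emitted every 30 min.
#'
#' @param profile one cohort row (or [subject_profile()]).
#' @param duration clamp length in min (>= 120).
#' @param seed integer seed for measurement noise; `NULL` gives the
#'   noiseless trajectory.
#' @param noise_levels named CVs `clamp_glucose`, `clamp_insulin`; zeros or
#'   `seed = NULL` give exact samples.
#' @param target glucose target (mmol/L).
#' @param control_interval controller update step (min).
#' @param dt fine integration step (min).
#' @return object of class `clamp_record`: `gir` trace
#'   (`time_min`, `gir_umol_kg_min`) on the controller grid, 30-min
#'   `samples` (`time_min`, `glucose_mmol_l`, `insulin_pmol_l`), the fixed
#'   insulin infusion rate and subject weight.
#' @examples
#' pr <- subject_profile(disposal_umol_kg_min = 30,
#'                       basal_egp_umol_kg_min = 2,
#'                       egp_suppression_frac = 0)
#' cl <- simulate_clamp(pr, duration = 180, seed = NULL)
#' tail(cl$gir)  # steady-state GIR near 30 - 2 = 28
#' @export
simulate_clamp <- function(profile, duration = 180, seed = NULL,
                           noise_levels = default_noise_levels(),
                           target = 5.0, control_interval = 5, dt = 0.5) {
  if (duration < 120)
    stop_config("duration %.0f min is too short: steady state unreachable before the M-value window", duration)
  d_ss <- profile[["disposal_umol_kg_min"]]
  basal <- profile[["basal_egp_umol_kg_min"]]
  egp_ss <- basal * (1 - profile[["egp_suppression_frac"]])
  g0 <- profile[["fasting_glucose_mmol_l"]]
  vg <- 190   # glucose distribution volume, umol/kg per mmol/L (0.19 L/kg)
  tau_act <- 8    # insulin action activation time constant (min)
  kp <- 25; ki <- 2.5   # controller gains

  n_ctrl <- floor(duration / control_interval)
  ctrl_times <- seq(0, by = control_interval, length.out = n_ctrl + 1)
  gir_trace <- numeric(n_ctrl + 1)
  g <- g0
  integ <- 0
  fine_per <- round(control_interval / dt)
  glucose_path <- numeric(n_ctrl + 1); glucose_path[1] <- g

  for (k in seq_len(n_ctrl + 1)) {
    t_k <- ctrl_times[k]
    ramp <- 1 - exp(-t_k / tau_act)
    ff <- 0.8 * max(d_ss - egp_ss, 0) * ramp
    e <- target - g
    gir <- ff + kp * e + ki * integ
    if (gir < 0) gir <- 0 else integ <- integ + e * control_interval
    gir_trace[k] <- gir
    if (k > n_ctrl) break
    for (j in seq_len(fine_per)) {
      tt <- t_k + (j - 1) * dt
      act <- 1 - exp(-tt / tau_act)
      egp_t <- egp_ss + (basal - egp_ss) * exp(-tt / (tau_act + 5))
      d_t <- basal + (d_ss - basal) * act
      g <- g + dt * (egp_t + gir - d_t * g / target) / vg
      if (g < 0.5) g <- 0.5
    }
    glucose_path[k + 1] <- g
  }

  sample_times <- seq(0, duration, by = 30)
  g_samp <- approx(ctrl_times, glucose_path, xout = sample_times, rule = 2)$y
  ins_ss <- 460  # incremental steady-state insulin at 40 mU/m2/min (pmol/L)
  i_samp <- profile[["fasting_insulin_pmol_l"]] +
    ins_ss * (1 - exp(-sample_times / 12))
  if (!is.null(seed)) {
    cv_g <- noise_levels[["clamp_glucose"]] %||% 0
    cv_i <- noise_levels[["clamp_insulin"]] %||% 0
    noisy <- with_seed(seed, list(
      g = g_samp * exp(rnorm(length(g_samp), 0, cv_g)),
      i = i_samp * exp(rnorm(length(i_samp), 0, cv_i))))
    g_samp <- noisy$g; i_samp <- noisy$i
  }

  structure(list(
    subject_id = profile[["subject_id"]] %||% "subject",
    gir = data.frame(time_min = ctrl_times, gir_umol_kg_min = gir_trace),
    samples = data.frame(time_min = sample_times,
                         glucose_mmol_l = g_samp,
                         insulin_pmol_l = i_samp),
    insulin_infusion_rate_mu_m2_min = 40,
    weight_kg = profile[["weight_kg"]] %||% NA_real_),
    class = "clamp_record")
}

#' @export
print.clamp_record <- function(x, ...) {
  cat(sprintf("<clamp_record '%s': %.0f min, final GIR %.1f umol/kg/min, final glucose %.2f mmol/L>\n",
              x$subject_id, max(x$gir$time_min),
              tail(x$gir$gir_umol_kg_min, 1),
              tail(x$samples$glucose_mmol_l, 1)))
  invisible(x)
}
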