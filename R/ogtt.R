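# Oral glucose tolerance test simulator: parametric glucose and insulin
# responses at the 0/30/60/120-min sampling grid, with excursion amplitudes
# scaled inversely to the profile's relative insulin sensitivity.

.ogtt_times <- c(0, 30, 60, 120)

#' Simulate a 75-g oral glucose tolerance test
#'
#' Glucose and insulin at 0, 30, 60 and 120 min follow fixed response
#' shapes scaled by the subject's fasting values, with amplitude inversely
#' proportional to the relative whole-body insulin sensitivity
#' (`disposal / 38`): less sensitive subjects show larger glucose
#' excursions and a larger compensatory insulin response.
#'
#' @param profile one cohort row.
#' @param seed integer seed for sampling noise; `NULL` for the noiseless
#'   response.
#' @param glucose_amp,insulin_amp response amplitude parameters
#'   (dimensionless); zero amplitudes give flat curves at the fasting
#'   values.
#' @param noise_cv multiplicative CV applied per sample when `seed` is set.
#' @return data.frame with `subject_id`, `time_min`, `glucose_mmol_l`,
#'   `insulin_pmol_l` (4 rows), all positive.
#' @examples
#' simulate_ogtt(subject_profile(), seed = 2)
#' @export
simulate_ogtt <- function(profile, seed = NULL,
                          glucose_amp = 0.35, insulin_amp = 1.0,
                          noise_cv = default_noise_levels()[["ogtt"]]) {
  sens <- profile[["disposal_umol_kg_min"]] / 38
  if (!is.finite(sens) || sens <= 0)
    stop_config("profile has non-positive disposal; cannot scale OGTT response")
  shape_g <- c(0, 0.45, 0.35, 0.08)
  shape_i <- c(0, 5.5, 4.5, 2.2)
  g <- profile[["fasting_glucose_mmol_l"]] *
    (1 + glucose_amp * shape_g / sens)
  i <- profile[["fasting_insulin_pmol_l"]] *
    (1 + insulin_amp * shape_i / sens)
  if (!is.null(seed)) {
    noisy <- with_seed(seed, list(
      g = g * exp(rnorm(4, 0, noise_cv)),
      i = i * exp(rnorm(4, 0, noise_cv))))
    g <- noisy$g; i <- noisy$i
  }
  data.frame(subject_id = profile[["subject_id"]] %||% "subject",
             time_min = .ogtt_times,
             glucose_mmol_l = g, insulin_pmol_l = i,
             stringsAsFactors = FALSE)
}
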