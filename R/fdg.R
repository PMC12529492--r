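# Dynamic FDG-PET study simulator: parametric plasma input function plus
# exact irreversible two-tissue-model tissue curves for liver, femoral
# muscle and abdominal subcutaneous adipose tissue (ASAT).
#
# The plasma curve is scaled so that whole-body FDG clearance is consistent
# with the profile's programmed glucose disposal: clearance =
# disposal * weight / glucose, and AUC(0, Inf) of plasma equals
# (dose - urine) / clearance. The rate-of-disappearance estimator therefore
# has the programmed disposal as its ground truth.

.default_fdg_times <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 10,
                        12.5, 15, 17.5, 20, 25, 30, 35, 40, 45, 50, 55, 60,
                        70, 80, 90, 100, 110, 120)

#' Simulate a dynamic FDG-PET study under clamp conditions
#'
#' @param profile one cohort row.
#' @param clamp optional [simulate_clamp()] record; its late (>= 60 min)
#'   glucose samples set the plasma glucose used for tracer/glucose
#'   consistency, otherwise 5.0 mmol/L is assumed.
#' @param sampling_times strictly increasing times > 0 (min).
#' @param seed integer seed for multiplicative TAC noise; `NULL` gives
#'   noiseless curves.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal TAC noise (>= 0).
#' @param regions tissue regions to scan.
#' @param input_shape optional list with `weights`, `decays`, `rise`
#'   overriding the default bolus shape (see [input_function()]).
#' @return object of class `fdg_study`: `plasma` ([tac()]), `tissues`
#'   (named list of [tac()]), `injected_dose_mbq`, `urine_activity_mbq`,
#'   `avg_glucose_mmol_l` and the underlying `input_function`.
#' @examples
#' pr <- subject_profile()
#' st <- simulate_fdg_study(pr, seed = 1)
#' st$plasma
#' @export
simulate_fdg_study <- function(profile, clamp = NULL,
                               sampling_times = .default_fdg_times,
                               seed = NULL,
                               noise_cv = default_noise_levels()[["tac"]],
                               regions = c("muscle", "liver", "asat"),
                               input_shape = NULL) {
  if (noise_cv < 0)
    stop_config("noise_cv must be >= 0")
  if (any(sampling_times <= 0) || any(diff(sampling_times) <= 0))
    stop_config("sampling_times must be strictly increasing and > 0")
  glucose <- 5.0
  if (!is.null(clamp)) {
    late <- clamp$samples$glucose_mmol_l[clamp$samples$time_min >= 60]
    if (length(late)) glucose <- mean(late)
  }
  dose_mbq <- profile[["dose_mbq"]] %||% 160
  urine_frac <- profile[["urine_fraction"]] %||% 0.10
  urine_mbq <- urine_frac * dose_mbq
  weight <- profile[["weight_kg"]]
  clearance_ml_min <- profile[["disposal_umol_kg_min"]] * weight / glucose
  total_auc <- (dose_mbq - urine_mbq) * 1000 / clearance_ml_min  # kBq*min/mL
  f <- if (is.null(input_shape)) input_function(total_auc = total_auc) else
    do.call(input_function, c(list(total_auc = total_auc), input_shape))

  cp <- input_eval(f, sampling_times)
  tissues <- lapply(regions, function(r) {
    tissue_curve_exact(profile_kinetics(profile, r), f, sampling_times)
  })
  names(tissues) <- regions

  if (!is.null(seed)) {
    k <- length(sampling_times)
    noise <- with_seed(seed, {
      lapply(seq_len(length(regions) + 1L),
             function(i) exp(rnorm(k, 0, noise_cv)))
    })
    cp <- cp * noise[[1]]
    tissues <- lapply(seq_along(tissues), function(i)
      tissues[[i]] * noise[[i + 1L]])
    names(tissues) <- regions
  }

  structure(list(
    subject_id = profile[["subject_id"]] %||% "subject",
    plasma = tac(sampling_times, cp, "plasma"),
    tissues = Map(function(a, r) tac(sampling_times, a, r),
                  tissues, regions),
    injected_dose_mbq = dose_mbq,
    urine_activity_mbq = urine_mbq,
    avg_glucose_mmol_l = glucose,
    input_function = f),
    class = "fdg_study")
}
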