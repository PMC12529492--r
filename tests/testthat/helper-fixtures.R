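# Shared fixtures, all built in code.

# Reference rate constants used throughout the kinetic tests.
ref_params <- c(K1 = 0.1, k2 = 0.15, k3 = 0.05)
ref_ki <- unname(ref_params["K1"] * ref_params["k3"] /
                   (ref_params["k2"] + ref_params["k3"]))  # 0.025

# Noiseless plasma + tissue curves on the default sampling grid.
make_study_curves <- function(params = ref_params, total_auc = 3000,
                              times = fdgclamp:::.default_fdg_times) {
  f <- input_function(total_auc = total_auc)
  list(f = f,
       plasma = tac(times, input_eval(f, times), "plasma"),
       tissue = tac(times,
                    fdgclamp:::tissue_curve_exact(params, f, times),
                    "tissue"))
}

cohort_covariates <- function(coh, scan_timing = FALSE) {
  tab <- data.frame(sex = as.numeric(coh$sex == "M"),
                    age = coh$age_years, bmi = coh$bmi_kg_m2)
  if (scan_timing) tab$scan_timing <- coh$scan_timing_min
  tab
}

# Equalized group demographics: isolates programmed effects from the
# default BMI/sex imbalance between groups.
balanced_null_config <- function(n_per_group, seed) {
  cohort_config(n_per_group = n_per_group, seed = seed,
                effect_scales = null_effect_scales(),
                sex_fraction_per_group = c(LL = 0.7, MEL = 0.7),
                bmi_params_per_group = list(
                  LL = c(median = 27, sdlog = 0.13),
                  MEL = c(median = 27, sdlog = 0.13)))
}
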