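test_that("config validation names the offending field", {
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  expect_error(cohort_config(noise_levels = c(tac = -0.1)), "noise_levels")
  expect_error(cohort_config(noise_levels = c(bogus = 0.1)), "noise_levels")
  expect_error(cohort_config(effect_scales = c(not_an_outcome = 1)),
               "effect_scales")
  expect_error(cohort_config(sex_fraction_per_group = c(LL = 1.2, MEL = 0.5)),
               "sex_fraction")
  expect_error(cohort_config(urine_fraction = 1.2), "urine_fraction")
})

test_that("identical seed and config give an identical cohort", {
  cfg <- cohort_config(n_per_group = 15, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_per_group = 15, seed = 12)
  expect_false(identical(generate_cohort(cfg)$bmi_kg_m2,
                         generate_cohort(cfg2)$bmi_kg_m2))
})

test_that("liver-lipid intervals partition the groups exactly", {
  coh <- generate_cohort(cohort_config(n_per_group = 200, seed = 3))
  ll <- coh$htg_percent[coh$group == "LL"]
  mel <- coh$htg_percent[coh$group == "MEL"]
  expect_true(all(ll > 0 & ll <= 1.85))
  expect_true(all(mel > 1.85 & mel <= 5.56))
  expect_equal(nrow(coh), 400)
  expect_true(all(coh[grep("^k[123]_", names(coh))] > 0))
  expect_true(all(coh$egp_suppression_frac >= 0 & coh$egp_suppression_frac <= 1))
})

test_that("default cohort medians sit near the calibration targets", {
  # averaged over seeds to separate calibration from sampling noise
  med <- rowMeans(sapply(1:6, function(s) {
    coh <- generate_cohort(cohort_config(seed = s))
    by_group <- function(v) tapply(v, coh$group, median)
    c(by_group(coh$htg_percent),
      by_group(coh$fasting_insulin_pmol_l * coh$fasting_ffa_mmol_l))
  }))
  expect_equal(unname(med[1]), 0.9, tolerance = 0.12)   # HTG LL
  expect_equal(unname(med[2]), 3.2, tolerance = 0.08)   # HTG MEL
  expect_equal(unname(med[3]), 17.6, tolerance = 0.12)  # Adipo-IR LL
  expect_equal(unname(med[4]), 28.4, tolerance = 0.12)  # Adipo-IR MEL
})

test_that("null effect scales leave group outcome distributions exchangeable", {
  # two-sample p-values over seeds are uniform for a balanced null config
  ps <- sapply(1:60, function(s) {
    coh <- generate_cohort(balanced_null_config(60, seed = 700 + s))
    t.test(log(fasting_insulin_pmol_l) ~ group, data = coh)$p.value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("downstream adjusted comparisons are null-calibrated across seeds", {
  # default (imbalanced) groups, zero effects: covariate adjustment must
  # absorb the BMI/sex differences
  ps <- sapply(1:60, function(s) {
    coh <- generate_cohort(cohort_config(n_per_group = 60, seed = 900 + s,
                                         effect_scales = null_effect_scales()))
    adjusted_group_comparison(coh$fasting_ffa_mmol_l, coh$group,
                              cohort_covariates(coh), transform = "log")$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
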