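ogtt_df <- function(g, i, times = c(0, 30, 60, 120)) {
  data.frame(time_min = times, glucose_mmol_l = g, insulin_pmol_l = i)
}

test_that("HOMA-IR matches its calibration point and hand arithmetic", {
  expect_equal(homa_ir(5, 4.5, insulin_unit = "uu_ml"), 1)
  expect_equal(homa_ir(5.6, 9, insulin_unit = "uu_ml"), 2.24)
  # pmol/L route with the default factor 6
  expect_equal(homa_ir(5.6, 54), 2.24)
  # monotone limit in insulin
  expect_lt(homa_ir(5, 1e-6, insulin_unit = "uu_ml"), 1e-6)
  expect_error(homa_ir(-5, 10), "positive")
})

test_that("Matsuda ISI follows the simplified formula and its homogeneity", {
  o <- ogtt_df(c(10, 11, 12, 10), c(10, 50, 40, 10))
  expect_equal(as.numeric(matsuda_isi(o)), 100)  # all four inputs 10
  o2 <- ogtt_df(c(5, 7, 6.5, 6), c(40, 300, 250, 50))
  expect_equal(as.numeric(matsuda_isi(o2)), 10000 / sqrt(5 * 40 * 6 * 50))
  # doubling insulin at both ends halves the index
  o3 <- o2; o3$insulin_pmol_l <- 2 * o3$insulin_pmol_l
  expect_equal(as.numeric(matsuda_isi(o3)),
               as.numeric(matsuda_isi(o2)) / 2)
  # unit convention is recorded and changes the scale deterministically
  expect_identical(attr(matsuda_isi(o2, "mgdl"), "units_mode"), "mgdl")
  expect_equal(as.numeric(matsuda_isi(o2, "mgdl")),
               as.numeric(matsuda_isi(o2)) * sqrt(6 * 6 / (18.016 * 18.016)))
  expect_error(matsuda_isi(ogtt_df(c(5, 7), c(40, 300), times = c(0, 30))),
               "120-min")
})

test_that("secretion indices are trapezoid ratios on the stated points", {
  o <- ogtt_df(c(5, 8, 7, 6), c(60, 300, 240, 120))
  expect_equal(secretion_first_phase(o), 5400 / 195)
  o2 <- ogtt_df(c(5, 6, 7, 6), c(60, 90, 240, 120))
  expect_equal(secretion_total_phase(o2),
               ((150 * 60) + (180 * 60)) / ((6 * 60) + (6.5 * 60)))
  # constants give I/G; linear homogeneity
  oc <- ogtt_df(rep(6, 4), rep(90, 4))
  expect_equal(secretion_first_phase(oc), 15)
  expect_equal(secretion_total_phase(oc), 15)
  od <- oc; od$insulin_pmol_l <- 2 * od$insulin_pmol_l
  expect_equal(secretion_first_phase(od), 30)
  oh <- oc; oh$glucose_mmol_l <- oh$glucose_mmol_l / 2
  expect_equal(secretion_total_phase(oh), 30)
})

test_that("Adipo-IR products and the glycerol variant", {
  expect_equal(adipo_ir(60, 0.5), 30)
  expect_equal(adipo_ir(60, 0), 0)
  expect_equal(adipo_ir_glycerol(100, 0.05), 5)
  expect_equal(adipo_ir_glycerol(100, 0), 0)
  expect_error(adipo_ir_glycerol(100), "glycerol")
  expect_error(adipo_ir(-1, 0.5), "positive")
})

test_that("unit conversions round-trip exactly", {
  x <- c(0.3, 7, 120)
  expect_equal(insulin_uu_to_pmol(insulin_pmol_to_uu(x)), x)
  expect_equal(glucose_mgdl_to_mmol(glucose_mmol_to_mgdl(x)), x)
})

test_that("OGTT simulator honours its degenerate and directional contracts", {
  pr <- subject_profile()
  # flat response parameters keep glucose at fasting level
  o0 <- simulate_ogtt(pr, seed = NULL, glucose_amp = 0, insulin_amp = 0)
  expect_equal(o0$glucose_mmol_l, rep(pr$fasting_glucose_mmol_l, 4))
  expect_equal(o0$insulin_pmol_l, rep(pr$fasting_insulin_pmol_l, 4))
  # determinism
  expect_identical(simulate_ogtt(pr, seed = 4), simulate_ogtt(pr, seed = 4))
  # cohort medians: MEL total-phase secretion above LL, Matsuda below
  coh <- generate_cohort(cohort_config(n_per_group = 60, seed = 21))
  idx <- compute_indices(coh, do.call(rbind, lapply(seq_len(nrow(coh)),
    function(i) simulate_ogtt(coh[i, ], seed = 100 + i))))
  med <- function(v) tapply(v, coh$group, median)
  tot <- med(idx$secretion_total_pmol_mmol)
  mats <- med(idx$matsuda_isi)
  expect_gt(tot[["MEL"]], tot[["LL"]])
  expect_lt(mats[["MEL"]], mats[["LL"]])
})
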