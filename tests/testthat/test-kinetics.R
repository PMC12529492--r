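make_clamp_record <- function(times, gir, sample_times, glucose) {
  structure(list(
    subject_id = "T1",
    gir = data.frame(time_min = times, gir_umol_kg_min = gir),
    samples = data.frame(time_min = sample_times,
                         glucose_mmol_l = glucose,
                         insulin_pmol_l = rep(400, length(sample_times))),
    insulin_infusion_rate_mu_m2_min = 40, weight_kg = 70),
    class = "clamp_record")
}

test_that("M-value averages three 20-min interval means from steady state", {
  tm <- seq(0, 180, by = 5)
  # constant GIR after steady state
  cl <- make_clamp_record(tm, rep(30, length(tm)), seq(0, 180, 30),
                          c(5.8, rep(5, 6)))
  mv <- m_value(cl)
  expect_equal(mv$m, 30)
  expect_equal(mv$t_steady, 30)

  # piecewise trace with interval means 28, 30, 32 from t0 = 30
  gir <- ifelse(tm < 30, 10,
         ifelse(tm < 50, 28, ifelse(tm < 70, 30, ifelse(tm < 90, 32, 25))))
  # ensure interval endpoints average correctly: build exact step means
  cl2 <- make_clamp_record(c(30, 49.9999, 50, 69.9999, 70, 90, 180),
                           c(28, 28, 30, 30, 32, 32, 32),
                           seq(0, 180, 30), c(5.8, rep(5, 6)))
  mv2 <- m_value(cl2)
  expect_equal(mv2$interval_means, c(28, 30, 32), tolerance = 1e-3)
  expect_equal(mv2$m, 30, tolerance = 1e-3)
})

test_that("steady state outside tolerance or trace raises an error", {
  tm <- seq(0, 180, by = 5)
  cl <- make_clamp_record(tm, rep(30, length(tm)), seq(0, 180, 30),
                          c(5.8, rep(6.0, 6)))
  expect_error(m_value(cl), "steady state never reached")
  # qualifying only within the last hour margin
  cl2 <- make_clamp_record(tm, rep(30, length(tm)), seq(0, 180, 30),
                           c(5.8, 6, 6, 6, 6, 5.0, 5.0))
  expect_error(m_value(cl2), "steady state never reached")
})

test_that("Rd follows the urine-corrected clearance formula", {
  # dense mono-exponential plasma: AUC known in closed form
  tt <- seq(0.05, 120, by = 0.05)
  lam <- 0.03; a0 <- 30
  pl <- tac(tt, a0 * exp(-lam * tt), "plasma")
  auc_true <- a0 / lam  # kBq*min/mL (tail fit is exact here)
  rd <- rate_of_disappearance(100, 10, pl, avg_glucose = 5, weight = 70)
  expect_equal(rd, (90 * 1000 / auc_true) * 5 / 70, tolerance = 2e-3)

  # linearity in (dose - urine): removing a 10% urine loss scales Rd by 1/0.9
  rd0 <- rate_of_disappearance(100, 0, pl, 5, 70)
  expect_equal(rd0 / rd, 1 / 0.9, tolerance = 1e-12)

  expect_error(rate_of_disappearance(100, 150, pl, 5, 70), "urine")
  expect_error(rate_of_disappearance(100, 10, pl, 5, -1), "weight")
  rising <- tac(c(1, 2, 3, 60, 90, 120), c(1, 1, 1, 1, 2, 3), "plasma")
  expect_error(rate_of_disappearance(100, 0, rising, 5, 70), "not decaying")
})

test_that("trapezoid + exponential tail reproduces the parametric AUC within 1%", {
  cur <- make_study_curves()
  expect_equal(fdgclamp:::plasma_auc(cur$plasma), input_auc(cur$f),
               tolerance = 0.01)
})

test_that("EGP is exactly Rd minus GIR, negatives preserved", {
  expect_equal(endogenous_glucose_production(10, 8)$egp, 2)
  expect_equal(endogenous_glucose_production(8, 8.2)$egp, -0.2)
  expect_equal(endogenous_glucose_production(8, 8)$egp, 0)
  r <- endogenous_glucose_production(12.3456789, 10.1112131)
  expect_identical(r$egp, 12.3456789 - 10.1112131)
  expect_error(endogenous_glucose_production(NA, 1), "finite")
})

test_that("noiseless end-to-end quantification recovers programmed disposal", {
  coh <- generate_cohort(cohort_config(n_per_group = 5, seed = 17))
  for (i in seq_len(nrow(coh))) {
    p <- coh[i, ]
    cl <- simulate_clamp(p, seed = NULL)
    st <- simulate_fdg_study(p, cl, seed = NULL)
    q <- quantify_subject(st, cl, weight = p$weight_kg)
    expect_equal(q$rd_umol_kg_min, p$disposal_umol_kg_min, tolerance = 0.05)
    egp_true <- p$basal_egp_umol_kg_min * (1 - p$egp_suppression_frac)
    expect_lt(abs(q$egp_umol_kg_min - egp_true), 0.5)
    # Patlak Ki against the closed-form oracle for each region, using a
    # window start beyond free-compartment equilibration (t* >= 3/(k2+k3))
    for (r in c("muscle", "liver", "asat")) {
      kin <- fdgclamp:::profile_kinetics(p, r)
      ki_true <- unname(kin["K1"] * kin["k3"] / (kin["k2"] + kin["k3"]))
      ts <- max(20, 3 / (kin[["k2"]] + kin[["k3"]]))
      fit <- patlak_ki(st$tissues[[r]], st$plasma, t_star = ts)
      expect_equal(fit$ki, ki_true, tolerance = 0.02)
    }
  }
})
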