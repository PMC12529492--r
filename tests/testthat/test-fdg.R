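test_that("input function has an exact closed-form AUC and zero onset", {
  f <- input_function(total_auc = 3000)
  expect_equal(input_eval(f, 0), 0, tolerance = 1e-12)
  expect_equal(input_auc(f), 3000, tolerance = 1e-9)
  # integral helper matches fine-grid quadrature
  tt <- seq(0, 120, by = 0.01)
  expect_equal(input_integral(f, 120),
               pracma::trapz(tt, input_eval(f, tt)), tolerance = 1e-5)
})

test_that("compartment solver matches known limits", {
  # zero plasma input -> zero tissue activity
  pl0 <- tac(c(1, 10, 60), c(0, 0, 0) + 1e-300, "plasma")
  ct <- solve_irreversible_2tc(ref_params, pl0, c(10, 30, 60))
  expect_equal(max(abs(ct$activities)), 0, tolerance = 1e-12)

  # k3 = 0, constant input: equilibrium volume K1/k2
  tt <- seq(0.5, 400, by = 0.5)
  plc <- tac(tt, rep(10, length(tt)), "plasma")
  ct2 <- solve_irreversible_2tc(c(K1 = 0.1, k2 = 0.15, k3 = 0), plc,
                                c(300, 350, 400))
  expect_equal(tail(ct2$activities, 1), 10 * 0.1 / 0.15, tolerance = 0.01)

  # step input: late-time slope tends to Ki * Cp
  ct3 <- solve_irreversible_2tc(ref_params, plc, seq(200, 400, by = 10))
  slope <- coef(lm(ct3$activities ~ ct3$times))[2]
  expect_equal(unname(slope), ref_ki * 10, tolerance = 0.01)
})

test_that("numerical solver agrees with the exact exponential solution", {
  cur <- make_study_curves()
  eval_t <- c(10, 20, 40, 60, 90, 120)
  num <- solve_irreversible_2tc(ref_params, cur$plasma, eval_t, dt = 0.02)
  exact <- fdgclamp:::tissue_curve_exact(ref_params, cur$f, eval_t)
  expect_equal(num$activities, exact, tolerance = 0.01)
  expect_error(solve_irreversible_2tc(ref_params, cur$plasma, c(10, 500)),
               "beyond the plasma support")
})

test_that("the FDG study is linear in dose and deterministic in seed", {
  pr <- subject_profile()
  a <- simulate_fdg_study(pr, seed = 3)
  expect_identical(a, simulate_fdg_study(pr, seed = 3))
  pr2 <- pr; pr2$dose_mbq <- 2 * pr$dose_mbq
  b <- simulate_fdg_study(pr2, seed = 3)
  expect_equal(b$plasma$activities, 2 * a$plasma$activities, tolerance = 1e-12)
  expect_equal(b$tissues$muscle$activities, 2 * a$tissues$muscle$activities,
               tolerance = 1e-12)
  expect_error(simulate_fdg_study(pr, noise_cv = -0.1), "noise_cv")
})

test_that("a region without trapping has a vanishing late Patlak slope", {
  pr <- subject_profile(k3_muscle_1_min = 0)
  # k3 = 0 violates no contract of the forward model
  st <- simulate_fdg_study(pr, seed = NULL)
  fit <- patlak_ki(st$tissues$muscle, st$plasma, t_star = 40)
  expect_lt(abs(fit$ki), 1e-3)  # two orders below a typical muscle Ki
})
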