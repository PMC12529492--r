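test_that("metabolome simulation is deterministic and respects effect maps", {
  coh <- generate_cohort(cohort_config(n_per_group = 10, seed = 8))
  a <- simulate_metabolome(coh[1, ], seed = 4)
  expect_identical(a, simulate_metabolome(coh[1, ], seed = 4))
  expect_true(all(a[, -1] > 0))
  expect_error(simulate_metabolome(coh[1, ], seed = 4,
                                   effects = c(NotAMeasure = 1)),
               "unknown measure")
  # batch generation matches subject-wise child-seed calls
  mm <- simulate_metabolome_cohort(coh, seed = 9)
  one <- simulate_metabolome(coh[3, ], seed = fdgclamp:::child_seed(9, 3, 4L))
  expect_equal(unlist(mm[3, -1]), unlist(one[-1]), tolerance = 1e-12)
  expect_identical(names(mm)[-1], default_metabolite_panel()$measure)
})

test_that("a dominant measure is flagged with minimal q among the panel", {
  set.seed(61)
  n <- 120
  g <- rep(c(0, 1), each = n / 2)
  panel <- data.frame(signal = exp(g + rnorm(n, 0, 0.05)))
  for (j in 1:9) panel[[paste0("null", j)]] <- exp(rnorm(n))
  sc <- metabolite_scan(panel, g, NULL)
  expect_equal(sc$measure[which.min(sc$q)], "signal")
  expect_gt(sc$or[sc$measure == "signal"], 10)
  # near-separation triggers the Firth fallback note
  expect_match(sc$note[sc$measure == "signal"], "firth", ignore.case = TRUE)
})

test_that("null measures give odds ratios near 1", {
  set.seed(62)
  n <- 600
  g <- rep(c(0, 1), each = n / 2)
  panel <- as.data.frame(matrix(exp(rnorm(n * 20)), n, 20))
  names(panel) <- paste0("m", 1:20)
  sc <- metabolite_scan(panel, g, NULL)
  expect_true(all(abs(log(sc$or)) < 0.35))
  expect_gt(median(sc$q), 0.3)
})

test_that("the scan OR is invariant to affine rescaling of a measure", {
  coh <- generate_cohort(cohort_config(n_per_group = 40, seed = 13))
  mm <- simulate_metabolome_cohort(coh, seed = 13)
  covs <- cohort_covariates(coh)
  sc1 <- metabolite_scan(mm, coh$group, covs)
  mm2 <- mm
  mm2$Serum_TG <- mm2$Serum_TG * 1000  # unit change mmol/L -> umol/L
  sc2 <- metabolite_scan(mm2, coh$group, covs)
  expect_equal(sc1$or[sc1$measure == "Serum_TG"],
               sc2$or[sc2$measure == "Serum_TG"], tolerance = 1e-8)
  expect_error(metabolite_scan(mm[, 1:2], coh$group, covs), "2 measures")
})

test_that("programmed log2 shifts are recovered by the scan estimate", {
  panel_spec <- metabolite_panel_spec(c("shifted", "null1", "null2"),
                                      median_ll = 1, sdlog2 = 0.5)
  # large-sample oracle for the OR per SD implied by a 0.8-SD shift
  big <- generate_cohort(balanced_null_config(4000, seed = 499))
  mm_big <- simulate_metabolome_cohort(big, seed = 499,
                                       effects = c(shifted = 0.8),
                                       panel = panel_spec)
  or_ref <- metabolite_scan(mm_big, big$group, NULL)
  or_ref <- or_ref$or[or_ref$measure == "shifted"]
  expect_gt(or_ref, 1.5)  # a 0.8-SD shift is a strong association

  hits <- sapply(1:40, function(r) {
    coh <- generate_cohort(balanced_null_config(60, seed = 400 + r))
    mm <- simulate_metabolome_cohort(coh, seed = 400 + r,
                                     effects = c(shifted = 0.8),
                                     panel = panel_spec)
    sc <- metabolite_scan(mm, coh$group, NULL)
    row <- sc[sc$measure == "shifted", ]
    c(inside = row$ci_low <= or_ref & or_ref <= row$ci_high,
      positive = row$or > 1)
  })
  expect_gte(mean(hits["inside", ]), 0.9)
  expect_gte(mean(hits["positive", ]), 0.95)
})
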