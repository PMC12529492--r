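# Serum NMR-style metabolite panel simulator. Measures are log-normal with
# block correlation by lipoprotein/metabolite class; the MEL group mean is
# shifted on the log2 scale by a configurable number of between-subject SDs
# per measure.

#' Metabolite panel specification
#'
#' `default_metabolite_panel()` returns the built-in 31-measure panel
#' (lipids, lipoprotein subclass summaries, fatty-acid ratios, amino acids,
#' glycolysis intermediates, glycoprotein acetyls). `metabolite_panel_spec()`
#' builds a custom panel, e.g. for simulation studies with programmed
#' null/shifted measures.
#'
#' @param measure character measure names (unique).
#' @param median_ll LL-group median concentration (assay units, > 0).
#' @param sdlog2 between-subject SD on the log2 scale.
#' @param block correlation block label (measures sharing a label are
#'   correlated with intra-block correlation `rho`, see
#'   [simulate_metabolome()]).
#' @param bmi_log2,age_log2,male_log2 log2-scale covariate slopes
#'   (per BMI unit above 26, per year above 48, for male sex).
#' @return data.frame with one row per measure.
#' @examples
#' metabolite_panel_spec(c("m1", "m2"), median_ll = c(1, 2), sdlog2 = 0.5)
#' @export
metabolite_panel_spec <- function(measure, median_ll, sdlog2 = 0.5,
                                  block = measure,
                                  bmi_log2 = 0, age_log2 = 0,
                                  male_log2 = 0) {
  if (anyDuplicated(measure))
    stop_config("panel measure names must be unique")
  if (any(median_ll <= 0)) stop_config("panel medians must be positive")
  data.frame(measure = as.character(measure),
             median_ll = median_ll,
             sdlog2 = sdlog2,
             block = as.character(block),
             bmi_log2 = bmi_log2, age_log2 = age_log2,
             male_log2 = male_log2,
             stringsAsFactors = FALSE)
}

#' @rdname metabolite_panel_spec
#' @export
default_metabolite_panel <- function() {
  p <- function(measure, med, sd2, block, bmi, male) {
    metabolite_panel_spec(measure, med, sd2, block,
                          bmi_log2 = bmi, male_log2 = male)
  }
  rbind(
    p("Serum_TG",    1.00, 0.55, "vldl", 0.040,  0.10),
    p("VLDL_TG",     0.55, 0.65, "vldl", 0.045,  0.10),
    p("VLDL_C",      0.65, 0.45, "vldl", 0.035,  0.08),
    p("VLDL_size",  36.5,  0.07, "vldl", 0.004,  0.01),
    p("Total_FA",   10.5,  0.25, "vldl", 0.015,  0.03),
    p("MUFA_pct",   28.0,  0.12, "fa",   0.008,  0.01),
    p("PUFA_pct",   38.0,  0.10, "fa",  -0.006, -0.02),
    p("Omega6_pct", 32.0,  0.10, "fa",  -0.005, -0.02),
    p("DHA_pct",     1.50, 0.25, "fa",  -0.003, -0.04),
    p("IDL_C",       0.70, 0.35, "apob", 0.020,  0.03),
    p("LDL_C",       1.40, 0.35, "apob", 0.015,  0.03),
    p("LDL_size",   23.6,  0.02, "apob", 0.000,  0.00),
    p("ApoB",        0.85, 0.30, "apob", 0.020,  0.03),
    p("HDL_C",       1.50, 0.25, "hdl", -0.015, -0.10),
    p("HDL_size",    9.90, 0.05, "hdl", -0.004, -0.02),
    p("ApoA1",       1.55, 0.15, "hdl", -0.005, -0.06),
    p("Ile",         0.055, 0.35, "bcaa", 0.020,  0.20),
    p("Leu",         0.075, 0.28, "bcaa", 0.018,  0.20),
    p("Val",         0.180, 0.25, "bcaa", 0.015,  0.18),
    p("Phe",         0.075, 0.18, "aa",   0.010,  0.05),
    p("Tyr",         0.055, 0.22, "aa",   0.012,  0.05),
    p("Ala",         0.330, 0.20, "aa",   0.012,  0.02),
    p("Gln",         0.500, 0.18, "aa",   0.000,  0.00),
    p("His",         0.065, 0.16, "aa",   0.000,  0.02),
    p("Lactate",     1.10, 0.35, "glyc",  0.020,  0.02),
    p("Pyruvate",    0.075, 0.40, "glyc", 0.020,  0.02),
    p("Citrate",     0.110, 0.20, "glyc", 0.000,  0.00),
    p("Glycerol",    0.056, 0.40, "glyc", 0.020, -0.10),
    p("GlycA",       1.20, 0.25, "inflam", 0.025, 0.03),
    p("Glucose_NMR", 5.40, 0.09, "gluc",  0.006,  0.01),
    p("Creatinine",  0.065, 0.18, "misc", 0.000,  0.25)
  )
}

# Default MEL-vs-LL shifts (SD units, log2 scale) for the built-in panel:
# positive for triglycerides, VLDL/LDL lipids, apolipoprotein B, BCAAs,
# glycolysis intermediates and glycoprotein acetyls; negative for HDL size
# and PUFA ratios; zero for designated null measures (HDL-C, ApoA1, LDL
# size, glutamine, histidine, citrate, creatinine).
default_metabolite_effects <- function() {
  c(Serum_TG = 0.65, VLDL_TG = 0.65, VLDL_C = 0.45, VLDL_size = 0.40,
    Total_FA = 0.40, MUFA_pct = 0.30, PUFA_pct = -0.45, Omega6_pct = -0.40,
    DHA_pct = -0.20, IDL_C = 0.40, LDL_C = 0.35, LDL_size = 0, ApoB = 0.45,
    HDL_C = 0, HDL_size = -0.45, ApoA1 = 0, Ile = 0.70, Leu = 0.60,
    Val = 0.60, Phe = 0.15, Tyr = 0.15, Ala = 0.20, Gln = 0, His = 0,
    Lactate = 0.45, Pyruvate = 0.45, Citrate = 0, Glycerol = 0.35,
    GlycA = 0.50, Glucose_NMR = 0.20, Creatinine = 0)
}

# One subject's panel draw; correlation within blocks via a shared factor.
.metabolome_draw_one <- function(profile, panel, eff, rho) {
  m <- nrow(panel)
  blocks <- factor(panel$block)
  bf <- rnorm(nlevels(blocks))[as.integer(blocks)]
  z <- sqrt(rho) * bf + sqrt(1 - rho) * rnorm(m)
  is_mel <- identical(profile[["group"]], "MEL")
  mu2 <- log2(panel$median_ll) +
    (if (is_mel) eff * panel$sdlog2 else 0) +
    panel$bmi_log2 * (profile[["bmi_kg_m2"]] - 26) +
    panel$age_log2 * (profile[["age_years"]] - 48) +
    panel$male_log2 * as.numeric(profile[["sex"]] == "M")
  vals <- 2^(mu2 + panel$sdlog2 * z)
  # Tie measures that duplicate profile ground truth to the profile value
  # (assay noise only), keeping the cohort internally consistent.
  cv <- 0.05
  if ("Glycerol" %in% panel$measure && !is.null(profile[["fasting_glycerol_mmol_l"]]))
    vals[panel$measure == "Glycerol"] <-
      profile[["fasting_glycerol_mmol_l"]] * exp(rnorm(1, 0, cv))
  if ("Glucose_NMR" %in% panel$measure && !is.null(profile[["fasting_glucose_mmol_l"]]))
    vals[panel$measure == "Glucose_NMR"] <-
      profile[["fasting_glucose_mmol_l"]] * exp(rnorm(1, 0, cv))
  setNames(vals, panel$measure)
}

#' Simulate a fasting serum metabolite panel
#'
#' Each measure is log-normal; for MEL-group subjects the mean is shifted on
#' the log2 scale by `effects[measure] * sdlog2[measure]`. Correlation is
#' block-diagonal by measure class with intra-block correlation `rho`.
#' `Glycerol` and `Glucose_NMR` (when present in the panel) reproduce the
#' subject's fasting values up to assay noise so that the panel agrees with
#' the cohort table.
#'
#' @param profile one cohort row (see [generate_cohort()]).
#' @param seed integer seed; identical seed and profile give an identical
#'   panel.
#' @param effects named standardized shifts; defaults to the panel's
#'   built-in effects for the default panel, zero for unknown custom
#'   measures. Unknown names are a configuration error.
#' @param panel a panel specification (see [metabolite_panel_spec()]).
#' @param rho intra-block correlation in \[0, 1).
#' @return one-row data.frame: `subject_id` plus one positive concentration
#'   column per measure.
#' @examples
#' coh <- generate_cohort(cohort_config(n_per_group = 2, seed = 1))
#' simulate_metabolome(coh[1, ], seed = 5)
#' @export
simulate_metabolome <- function(profile, seed,
                                effects = NULL,
                                panel = default_metabolite_panel(),
                                rho = 0.4) {
  eff <- .resolve_metabolite_effects(effects, panel)
  with_seed(seed, {
    vals <- .metabolome_draw_one(profile, panel, eff, rho)
    cbind(data.frame(subject_id = profile[["subject_id"]],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), check.names = FALSE))
  })
}

.resolve_metabolite_effects <- function(effects, panel) {
  eff <- setNames(numeric(nrow(panel)), panel$measure)
  defaults <- default_metabolite_effects()
  known <- intersect(names(defaults), panel$measure)
  eff[known] <- defaults[known]
  if (!is.null(effects)) {
    unknown <- setdiff(names(effects), panel$measure)
    if (length(unknown))
      stop_config("unknown measure name(s) in effect map: %s",
                  paste(unknown, collapse = ", "))
    eff[] <- 0  # an explicit map replaces the defaults wholesale
    eff[names(effects)] <- effects
  }
  eff
}

#' @rdname simulate_metabolome
#' @param cohort a full cohort table; per-subject child seeds derive from
#'   `seed` so the batch output matches subject-wise calls.
#' @export
simulate_metabolome_cohort <- function(cohort, seed, effects = NULL,
                                       panel = default_metabolite_panel(),
                                       rho = 0.4) {
  eff <- .resolve_metabolite_effects(effects, panel)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    with_seed(child_seed(seed, i, salt = 4L),
              .metabolome_draw_one(cohort[i, ], panel, eff, rho))
  })
  mat <- do.call(rbind, rows)
  cbind(data.frame(subject_id = cohort$subject_id, stringsAsFactors = FALSE),
        as.data.frame(mat, check.names = FALSE))
}
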