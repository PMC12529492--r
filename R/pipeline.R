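# End-to-end pipeline: simulate -> quantify -> indices -> compare, with a
# manifest of content hashes so identical config + seed gives identical
# artifacts.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()].
#' @param kinetics list: `t_star` (Patlak window start, min), `tolerance`
#'   (steady-state glucose tolerance, mmol/L), `duration` (clamp min).
#' @param indices list: `units_mode` ("si"/"mgdl"), `conversion_factor`
#'   (insulin pmol/L per uU/mL).
#' @param stats list: `covariates` (subset of sex, age, bmi),
#'   `scan_timing_covariate` (add PET scan timing to tissue-GU models),
#'   `transform`, `lambda` (Storey grid).
#' @param seed master seed; defaults to the cohort seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            kinetics = list(t_star = 20, tolerance = 0.3,
                                            duration = 180),
                            indices = list(units_mode = "si",
                                           conversion_factor = 6),
                            stats = list(covariates = c("sex", "age", "bmi"),
                                         scan_timing_covariate = TRUE,
                                         transform = "auto",
                                         lambda = seq(0.05, 0.95, 0.05)),
                            seed = NULL) {
  if (!inherits(cohort, "cohort_config"))
    stop_config("cohort must be a cohort_config")
  defaults <- eval(formals(pipeline_config)$kinetics)
  kinetics <- modifyList(defaults, kinetics)
  indices <- modifyList(eval(formals(pipeline_config)$indices), indices)
  stats <- modifyList(eval(formals(pipeline_config)$stats), stats)
  structure(list(cohort = cohort, kinetics = kinetics, indices = indices,
                 stats = stats, seed = as.integer(seed %||% cohort$seed)),
            class = "pipeline_config")
}

# Covariate table used by the comparison and scan stages.
.covariate_table <- function(cohort, covariates, scan_timing = FALSE) {
  tab <- data.frame(row.names = seq_len(nrow(cohort)))
  if ("sex" %in% covariates) tab$sex <- as.numeric(cohort$sex == "M")
  if ("age" %in% covariates) tab$age <- cohort$age_years
  if ("bmi" %in% covariates) tab$bmi <- cohort$bmi_kg_m2
  if (scan_timing) tab$scan_timing <- cohort$scan_timing_min
  tab
}

#' Run the full pipeline
#'
#' Generates the synthetic cohort, simulates clamp / FDG-PET / OGTT /
#' metabolome records for every subject, quantifies tracer kinetics,
#' computes insulin indices, runs the covariate-adjusted group comparisons
#' and the metabolite scan, and writes all artifacts plus a manifest with
#' per-file MD5 content hashes to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (list with `artifacts`, `seed`,
#'   `config`).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort_config(n_per_group = 5, seed = 11))
#' man <- run_pipeline(cfg, tempfile("run"))
#' names(man$artifacts)
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  meta <- list(seed = seed, package = "fdgclamp",
               units = "glucose mmol/L; insulin pmol/L; FFA/glycerol mmol/L; activity kBq/mL; time min")

  stage <- "simulate"; current_subject <- NA_character_
  res <- tryCatch({
    cohort <- generate_cohort(config$cohort)
    noise <- config$cohort$noise_levels

    tac_rows <- list(); clamp_rows <- list(); ogtt_rows <- list()
    kin_rows <- list(); dose_rows <- list()
    for (i in seq_len(nrow(cohort))) {
      p <- cohort[i, ]
      current_subject <- p$subject_id
      cl <- simulate_clamp(p, duration = config$kinetics$duration,
                           seed = child_seed(seed, i, 1L),
                           noise_levels = noise)
      st <- simulate_fdg_study(p, cl, seed = child_seed(seed, i, 2L),
                               noise_cv = noise[["tac"]])
      og <- simulate_ogtt(p, seed = child_seed(seed, i, 3L),
                          noise_cv = noise[["ogtt"]])
      gir <- cl$gir
      samp <- cl$samples
      clamp_rows[[i]] <- merge(
        data.frame(subject_id = p$subject_id, gir),
        data.frame(subject_id = p$subject_id, samp),
        by = c("subject_id", "time_min"), all = TRUE)
      tac_rows[[i]] <- cbind(subject_id = p$subject_id, do.call(rbind, c(
        list(as.data.frame(st$plasma)),
        lapply(st$tissues, as.data.frame))))
      ogtt_rows[[i]] <- og
      dose_rows[[i]] <- data.frame(subject_id = p$subject_id,
                                   dose_mbq = st$injected_dose_mbq,
                                   urine_mbq = st$urine_activity_mbq,
                                   weight_kg = p$weight_kg)
      stage <- "quantify"
      kin_rows[[i]] <- quantify_subject(st, cl, weight = p$weight_kg,
                                        t_star = config$kinetics$t_star,
                                        tolerance = config$kinetics$tolerance)
      stage <- "simulate"
    }
    metab <- simulate_metabolome_cohort(cohort, seed,
                                        panel = config$cohort$panel,
                                        effects = config$cohort$effect_scales[
                                          intersect(names(config$cohort$effect_scales),
                                                    config$cohort$panel$measure)])
    ogtt <- do.call(rbind, ogtt_rows)
    kinetics <- do.call(rbind, kin_rows)

    stage <- "indices"
    idx <- compute_indices(cohort, ogtt,
                           units_mode = config$indices$units_mode,
                           conversion_factor = config$indices$conversion_factor)

    stage <- "compare"
    covs <- .covariate_table(cohort, config$stats$covariates)
    covs_pet <- .covariate_table(cohort, config$stats$covariates,
                                 scan_timing = config$stats$scan_timing_covariate)
    merged <- merge(merge(cohort, kinetics, by = "subject_id"),
                    idx, by = "subject_id")
    merged <- merged[match(cohort$subject_id, merged$subject_id), ]
    outcomes <- c(egp_umol_kg_min = "identity",
                  m_value_umol_kg_min = "auto",
                  rd_umol_kg_min = "auto",
                  gu_muscle_umol_kg_min = "auto",
                  gu_liver_umol_kg_min = "auto",
                  gu_asat_umol_kg_min = "auto",
                  homa_ir = "log", adipo_ir_pmol_mmol = "log",
                  adipo_ir_glycerol_pmol_mmol = "log",
                  matsuda_isi = "log",
                  secretion_first_pmol_mmol = "log",
                  secretion_total_pmol_mmol = "log")
    comparisons <- do.call(rbind, lapply(names(outcomes), function(nm) {
      use_pet <- grepl("^gu_", nm)
      adjusted_group_comparison(merged[[nm]], merged$group,
                                covariates = if (use_pet) covs_pet else covs,
                                transform = unname(outcomes[[nm]]),
                                outcome_name = nm)
    }))
    scan <- metabolite_scan(metab, cohort$group, covs,
                            lambda = config$stats$lambda)

    stage <- "write"
    files <- list(
      cohort.csv = function(f) write_dialect_csv(cohort, f, meta),
      clamp.csv = function(f) write_dialect_csv(do.call(rbind, clamp_rows), f, meta),
      tac.csv = function(f) write_dialect_csv(do.call(rbind, tac_rows), f, meta),
      ogtt.csv = function(f) write_dialect_csv(ogtt, f, meta),
      doses.csv = function(f) write_dialect_csv(do.call(rbind, dose_rows), f, meta),
      metabolome.csv = function(f) write_dialect_csv(metab, f, meta),
      indices.csv = function(f) write_dialect_csv(idx, f, meta),
      kinetics.json = function(f) jsonlite::write_json(
        c(meta, list(subjects = kinetics)), f, dataframe = "rows",
        auto_unbox = TRUE, digits = NA, pretty = TRUE),
      comparisons.tsv = function(f) utils::write.table(
        comparisons, f, sep = "\t", row.names = FALSE, quote = FALSE),
      scan_forest.tsv = function(f) utils::write.table(
        scan, f, sep = "\t", row.names = FALSE, quote = FALSE))
    paths <- character(0)
    for (nm in names(files)) {
      f <- file.path(out_dir, nm)
      files[[nm]](f)
      paths[nm] <- f
    }
    hashes <- tools::md5sum(paths)
    manifest <- list(seed = seed,
                     n_per_group = config$cohort$n_per_group,
                     artifacts = as.list(setNames(unname(hashes), names(paths))),
                     defaults = list(
                       t_star_min = config$kinetics$t_star,
                       steady_state_tolerance_mmol_l = config$kinetics$tolerance,
                       units_mode = config$indices$units_mode,
                       insulin_conversion_factor = config$indices$conversion_factor,
                       densities_kg_l = as.list(.region_density),
                       lumped_constants = as.list(.region_lumped_constant)),
                     effect_scales = as.list(config$cohort$effect_scales),
                     noise_levels = as.list(config$cohort$noise_levels))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed%s: %s", stage,
                 if (!is.na(current_subject))
                   sprintf(" (subject %s)", current_subject) else "",
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
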