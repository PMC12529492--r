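# Fasting and OGTT-derived insulin sensitivity and secretion indices.
# Insulin is carried in pmol/L; conversions to uU/mL are explicit and
# configurable (the 6.00 pmol/L per uU/mL factor is convention, not
# universal across immunoassays).

#' HOMA-IR
#'
#' `HOMA-IR = glucose[mmol/L] * insulin[uU/mL] / 22.5`. Insulin given in
#' pmol/L is converted with `conversion_factor`.
#'
#' @param glucose fasting glucose (mmol/L, > 0).
#' @param insulin fasting insulin.
#' @param insulin_unit `"pmol_l"` (default) or `"uu_ml"`.
#' @param conversion_factor pmol/L per uU/mL.
#' @return dimensionless index; vectorized.
#' @examples
#' homa_ir(5, 4.5, insulin_unit = "uu_ml")  # 1
#' homa_ir(5.6, 54)                          # 5.6 * 9 / 22.5
#' @export
homa_ir <- function(glucose, insulin, insulin_unit = c("pmol_l", "uu_ml"),
                    conversion_factor = 6) {
  insulin_unit <- match.arg(insulin_unit)
  if (any(glucose <= 0, na.rm = TRUE) || any(insulin <= 0, na.rm = TRUE))
    stop_config("glucose and insulin must be positive")
  ins_uu <- if (insulin_unit == "pmol_l")
    insulin_pmol_to_uu(insulin, conversion_factor) else insulin
  glucose * ins_uu / 22.5
}

#' Simplified Matsuda insulin sensitivity index
#'
#' `10000 / sqrt(G0 * I0 * G120 * I120)` from the 0- and 120-min OGTT
#' samples. `units_mode = "si"` uses the inputs as given (glucose mmol/L,
#' insulin pmol/L), matching index magnitudes around 19-29;
#' `units_mode = "mgdl"` first converts to the classic convention
#' (glucose mg/dL, insulin uU/mL).
#'
#' @param ogtt data.frame with `time_min`, `glucose_mmol_l`,
#'   `insulin_pmol_l` containing rows at 0 and 120 min (see
#'   [simulate_ogtt()]).
#' @param units_mode `"si"` or `"mgdl"`.
#' @param conversion_factor insulin pmol/L per uU/mL, used in `"mgdl"` mode.
#' @return dimensionless index with attribute `units_mode`.
#' @examples
#' o <- data.frame(time_min = c(0, 30, 60, 120),
#'                 glucose_mmol_l = c(5, 7, 6.5, 6),
#'                 insulin_pmol_l = c(40, 300, 250, 50))
#' matsuda_isi(o)  # 10000 / sqrt(5 * 40 * 6 * 50)
#' @export
matsuda_isi <- function(ogtt, units_mode = c("si", "mgdl"),
                        conversion_factor = 6) {
  units_mode <- match.arg(units_mode)
  g0 <- .ogtt_at(ogtt, 0, "glucose_mmol_l")
  i0 <- .ogtt_at(ogtt, 0, "insulin_pmol_l")
  g120 <- .ogtt_at(ogtt, 120, "glucose_mmol_l")
  i120 <- .ogtt_at(ogtt, 120, "insulin_pmol_l")
  if (units_mode == "mgdl") {
    g0 <- glucose_mmol_to_mgdl(g0); g120 <- glucose_mmol_to_mgdl(g120)
    i0 <- insulin_pmol_to_uu(i0, conversion_factor)
    i120 <- insulin_pmol_to_uu(i120, conversion_factor)
  }
  structure(10000 / sqrt(g0 * i0 * g120 * i120), units_mode = units_mode)
}

.ogtt_at <- function(ogtt, t, col) {
  i <- which(ogtt$time_min == t)
  if (length(i) != 1L)
    stop_config("OGTT record is missing the %d-min time point", t)
  v <- ogtt[[col]][i]
  if (!is.finite(v) || v <= 0)
    stop_config("OGTT %s at %d min must be positive", col, t)
  v
}

.auc_points <- function(ogtt, col, times) {
  v <- vapply(times, function(t) .ogtt_at(ogtt, t, col), numeric(1))
  pracma::trapz(times, v)
}

#' OGTT insulin secretion indices
#'
#' First-phase secretion is `AUC(insulin, 0-30) / AUC(glucose, 0-30)` using
#' exactly the 0- and 30-min samples; total/second phase uses the 0-, 60-
#' and 120-min samples. AUCs are trapezoidal on the named points only (the
#' 30-min sample is not interpolated into the 0-120 AUC).
#'
#' @param ogtt OGTT record, see [matsuda_isi()].
#' @return ratio in pmol/mmol.
#' @examples
#' o <- data.frame(time_min = c(0, 30, 60, 120),
#'                 glucose_mmol_l = c(5, 8, 7, 6),
#'                 insulin_pmol_l = c(60, 300, 240, 120))
#' secretion_first_phase(o)   # 5400 / 195
#' secretion_total_phase(o)
#' @export
secretion_first_phase <- function(ogtt) {
  .auc_points(ogtt, "insulin_pmol_l", c(0, 30)) /
    .auc_points(ogtt, "glucose_mmol_l", c(0, 30))
}

#' @rdname secretion_first_phase
#' @export
secretion_total_phase <- function(ogtt) {
  .auc_points(ogtt, "insulin_pmol_l", c(0, 60, 120)) /
    .auc_points(ogtt, "glucose_mmol_l", c(0, 60, 120))
}

#' Adipose tissue insulin resistance indices
#'
#' `adipo_ir()` is the product of insulin (pmol/L) and free fatty acids
#' (mmol/L); the same operation applies to clamp-state samples.
#' `adipo_ir_glycerol()` substitutes glycerol (mmol/L) for FFA.
#'
#' @param insulin insulin (pmol/L, > 0).
#' @param ffa free fatty acids (mmol/L, >= 0).
#' @param glycerol glycerol (mmol/L, >= 0).
#' @return index in pmol/L x mmol/L; vectorized.
#' @examples
#' adipo_ir(60, 0.5)            # 30
#' adipo_ir_glycerol(100, 0.05) # 5
#' @export
adipo_ir <- function(insulin, ffa) {
  if (any(insulin <= 0, na.rm = TRUE))
    stop_config("insulin must be positive")
  if (any(ffa < 0, na.rm = TRUE)) stop_config("ffa must be >= 0")
  insulin * ffa
}

#' @rdname adipo_ir
#' @export
adipo_ir_glycerol <- function(insulin, glycerol) {
  if (missing(glycerol) || is.null(glycerol) || all(is.na(glycerol)))
    stop_config("glycerol measurement is missing")
  if (any(insulin <= 0, na.rm = TRUE))
    stop_config("insulin must be positive")
  if (any(glycerol < 0, na.rm = TRUE)) stop_config("glycerol must be >= 0")
  insulin * glycerol
}

#' Per-subject index table
#'
#' Computes all fasting and OGTT indices for a cohort, given the cohort
#' table and a long OGTT table.
#'
#' @param cohort a [generate_cohort()] table.
#' @param ogtt long OGTT table (`subject_id`, `time_min`, `glucose_mmol_l`,
#'   `insulin_pmol_l`).
#' @param units_mode Matsuda convention, see [matsuda_isi()].
#' @param conversion_factor insulin pmol/L per uU/mL.
#' @return data.frame, one row per subject, unit-suffixed columns.
#' @export
compute_indices <- function(cohort, ogtt, units_mode = "si",
                            conversion_factor = 6) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    p <- cohort[i, ]
    o <- ogtt[ogtt$subject_id == p$subject_id, , drop = FALSE]
    data.frame(
      subject_id = p$subject_id,
      homa_ir = homa_ir(p$fasting_glucose_mmol_l, p$fasting_insulin_pmol_l,
                        conversion_factor = conversion_factor),
      adipo_ir_pmol_mmol = adipo_ir(p$fasting_insulin_pmol_l,
                                    p$fasting_ffa_mmol_l),
      adipo_ir_glycerol_pmol_mmol = adipo_ir_glycerol(
        p$fasting_insulin_pmol_l, p$fasting_glycerol_mmol_l),
      matsuda_isi = as.numeric(matsuda_isi(o, units_mode,
                                           conversion_factor)),
      secretion_first_pmol_mmol = secretion_first_phase(o),
      secretion_total_pmol_mmol = secretion_total_phase(o),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "units_mode") <- units_mode
  attr(out, "insulin_conversion_factor") <- conversion_factor
  out
}
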