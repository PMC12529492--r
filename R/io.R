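# File dialects: UTF-8 comma-separated CSV with "." decimal, mandatory
# header row, and "#"-prefixed metadata lines above the header. Every
# numeric column name embeds its unit.

#' Read and write the package CSV dialect
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param meta named list written as `# key: value` metadata lines.
#' @return `read_dialect_csv()` returns the data.frame with a `meta`
#'   attribute of raw metadata lines.
#' @export
write_dialect_csv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dialect_csv
#' @export
read_dialect_csv <- function(path) {
  lines <- readLines(path, n = 100L, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

.dialect_columns <- list(
  cohort = c("subject_id", "group", "sex", "age_years", "bmi_kg_m2",
             "weight_kg", "htg_percent", "fasting_insulin_pmol_l",
             "fasting_glucose_mmol_l", "fasting_ffa_mmol_l"),
  tac = c("subject_id", "region", "time_min", "activity_kbq_ml"),
  clamp = c("subject_id", "time_min", "gir_umol_kg_min"),
  ogtt = c("subject_id", "time_min", "glucose_mmol_l", "insulin_pmol_l"),
  metabolome = c("subject_id")
)

.guess_dialect <- function(path) {
  base <- tolower(basename(path))
  hit <- names(.dialect_columns)[vapply(names(.dialect_columns),
                                        function(d) grepl(d, base),
                                        logical(1))]
  if (length(hit)) hit[1] else NA_character_
}

#' Validate pipeline input files
#'
#' Schema-checks every file of the CSV dialects written by
#' [run_pipeline()]: required unit-suffixed columns, strictly increasing
#' times per subject and region, LL/MEL group labels, and the liver-lipid
#' inclusion rule `0 < htg_percent <= 5.56`. Inputs are never mutated.
#'
#' @param paths character vector of file paths; the dialect is inferred
#'   from the file name (cohort/tac/clamp/ogtt/metabolome).
#' @return data.frame of violations (`file`, `row`, `rule`, `message`);
#'   zero rows when everything is well-formed.
#' @export
validate_inputs <- function(paths) {
  v <- list()
  flag <- function(file, row, rule, message)
    v[[length(v) + 1L]] <<- data.frame(file = file, row = row, rule = rule,
                                       message = message,
                                       stringsAsFactors = FALSE)
  for (path in paths) {
    if (!file.exists(path))
      stop_config("cannot read input file '%s'", path)
    dialect <- .guess_dialect(path)
    if (is.na(dialect)) {
      flag(path, NA_integer_, "unknown_dialect",
           "file name matches no known dialect")
      next
    }
    df <- tryCatch(read_dialect_csv(path), error = function(e) NULL)
    if (is.null(df)) {
      flag(path, NA_integer_, "unreadable", "file could not be parsed as CSV")
      next
    }
    missing <- setdiff(.dialect_columns[[dialect]], names(df))
    if (length(missing)) {
      flag(path, NA_integer_, "missing_columns",
           paste("missing required column(s):",
                 paste(missing, collapse = ", ")))
      next
    }
    if (dialect == "cohort") {
      bad <- which(!(df$group %in% c("LL", "MEL")))
      for (i in bad) flag(path, i, "group_label",
                          sprintf("group '%s' not in {LL, MEL}", df$group[i]))
      bad <- which(!(df$htg_percent > 0 & df$htg_percent <= 5.56))
      for (i in bad)
        flag(path, i, "htg_range",
             sprintf("htg_percent %.2f violates the inclusion rule 0 < HTG <= 5.56",
                     df$htg_percent[i]))
      bad <- which(df$group == "LL" & df$htg_percent > 1.85)
      for (i in bad)
        flag(path, i, "group_interval",
             sprintf("LL subject with htg_percent %.2f > 1.85", df$htg_percent[i]))
      bad <- which(df$group == "MEL" & df$htg_percent <= 1.85)
      for (i in bad)
        flag(path, i, "group_interval",
             sprintf("MEL subject with htg_percent %.2f <= 1.85", df$htg_percent[i]))
    }
    if (dialect %in% c("tac", "clamp", "ogtt")) {
      key <- if (dialect == "tac") interaction(df$subject_id, df$region)
             else df$subject_id
      for (k in unique(key)) {
        idx <- which(key == k)
        tt <- df$time_min[idx]
        bad <- idx[which(diff(tt) <= 0) + 1L]
        for (i in bad)
          flag(path, i, "non_monotone_time",
               sprintf("time_min %.3g does not increase within '%s'",
                       df$time_min[i], as.character(k)))
      }
    }
    if (dialect == "metabolome") {
      num <- names(df)[vapply(df, is.numeric, logical(1))]
      for (nm in num) {
        bad <- which(!(df[[nm]] > 0))
        for (i in bad)
          flag(path, i, "non_positive_concentration",
               sprintf("%s = %.3g is not positive", nm, df[[nm]][i]))
      }
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(file = character(), row = integer(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
}
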