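# Study-level data model: aggregated biomonitoring records, paired
# blood/urine records, harmonized panel rows, and their CSV readers/writers.

#' @name study_schema
#' @title Column schemas for study-level CSV files
#' @description
#' Three tabular record types flow through the pipeline:
#'
#' * **study records** — one published (or aligned-study) aggregated report
#'   per row: a study label, country/region, sampling-year window, sample
#'   matrix, smoking stratum, analyte, participant count, and whatever
#'   summary statistics the source printed (mean, median, quartiles, range,
#'   SD), together with its unit and basic population descriptors.
#'   Empty cells mean "not reported"; `0` is always a real measurement.
#' * **dual-matrix records** — one individual's simultaneously sampled blood
#'   hemoglobin-adduct level (pmol/g Hb) and urinary mercapturic-acid
#'   metabolite level (ug/L), used to fit the blood-to-urine conversion
#'   factor.
#' * **harmonized records** — the output of [harmonize()]: one study-year
#'   stratum mean in ug/L with a provenance code describing which
#'   estimation/conversion steps produced it.
#'
#' Matrices: `blood`, `spot_urine`, `morning_urine`, `urine_24h`,
#' `urine_12h`. Smoking strata: `nonsmoker`, `smoker`, `mixed`. Analytes:
#' `AAMA`, `GAMA` (urinary metabolites, ug/L), `AAVal`, `GAVal`
#' (hemoglobin adducts, pmol/g Hb). Units: `ug_per_L`, `pmol_per_g_Hb`,
#' `pmol_per_L`, `ug_per_g_creatinine`, `nmol_per_day`.
NULL

.matrices  <- c("blood", "spot_urine", "morning_urine", "urine_24h", "urine_12h")
.smoking   <- c("nonsmoker", "smoker", "mixed")
.analytes  <- c("AAMA", "GAMA", "AAVal", "GAVal")
.units     <- c("ug_per_L", "pmol_per_g_Hb", "pmol_per_L",
                "ug_per_g_creatinine", "nmol_per_day")
.regions   <- c("north", "central_west", "south")
.sources   <- c("published", "aligned")
.provenance <- c("measured_mean", "mean_from_median_range",
                 "mean_from_quartiles", "trans_matrix",
                 "trans_matrix_plus_median")

study_char_cols <- c("study_id", "country", "region", "matrix", "smoking",
                     "analyte", "unit", "source", "exclusion_reason")
study_num_cols  <- c("year_start", "year_end", "n", "mean", "median", "q1",
                     "q3", "min", "max", "sd", "lod", "mean_age", "pct_male")
study_lgl_cols  <- c("lod_unknown", "excluded_flag")
study_cols <- c("study_id", "country", "region", "year_start", "year_end",
                "matrix", "smoking", "analyte", "n", "mean", "median", "q1",
                "q3", "min", "max", "sd", "lod", "lod_unknown", "unit",
                "mean_age", "pct_male", "source", "excluded_flag",
                "exclusion_reason")

panel_cols <- c("study_id", "country", "region", "year", "analyte", "smoking",
                "mean_ugL", "sd_ugL", "n", "mean_age", "pct_male",
                "provenance", "multi_year", "low_confidence")
panel_num_cols <- c("year", "mean_ugL", "sd_ugL", "n", "mean_age", "pct_male")
panel_lgl_cols <- c("multi_year", "low_confidence")

dual_cols <- c("subject_id", "blood_value", "urine_value", "analyte_pair",
               "smoking")

.coerce_numeric <- function(df, cols, path) {
  bad <- character(0)
  for (col in cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    fail <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(fail)) {
      bad <- c(bad, sprintf("row %d, column '%s': '%s'", fail, col, raw[fail]))
    }
    val[raw == "" | is.na(raw)] <- NA_real_
    df[[col]] <- val
  }
  if (length(bad)) {
    abort_acry(sprintf("non-numeric values in '%s':\n  %s", path,
                       paste(bad, collapse = "\n  ")), "acry_parse_error")
  }
  df
}

.coerce_logical <- function(df, cols) {
  for (col in cols) {
    raw <- df[[col]]
    val <- rep(NA, length(raw))
    val[raw %in% c("TRUE", "true", "T", "1")] <- TRUE
    val[raw %in% c("FALSE", "false", "F", "0")] <- FALSE
    df[[col]] <- val
  }
  df
}

.check_schema <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_acry(sprintf("'%s' is missing mandatory column(s): %s", path,
                       paste(missing, collapse = ", ")), "acry_schema_error")
  }
}

.read_raw_csv <- function(path) {
  if (!file.exists(path)) {
    abort_acry(sprintf("file not found: '%s'", path), "acry_schema_error")
  }
  utils::read.csv(path, colClasses = "character", na.strings = character(0),
                  check.names = FALSE, fileEncoding = "UTF-8")
}

#' Read aggregated study records from CSV
#'
#' Parses a CSV file in the study-record schema (see [study_schema]) into a
#' validated data frame. Empty cells become `NA` ("not reported"), never
#' zero. Rows that violate the record invariants (participant count below 1,
#' unordered year window or order statistics, neither a mean nor a median)
#' are rejected with their row numbers.
#'
#' @param path Path to a CSV file with the study-record header.
#' @return A `data.frame` with class `acry_studies`, one row per record.
#' @examples
#' tab2 <- read_studies(acry_fixture("table2_aligned.csv"))
#' nrow(tab2)
#' @seealso [harmonize()], [acry_fixture()]
#' @export
read_studies <- function(path) {
  df <- .read_raw_csv(path)
  .check_schema(df, study_cols, path)
  df <- df[study_cols]
  if (nrow(df) == 0) {
    df <- .coerce_numeric(df, study_num_cols, path)
    df <- .coerce_logical(df, study_lgl_cols)
    class(df) <- c("acry_studies", "data.frame")
    return(df)
  }
  df <- .coerce_numeric(df, study_num_cols, path)
  df <- .coerce_logical(df, study_lgl_cols)
  for (col in study_char_cols) df[[col]][df[[col]] == ""] <- NA_character_
  df$lod_unknown[is.na(df$lod_unknown)] <- FALSE
  df$excluded_flag[is.na(df$excluded_flag)] <- FALSE
  validate_studies(df, path)
  rownames(df) <- NULL
  class(df) <- c("acry_studies", "data.frame")
  df
}

#' Validate study-record invariants
#'
#' @param df Data frame in the study-record schema.
#' @param path Label used in error messages.
#' @return `df`, invisibly, if valid; otherwise an error listing offending
#'   row numbers.
#' @keywords internal
validate_studies <- function(df, path = "<studies>") {
  probs <- character(0)
  add <- function(rows, what) {
    if (length(rows)) {
      probs <<- c(probs, sprintf("row %d: %s", rows, what))
    }
  }
  add(which(!is.na(df$n) & df$n < 1), "n must be >= 1")
  add(which(is.na(df$n)), "n is mandatory")
  add(which(!is.na(df$year_start) & !is.na(df$year_end) &
              df$year_start > df$year_end), "year_start > year_end")
  add(which(is.na(df$mean) & is.na(df$median)),
      "neither mean nor median reported")
  add(which(!is.na(df$pct_male) & (df$pct_male < 0 | df$pct_male > 100)),
      "pct_male outside [0, 100]")
  add(which(!df$matrix %in% .matrices), "unknown matrix")
  add(which(!df$smoking %in% .smoking), "unknown smoking stratum")
  add(which(!df$analyte %in% .analytes), "unknown analyte")
  add(which(!df$unit %in% .units), "unknown unit")
  # ordering of reported order statistics, pairwise where both present
  ord_pairs <- list(c("min", "q1"), c("q1", "median"), c("median", "q3"),
                    c("q3", "max"), c("min", "median"), c("median", "max"))
  for (p in ord_pairs) {
    lo <- df[[p[1]]]; hi <- df[[p[2]]]
    add(which(!is.na(lo) & !is.na(hi) & lo > hi),
        sprintf("%s > %s", p[1], p[2]))
  }
  if (length(probs)) {
    abort_acry(sprintf("invalid study records in '%s':\n  %s", path,
                       paste(probs, collapse = "\n  ")), "acry_data_error")
  }
  invisible(df)
}

#' Write / read a harmonized panel as CSV
#'
#' The harmonized panel is the analysis table entering the trend models: one
#' study-year stratum mean in ug/L per row, with provenance. Serialization is
#' lossless: absent values are written as empty cells and read back as `NA`,
#' so `read_panel(write_panel(p))` reproduces `p` field for field.
#'
#' @param panel Data frame in the harmonized-panel schema (see
#'   [study_schema]); may have zero rows.
#' @param path Output (input) CSV path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns
#'   a `data.frame` with class `acry_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(is.data.frame(panel))
  .check_schema(panel, panel_cols, "<panel>")
  out <- panel[panel_cols]
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e)
                    abort_acry(sprintf("cannot write '%s': %s", path,
                                       conditionMessage(e)), "acry_io_error"))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- .read_raw_csv(path)
  .check_schema(df, panel_cols, path)
  df <- df[panel_cols]
  df <- .coerce_numeric(df, panel_num_cols, path)
  df <- .coerce_logical(df, panel_lgl_cols)
  for (col in setdiff(panel_cols, c(panel_num_cols, panel_lgl_cols))) {
    df[[col]][df[[col]] == ""] <- NA_character_
  }
  rownames(df) <- NULL
  class(df) <- c("acry_panel", "data.frame")
  df
}

#' Read individual dual-matrix (blood + urine) records from CSV
#'
#' @param path CSV with columns `subject_id`, `blood_value` (pmol/g Hb),
#'   `urine_value` (ug/L), `analyte_pair` (`AAVal_AAMA` or `GAVal_GAMA`) and
#'   `smoking` (`nonsmoker`/`smoker`).
#' @return A validated `data.frame`.
#' @export
read_dual_matrix <- function(path) {
  df <- .read_raw_csv(path)
  .check_schema(df, dual_cols, path)
  df <- .coerce_numeric(df, c("blood_value", "urine_value"), path)
  bad <- which(df$blood_value < 0 | df$urine_value < 0)
  if (length(bad)) {
    abort_acry(sprintf("negative biomarker values in '%s' (rows %s)", path,
                       paste(bad, collapse = ", ")), "acry_data_error")
  }
  df
}

#' Path to a packaged fixture file
#'
#' The package ships hand-transcribed CSV versions of the two published
#' study-overview tables: `table1_published.csv` (literature studies
#' 2001-2017, one row per study x matrix x smoking stratum x analyte) and
#' `table2_aligned.csv` (the aligned-survey yearly means 2014-2020).
#' Combined cells in the printed tables (a non-smoker and a smoker value in
#' one cell) are transcribed as two stratum rows; value ranges quoted only
#' in the running text for the dual-matrix validation studies are included
#' on those rows. A range printed as "LOD-x" with no numeric detection limit
#' is stored with `min` absent and `lod_unknown = TRUE`.
#'
#' @param file Fixture file name; with no argument, lists available fixtures.
#' @return A file path (or a character vector of file names).
#' @export
acry_fixture <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "acrytrend")))
  }
  path <- system.file("extdata", file, package = "acrytrend")
  if (path == "") {
    abort_acry(sprintf("no packaged fixture '%s'", file), "acry_schema_error")
  }
  path
}
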