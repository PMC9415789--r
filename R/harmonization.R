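# Harmonization: order-statistic mean/SD estimators, blood-to-urine
# trans-matrix conversion, and the inclusion/year-assignment rule engine.

#' Estimate an arithmetic mean from a median and range or quartiles
#'
#' Published biomonitoring studies often report only a median with the
#' observed range (or the quartiles). For right-skewed, non-negative
#' concentration data the arithmetic mean can be approximated from these
#' order statistics:
#'
#' * from median `m` and range `[a, b]`:  (a + 2 m + b) / 4
#' * from quartiles `q1`, `m`, `q3`:      (q1 + m + q3) / 3
#'
#' Both estimators are affine-equivariant: scaling or shifting all inputs
#' scales/shifts the estimate identically.
#'
#' @param m Median.
#' @param a,b Sample minimum and maximum, same unit as `m`.
#' @param q1,q3 First and third quartile.
#' @return The estimated mean.
#' @examples
#' estimate_mean_from_range(m = 30, a = 15, b = 71)     # 36.5
#' estimate_mean_from_quartiles(q1 = 10, m = 20, q3 = 45) # 25
#' @export
estimate_mean_from_range <- function(m, a, b) {
  stopifnot(is.finite(m), is.finite(a), is.finite(b))
  if (any(a > m | m > b)) {
    abort_acry("order statistics must satisfy a <= m <= b", "acry_domain_error")
  }
  (a + 2 * m + b) / 4
}

#' @rdname estimate_mean_from_range
#' @export
estimate_mean_from_quartiles <- function(q1, m, q3) {
  stopifnot(is.finite(q1), is.finite(m), is.finite(q3))
  if (any(q1 > m | m > q3)) {
    abort_acry("quartiles must satisfy q1 <= m <= q3", "acry_domain_error")
  }
  (q1 + m + q3) / 3
}

#' Estimate a standard deviation from a median, range, and sample size
#'
#' Small-sample SD estimation from order statistics, with the usual
#' size-dependent switch:
#' for n <= 15, `sqrt(((a - 2 m + b)^2 / 4 + (b - a)^2) / 12)`;
#' for 15 < n <= 70, `(b - a) / 4`; for n > 70, `(b - a) / 6`.
#'
#' @inheritParams estimate_mean_from_range
#' @param n Sample size behind the reported statistics.
#' @return The estimated SD (always >= 0).
#' @examples
#' estimate_sd(m = 5, a = 0, b = 12, n = 30)   # 3
#' estimate_sd(m = 5, a = 0, b = 12, n = 100)  # 2
#' @export
estimate_sd <- function(m, a, b, n) {
  stopifnot(is.finite(m), is.finite(a), is.finite(b), n >= 1)
  if (any(a > m | m > b)) {
    abort_acry("order statistics must satisfy a <= m <= b", "acry_domain_error")
  }
  if (n <= 15) {
    sqrt(((a - 2 * m + b)^2 / 4 + (b - a)^2) / 12)
  } else if (n <= 70) {
    (b - a) / 4
  } else {
    (b - a) / 6
  }
}

#' Fit the blood-to-urine conversion factor (zero-intercept least squares)
#'
#' Hemoglobin-adduct levels (pmol/g Hb) and urinary mercapturic-acid levels
#' (ug/L) sampled simultaneously in individuals with stable exposure are
#' proportional; under no exposure both vanish, so the fit is forced through
#' the origin. The slope is the zero-intercept least-squares estimate
#' `sum(u * b) / sum(b^2)`, with its standard error and no-intercept R^2
#' from the same model.
#'
#' @param records Data frame of dual-matrix records (see
#'   [read_dual_matrix()] for the schema).
#' @param pair `"AAVal_AAMA"` or `"GAVal_GAMA"`.
#' @return An object of class `conversion_factor`: list with `analyte_pair`,
#'   `slope` (ug/L urine per pmol/g Hb blood), `se_slope`, `n_fit`,
#'   `r_squared`, `fit_population`.
#' @examples
#' rec <- gen_dual_matrix(dual_matrix_scenario(seed = 7))
#' fit_conversion_factor(rec, "AAVal_AAMA")
#' @export
fit_conversion_factor <- function(records, pair = c("AAVal_AAMA", "GAVal_GAMA")) {
  pair <- match.arg(pair)
  rec <- records[records$analyte_pair == pair, , drop = FALSE]
  b <- rec$blood_value
  u <- rec$urine_value
  if (length(b) < 2) {
    abort_acry("need at least 2 dual-matrix records to fit a factor",
               "acry_data_error")
  }
  if (all(b == 0)) {
    abort_acry("all blood values are zero: zero-intercept fit is singular",
               "acry_model_error")
  }
  sxx <- sum(b^2)
  slope <- sum(u * b) / sxx
  rss <- sum((u - slope * b)^2)
  df <- length(b) - 1L
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  r2 <- if (sum(u^2) > 0) max(0, min(1, 1 - rss / sum(u^2))) else 1
  pop <- if (any(rec$smoking == "smoker")) "smokers_included" else "nonsmokers_only"
  structure(list(analyte_pair = pair, slope = slope, se_slope = se,
                 n_fit = length(b), r_squared = r2, fit_population = pop),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("Trans-matrix conversion factor (%s)\n", x$analyte_pair))
  cat(sprintf("  slope: %.4f ug/L per pmol/g Hb (SE %.4f), n = %d, R^2 = %.3f\n",
              x$slope, x$se_slope, x$n_fit, x$r_squared))
  cat(sprintf("  fitted on: %s\n", x$fit_population))
  invisible(x)
}

#' Fixed published conversion factors
#'
#' The two-decimal factors in routine use for the acrylamide pair
#' (AAVal -> AAMA: 1.64) and the glycidamide pair (GAVal -> GAMA: 0.35),
#' packaged as `conversion_factor` objects without uncertainty (the paired
#' individual-level data behind them are unpublished). Use these to
#' reproduce the published arithmetic exactly; use
#' [fit_conversion_factor()] on your own dual-matrix data otherwise.
#'
#' @return Named list with elements `AAVal_AAMA` and `GAVal_GAMA`.
#' @export
fixed_conversion_factors <- function() {
  mk <- function(pair, slope) {
    structure(list(analyte_pair = pair, slope = slope, se_slope = NA_real_,
                   n_fit = 24L, r_squared = NA_real_,
                   fit_population = "smokers_included"),
              class = "conversion_factor")
  }
  list(AAVal_AAMA = mk("AAVal_AAMA", 1.64), GAVal_GAMA = mk("GAVal_GAMA", 0.35))
}

#' Convert a blood adduct mean to a urinary metabolite equivalent
#'
#' Applies the proportionality factor: `urine = slope * blood`. Linear by
#' construction (`f(0) = 0`, `f(x + y) = f(x) + f(y)`).
#'
#' @param value Blood adduct mean, pmol/g Hb; must be >= 0.
#' @param factor A `conversion_factor` (or a bare positive slope).
#' @return The urinary-equivalent mean in ug/L.
#' @examples
#' blood_to_urine(79.1, fixed_conversion_factors()$AAVal_AAMA)  # 129.724
#' @export
blood_to_urine <- function(value, factor) {
  slope <- if (inherits(factor, "conversion_factor")) factor$slope else factor
  stopifnot(is.numeric(slope), slope > 0)
  if (any(value < 0)) {
    abort_acry("blood adduct levels cannot be negative", "acry_domain_error")
  }
  slope * value
}

#' Signed relative error in percent
#'
#' @param estimate Estimated value.
#' @param reference Reference value; must be > 0.
#' @return `100 * (estimate - reference) / reference`.
#' @examples
#' relative_error(59.04, 64.5)  # -8.47
#' @export
relative_error <- function(estimate, reference) {
  if (any(reference <= 0)) {
    abort_acry("reference must be positive", "acry_domain_error")
  }
  100 * (estimate - reference) / reference
}

#' Harmonization rule set
#'
#' Captures the inclusion/exclusion and year-assignment policy applied by
#' [harmonize()]:
#' the minimum number of participants behind a usable mean (`min_n`, default
#' 6), the urine matrices comparable on the ug/L scale (spot and morning
#' urine; 24 h and 12 h collections are systematically more dilute and are
#' dropped, as are creatinine- and per-day-based units), the requirement
#' that records be stratified by smoking status (mixed populations are
#' dropped), the policy for multi-year sampling windows (assign the
#' midpoint year, or exclude), and whether glycidamide blood records may be
#' converted to urinary equivalents (off by default: the glycidamide
#' conversion factor varies regionally with CYP2E1 metabolism, so a
#' region-matched factor must be supplied deliberately).
#'
#' @param min_n Minimum participants per record.
#' @param allowed_matrices_for_trend Urine matrices usable directly.
#' @param require_smoking_stratified Drop `smoking == "mixed"` records?
#' @param multi_year_policy `"midpoint"` or `"exclude"`.
#' @param apply_gama_trans_matrix Convert GAVal blood records to GAMA?
#' @return A list of class `harmonization_rules`.
#' @export
harmonization_rules <- function(min_n = 6,
                                allowed_matrices_for_trend = c("spot_urine",
                                                               "morning_urine"),
                                require_smoking_stratified = TRUE,
                                multi_year_policy = c("midpoint", "exclude"),
                                apply_gama_trans_matrix = FALSE) {
  multi_year_policy <- match.arg(multi_year_policy)
  stopifnot(min_n >= 1,
            all(allowed_matrices_for_trend %in% .matrices))
  structure(list(min_n = min_n,
                 allowed_matrices_for_trend = allowed_matrices_for_trend,
                 require_smoking_stratified = require_smoking_stratified,
                 multi_year_policy = multi_year_policy,
                 apply_gama_trans_matrix = apply_gama_trans_matrix),
            class = "harmonization_rules")
}

.empty_panel <- function() {
  df <- data.frame(study_id = character(0), country = character(0),
                   region = character(0), year = numeric(0),
                   analyte = character(0), smoking = character(0),
                   mean_ugL = numeric(0), sd_ugL = numeric(0), n = numeric(0),
                   mean_age = numeric(0), pct_male = numeric(0),
                   provenance = character(0), multi_year = logical(0),
                   low_confidence = logical(0), stringsAsFactors = FALSE)
  class(df) <- c("acry_panel", "data.frame")
  df
}

#' Harmonize study records into a yearly-mean panel
#'
#' Applies, in order:
#' \enumerate{
#'   \item drop records not stratified by smoking status (`mixed`);
#'   \item drop records with fewer than `min_n` participants;
#'   \item drop records with no assignable sampling year (and, under the
#'     `exclude` multi-year policy, any multi-year window);
#'   \item drop matrix/unit combinations not usable for the ug/L trend:
#'     24 h and 12 h urine, creatinine- or per-day-based urine units,
#'     blood not reported in pmol/g Hb, and glycidamide blood records
#'     unless `apply_gama_trans_matrix` is on;
#'   \item assign `year` as the midpoint of the sampling window, flagging
#'     multi-year windows;
#'   \item where no mean is reported, estimate it from quartiles
#'     ([estimate_mean_from_quartiles()]) or from median and range
#'     ([estimate_mean_from_range()]); a range whose lower end is an
#'     unquantified detection limit is closed at 0 and the record flagged
#'     `low_confidence`; records with neither statistic are dropped;
#'   \item convert blood adduct means to urinary equivalents in ug/L via
#'     the supplied conversion factors ([blood_to_urine()]);
#'   \item drop records carrying an exclusion flag from the source table
#'     (e.g. overlap with an aligned dataset).
#' }
#' Every dropped record is logged with its rule number and reason. The
#' result is permutation-invariant in the input order and idempotent:
#' re-harmonizing a harmonized panel (via [as_study_records()]) changes no
#' mean, year, or count.
#'
#' @param studies Data frame of study records ([read_studies()]).
#' @param rules A [harmonization_rules()] object.
#' @param factors Named list of `conversion_factor` objects keyed by pair
#'   (default [fixed_conversion_factors()]).
#' @return A list of class `harmonization_result`: `panel` (class
#'   `acry_panel`) and `exclusions` (data frame `study_id`, `analyte`,
#'   `smoking`, `rule`, `reason`).
#' @examples
#' studies <- read_studies(acry_fixture("table2_aligned.csv"))
#' h <- harmonize(studies)
#' table(h$panel$analyte, h$panel$smoking)
#' @export
harmonize <- function(studies, rules = harmonization_rules(),
                      factors = fixed_conversion_factors()) {
  stopifnot(is.data.frame(studies), inherits(rules, "harmonization_rules"))
  df <- as.data.frame(studies)
  excl <- data.frame(study_id = character(0), analyte = character(0),
                     smoking = character(0), rule = integer(0),
                     reason = character(0), stringsAsFactors = FALSE)
  drop_rows <- function(idx, rule, reason) {
    if (!length(idx)) return(invisible())
    excl <<- rbind(excl, data.frame(study_id = df$study_id[idx],
                                    analyte = df$analyte[idx],
                                    smoking = df$smoking[idx],
                                    rule = rule, reason = reason,
                                    stringsAsFactors = FALSE))
    df <<- df[-idx, , drop = FALSE]
    invisible()
  }

  # (1) smoking stratification
  if (rules$require_smoking_stratified) {
    drop_rows(which(df$smoking == "mixed"), 1L,
              "population not stratified for smoking")
  }
  # (2) minimum study size
  drop_rows(which(df$n < rules$min_n), 2L,
            sprintf("fewer than %d participants", rules$min_n))
  # (3) assignable sampling year
  drop_rows(which(is.na(df$year_start) | is.na(df$year_end)), 3L,
            "no sampling year reported")
  if (rules$multi_year_policy == "exclude") {
    drop_rows(which(df$year_end > df$year_start), 3L,
              "multi-year sampling window excluded by policy")
  }
  # (4) usable matrix/unit combinations
  urine_matrices <- setdiff(.matrices, "blood")
  bad_urine <- df$matrix %in% urine_matrices &
    (!(df$matrix %in% rules$allowed_matrices_for_trend) |
       df$unit != "ug_per_L")
  bad_blood <- df$matrix == "blood" &
    (df$unit != "pmol_per_g_Hb" |
       (df$analyte == "GAVal" & !rules$apply_gama_trans_matrix))
  drop_rows(which(bad_urine | bad_blood), 4L,
            "matrix/unit not usable for ug/L trend")

  if (nrow(df) == 0) {
    return(structure(list(panel = .empty_panel(), exclusions = excl),
                     class = "harmonization_result"))
  }

  # (5) year assignment
  year <- (df$year_start + df$year_end) / 2
  multi_year <- df$year_end > df$year_start

  # (6) mean estimation from order statistics
  mean_ugL <- df$mean
  sd_est <- df$sd
  provenance <- ifelse(is.na(df$mean), NA_character_, "measured_mean")
  low_conf <- rep(FALSE, nrow(df))
  estimable <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!is.na(mean_ugL[i])) next
    m <- df$median[i]
    if (!is.na(df$q1[i]) && !is.na(df$q3[i])) {
      mean_ugL[i] <- estimate_mean_from_quartiles(df$q1[i], m, df$q3[i])
      provenance[i] <- "mean_from_quartiles"
      if (!is.na(df$min[i]) && !is.na(df$max[i]) && is.na(sd_est[i])) {
        sd_est[i] <- estimate_sd(m, df$min[i], df$max[i], df$n[i])
      }
    } else {
      a <- df$min[i]
      if (is.na(a) && isTRUE(df$lod_unknown[i])) {
        a <- 0          # range printed as "LOD-max": close it at zero, flag
        low_conf[i] <- TRUE
      }
      if (!is.na(a) && !is.na(df$max[i])) {
        mean_ugL[i] <- estimate_mean_from_range(m, a, df$max[i])
        provenance[i] <- "mean_from_median_range"
        if (is.na(sd_est[i])) sd_est[i] <- estimate_sd(m, a, df$max[i], df$n[i])
      } else {
        estimable[i] <- FALSE
      }
    }
  }
  if (any(!estimable)) {
    idx <- which(!estimable)
    excl <- rbind(excl, data.frame(study_id = df$study_id[idx],
                                   analyte = df$analyte[idx],
                                   smoking = df$smoking[idx], rule = 6L,
                                   reason = "no mean and no usable order statistics",
                                   stringsAsFactors = FALSE))
    keep <- estimable
    df <- df[keep, , drop = FALSE]
    year <- year[keep]; multi_year <- multi_year[keep]
    mean_ugL <- mean_ugL[keep]; sd_est <- sd_est[keep]
    provenance <- provenance[keep]; low_conf <- low_conf[keep]
  }

  # (7) trans-matrix conversion of blood records
  analyte <- df$analyte
  is_blood <- df$matrix == "blood"
  for (i in which(is_blood)) {
    pair <- if (analyte[i] == "AAVal") "AAVal_AAMA" else "GAVal_GAMA"
    fac <- factors[[pair]]
    if (is.null(fac)) {
      abort_acry(sprintf("no conversion factor supplied for pair '%s'", pair),
                 "acry_config_error")
    }
    mean_ugL[i] <- blood_to_urine(mean_ugL[i], fac)
    if (!is.na(sd_est[i])) sd_est[i] <- blood_to_urine(sd_est[i], fac)
    provenance[i] <- if (provenance[i] == "measured_mean") "trans_matrix"
                     else "trans_matrix_plus_median"
    analyte[i] <- if (analyte[i] == "AAVal") "AAMA" else "GAMA"
  }

  # (8) source-table exclusion flags
  flagged <- which(df$excluded_flag %in% TRUE)
  if (length(flagged)) {
    reason <- ifelse(is.na(df$exclusion_reason[flagged]),
                     "flagged excluded in source table",
                     df$exclusion_reason[flagged])
    excl <- rbind(excl, data.frame(study_id = df$study_id[flagged],
                                   analyte = df$analyte[flagged],
                                   smoking = df$smoking[flagged], rule = 8L,
                                   reason = reason, stringsAsFactors = FALSE))
    keep <- setdiff(seq_len(nrow(df)), flagged)
    df <- df[keep, , drop = FALSE]
    year <- year[keep]; multi_year <- multi_year[keep]
    mean_ugL <- mean_ugL[keep]; sd_est <- sd_est[keep]
    provenance <- provenance[keep]; low_conf <- low_conf[keep]
    analyte <- analyte[keep]
  }

  panel <- data.frame(study_id = df$study_id, country = df$country,
                      region = df$region, year = year, analyte = analyte,
                      smoking = df$smoking, mean_ugL = mean_ugL,
                      sd_ugL = sd_est, n = df$n, mean_age = df$mean_age,
                      pct_male = df$pct_male, provenance = provenance,
                      multi_year = multi_year, low_confidence = low_conf,
                      stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  class(panel) <- c("acry_panel", "data.frame")
  structure(list(panel = panel, exclusions = excl),
            class = "harmonization_result")
}

#' @export
print.harmonization_result <- function(x, ...) {
  cat(sprintf("Harmonized panel: %d record(s); %d excluded\n",
              nrow(x$panel), nrow(x$exclusions)))
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$rule)
    for (r in names(tab)) cat(sprintf("  rule %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Recast a harmonized panel as study records
#'
#' Maps harmonized rows back onto the study-record schema (spot urine,
#' ug/L, measured mean), so a panel can be fed through [harmonize()] again;
#' doing so changes no mean, year, or count (idempotence).
#'
#' @param panel An `acry_panel` data frame.
#' @return A data frame in the study-record schema.
#' @export
as_study_records <- function(panel) {
  stopifnot(is.data.frame(panel))
  df <- data.frame(study_id = panel$study_id, country = panel$country,
                   region = panel$region, year_start = panel$year,
                   year_end = panel$year, matrix = "spot_urine",
                   smoking = panel$smoking, analyte = panel$analyte,
                   n = panel$n, mean = panel$mean_ugL, median = NA_real_,
                   q1 = NA_real_, q3 = NA_real_, min = NA_real_,
                   max = NA_real_, sd = panel$sd_ugL, lod = NA_real_,
                   lod_unknown = FALSE, unit = "ug_per_L",
                   mean_age = panel$mean_age, pct_male = panel$pct_male,
                   source = "published", excluded_flag = FALSE,
                   exclusion_reason = NA_character_, stringsAsFactors = FALSE)
  class(df) <- c("acry_studies", "data.frame")
  df
}
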