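# Synthetic-data generators emulating every input the pipeline consumes:
# paired blood/urine individual records, individual studies summarized as
# order statistics, and aggregated yearly panels with known injected trends.

#' Scenario for synthetic dual-matrix (blood + urine) records
#'
#' Describes the paired-sample population used to fit the trans-matrix
#' conversion factor: a predominantly smoking group of 24 subjects (13
#' smokers), blood adduct levels drawn log-normally per stratum with
#' smokers centered markedly higher, and urinary levels proportional to
#' blood with multiplicative log-normal noise. The default true slopes are
#' the published two-decimal factors (1.64 ug/L AAMA per pmol/g Hb AAVal;
#' 0.35 for the glycidamide pair). Default blood locations put non-smokers
#' near 27 pmol/g Hb and smokers near 80 (acrylamide pair), with about 40%
#' log-scale spread.
#'
#' @param n_subjects Number of paired records per analyte pair.
#' @param smoker_fraction Fraction of smokers (default 13/24).
#' @param true_slope_aa,true_slope_ga True proportionality slopes.
#' @param blood_meanlog,blood_sdlog Named vectors (`nonsmoker`, `smoker`)
#'   of log-normal parameters for the acrylamide-pair blood levels; the
#'   glycidamide pair uses the same spread with locations shifted down.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return List of class `dual_matrix_scenario`.
#' @export
dual_matrix_scenario <- function(n_subjects = 24, smoker_fraction = 13 / 24,
                                 true_slope_aa = 1.64, true_slope_ga = 0.35,
                                 blood_meanlog = c(nonsmoker = log(27),
                                                   smoker = log(80)),
                                 blood_sdlog = c(nonsmoker = 0.4,
                                                 smoker = 0.4),
                                 noise_cv = 0.2, seed = 1) {
  if (smoker_fraction < 0 || smoker_fraction > 1) {
    abort_acry("smoker_fraction must lie in [0, 1]", "acry_config_error")
  }
  if (noise_cv < 0) abort_acry("noise_cv must be >= 0", "acry_config_error")
  if (true_slope_aa <= 0 || true_slope_ga <= 0) {
    abort_acry("true slopes must be positive", "acry_config_error")
  }
  if (n_subjects < 2) {
    abort_acry("need at least 2 subjects", "acry_config_error")
  }
  structure(list(n_subjects = n_subjects, smoker_fraction = smoker_fraction,
                 true_slope_aa = true_slope_aa, true_slope_ga = true_slope_ga,
                 blood_meanlog = blood_meanlog, blood_sdlog = blood_sdlog,
                 noise_cv = noise_cv, seed = seed),
            class = "dual_matrix_scenario")
}

#' Generate synthetic paired blood/urine records
#'
#' Draws blood adduct levels log-normally per smoking stratum (smokers
#' higher by construction) and sets each urinary level to
#' `true_slope * blood * exp(eps)` with `eps` normal on the log scale,
#' its SD chosen so the multiplicative noise has the scenario's CV
#' (`sdlog = sqrt(log(1 + cv^2))`). Both analyte pairs are emitted for the
#' same subjects; the glycidamide-pair blood locations sit lower
#' (log(20)/log(60)) reflecting the lower adduct burden. Identical seeds
#' give identical output.
#'
#' @param scn A [dual_matrix_scenario()].
#' @return Data frame of dual-matrix records (schema of
#'   [read_dual_matrix()]), with the true slopes attached as attribute
#'   `truth`.
#' @examples
#' rec <- gen_dual_matrix(dual_matrix_scenario(noise_cv = 0, seed = 2))
#' aa <- rec[rec$analyte_pair == "AAVal_AAMA", ]
#' all.equal(aa$urine_value / aa$blood_value, rep(1.64, nrow(aa)))
#' @export
gen_dual_matrix <- function(scn) {
  stopifnot(inherits(scn, "dual_matrix_scenario"))
  with_seed(scn$seed, {
    n <- scn$n_subjects
    n_smoke <- round(n * scn$smoker_fraction)
    smoking <- c(rep("smoker", n_smoke), rep("nonsmoker", n - n_smoke))
    sdlog_noise <- sqrt(log(1 + scn$noise_cv^2))
    draw_pair <- function(pair, slope, shift) {
      ml <- scn$blood_meanlog[smoking] + shift
      sl <- scn$blood_sdlog[smoking]
      blood <- stats::rlnorm(n, meanlog = ml, sdlog = sl)
      eps <- if (sdlog_noise > 0) stats::rnorm(n, 0, sdlog_noise) else rep(0, n)
      urine <- slope * blood * exp(eps)
      data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                 blood_value = blood, urine_value = urine,
                 analyte_pair = pair, smoking = smoking,
                 stringsAsFactors = FALSE)
    }
    out <- rbind(
      draw_pair("AAVal_AAMA", scn$true_slope_aa, 0),
      draw_pair("GAVal_GAMA", scn$true_slope_ga,
                log(20) - scn$blood_meanlog[["nonsmoker"]])
    )
    rownames(out) <- NULL
    attr(out, "truth") <- list(true_slope_aa = scn$true_slope_aa,
                               true_slope_ga = scn$true_slope_ga)
    out
  })
}

#' Generate one synthetic study reported as order statistics
#'
#' Draws `n` individual log-normal concentrations and reports them the way
#' a publication without a mean would: median, min, max, quartiles and the
#' count, with the mean cell left absent. The true sample mean is attached
#' as attribute `truth` for estimator validation.
#'
#' @param n Number of individuals (>= 6, the minimum usable study size).
#' @param lognormal_mu,lognormal_sigma Log-scale location and spread.
#' @param seed Integer seed.
#' @param study_id Label for the emitted record.
#' @return One-row data frame in the study-record schema.
#' @export
gen_individual_study <- function(n, lognormal_mu = log(50),
                                 lognormal_sigma = 0.5, seed = 1,
                                 study_id = "SYN") {
  if (n < 6) {
    abort_acry("synthetic studies respect the minimum size of 6", "acry_config_error")
  }
  with_seed(seed, {
    vals <- stats::rlnorm(n, lognormal_mu, lognormal_sigma)
    qs <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    rec <- data.frame(study_id = study_id, country = "XX", region = "north",
                      year_start = 2010, year_end = 2010,
                      matrix = "spot_urine", smoking = "nonsmoker",
                      analyte = "AAMA", n = n, mean = NA_real_,
                      median = qs[2], q1 = qs[1], q3 = qs[3],
                      min = min(vals), max = max(vals), sd = NA_real_,
                      lod = NA_real_, lod_unknown = FALSE, unit = "ug_per_L",
                      mean_age = 30, pct_male = 50, source = "published",
                      excluded_flag = FALSE,
                      exclusion_reason = NA_character_,
                      stringsAsFactors = FALSE)
    attr(rec, "truth") <- list(true_mean = mean(vals), true_sd = stats::sd(vals))
    rec
  })
}

#' Scenario for a synthetic yearly-mean panel
#'
#' Encodes the statistical structure the trend models assume: study-level
#' means that follow a (possibly broken) linear trend in year with
#' additive covariate effects, observed with between-study noise shrinking
#' as `1/sqrt(n/100)` so that larger studies are more precise and
#' study-size weighting is the efficient choice. Defaults mimic the
#' European non-smoker acrylamide panel: years 2001-2020, two studies per
#' year, study sizes 20-400, 40 ug/L at the reference year rising by
#' +2.1 ug/L per year up to a 2017 breakpoint and declining by 1 ug/L per
#' year after it, a mild negative age effect (-0.5 ug/L per year of age
#' around a reference of 25), no sex effect (none is seen in the real
#' data), and 8 ug/L of between-study spread at n = 100.
#'
#' @param years Sampling years.
#' @param studies_per_year Studies generated per year.
#' @param n_range Min/max study size (min must be >= 6).
#' @param intercept Mean ug/L at the reference (first) year, at reference
#'   age and a 50% male population.
#' @param slope_pre,slope_post Trend slopes before/after the breakpoint,
#'   ug/L per year.
#' @param psi True breakpoint year, or `NA` for a purely linear trend.
#' @param age_effect ug/L per year of mean age (centered at `ref_age`).
#' @param sex_effect ug/L per percentage point of males (centered at 50).
#' @param age_range,pct_male_range Ranges the population descriptors are
#'   drawn from.
#' @param ref_age Reference age for centering.
#' @param between_study_sd Between-study SD at n = 100, ug/L.
#' @param seed Integer seed.
#' @return List of class `panel_scenario`.
#' @export
panel_scenario <- function(years = 2001:2020, studies_per_year = 2,
                           n_range = c(20, 400), intercept = 40,
                           slope_pre = 2.1, slope_post = -1, psi = 2017,
                           age_effect = -0.5, sex_effect = 0,
                           age_range = c(6, 50), pct_male_range = c(30, 60),
                           ref_age = 25, between_study_sd = 8, seed = 1) {
  if (length(years) < 2) {
    abort_acry("need at least 2 years", "acry_config_error")
  }
  if (n_range[1] < 6) {
    abort_acry("minimum study size in a scenario is 6", "acry_config_error")
  }
  if (!is.na(psi) && (psi <= min(years) || psi >= max(years))) {
    abort_acry("psi must lie inside the year range (or be NA)",
               "acry_config_error")
  }
  structure(list(years = years, studies_per_year = studies_per_year,
                 n_range = n_range, intercept = intercept,
                 slope_pre = slope_pre, slope_post = slope_post, psi = psi,
                 age_effect = age_effect, sex_effect = sex_effect,
                 age_range = age_range, pct_male_range = pct_male_range,
                 ref_age = ref_age, between_study_sd = between_study_sd,
                 seed = seed),
            class = "panel_scenario")
}

#' Generate a synthetic harmonized panel with a known trend
#'
#' For each study: size `n` uniform over `n_range`, mean age and percent
#' male uniform over their ranges, true mean
#' `mu = intercept + slope_pre * (t - t0) + (slope_post - slope_pre) *
#' (t - psi)_+ + age_effect * (age - ref_age) + sex_effect * (pct_male -
#' 50)`, and observed mean `mu + N(0, between_study_sd / sqrt(n / 100))`.
#' The generating parameters and per-record true means are returned in a
#' separate `truth` element (serialized as a sidecar JSON by
#' [cmd_simulate()]); the panel itself carries no truth columns.
#'
#' @param scn A [panel_scenario()].
#' @return List with `panel` (class `acry_panel`) and `truth` (list of the
#'   scenario parameters plus per-record `true_mean`).
#' @examples
#' out <- gen_panel(panel_scenario(between_study_sd = 0, seed = 9))
#' fit_segmented(out$panel)$psi
#' @export
gen_panel <- function(scn) {
  stopifnot(inherits(scn, "panel_scenario"))
  with_seed(scn$seed, {
    t0 <- min(scn$years)
    yrs <- rep(scn$years, each = scn$studies_per_year)
    k <- length(yrs)
    n <- round(stats::runif(k, scn$n_range[1], scn$n_range[2]))
    age <- stats::runif(k, scn$age_range[1], scn$age_range[2])
    pmale <- stats::runif(k, scn$pct_male_range[1], scn$pct_male_range[2])
    brk <- if (is.na(scn$psi)) 0 else pmax(yrs - scn$psi, 0)
    mu <- scn$intercept + scn$slope_pre * (yrs - t0) +
      (if (is.na(scn$psi)) 0 else (scn$slope_post - scn$slope_pre) * brk) +
      scn$age_effect * (age - scn$ref_age) +
      scn$sex_effect * (pmale - 50)
    noise_sd <- scn$between_study_sd / sqrt(n / 100)
    obs <- mu + if (scn$between_study_sd > 0) stats::rnorm(k, 0, noise_sd) else 0
    panel <- data.frame(study_id = sprintf("SYN%03d", seq_len(k)),
                        country = "XX", region = "central_west", year = yrs,
                        analyte = "AAMA", smoking = "nonsmoker",
                        mean_ugL = obs, sd_ugL = NA_real_, n = n,
                        mean_age = age, pct_male = pmale,
                        provenance = "measured_mean", multi_year = FALSE,
                        low_confidence = FALSE, stringsAsFactors = FALSE)
    class(panel) <- c("acry_panel", "data.frame")
    truth <- list(intercept = scn$intercept, slope_pre = scn$slope_pre,
                  slope_post = scn$slope_post, psi = scn$psi,
                  age_effect = scn$age_effect, sex_effect = scn$sex_effect,
                  ref_year = t0, ref_age = scn$ref_age,
                  between_study_sd = scn$between_study_sd, seed = scn$seed,
                  true_mean = mu)
    list(panel = panel, truth = truth)
  })
}
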