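test_that("mean estimators reproduce their closed forms", {
  expect_equal(estimate_mean_from_range(m = 30, a = 15, b = 71), 36.5)
  expect_equal(estimate_mean_from_range(m = 7, a = 7, b = 7), 7)
  expect_equal(estimate_mean_from_range(m = 5, a = 0, b = 10), 5)
  expect_equal(estimate_mean_from_quartiles(q1 = 3, m = 6, q3 = 9), 6)
  expect_equal(estimate_mean_from_quartiles(q1 = 0, m = 0, q3 = 0), 0)
  expect_equal(estimate_mean_from_quartiles(q1 = 10, m = 20, q3 = 45), 25)
  expect_error(estimate_mean_from_range(m = 1, a = 5, b = 10),
               class = "acry_domain_error")
  expect_error(estimate_mean_from_quartiles(q1 = 5, m = 1, q3 = 10),
               class = "acry_domain_error")
})

test_that("SD estimator switches on sample size and is non-negative", {
  expect_equal(estimate_sd(m = 5, a = 0, b = 12, n = 30), 3)   # range / 4
  expect_equal(estimate_sd(m = 5, a = 0, b = 12, n = 100), 2)  # range / 6
  expect_equal(estimate_sd(m = 5, a = 5, b = 5, n = 10), 0)
  # small-sample formula, checked against independent arithmetic
  expect_equal(estimate_sd(m = 5, a = 0, b = 12, n = 10),
               sqrt(((0 - 10 + 12)^2 / 4 + 144) / 12))
  # monotone non-increasing in n at fixed range
  for (rng in list(c(0, 8), c(2, 50))) {
    s_mid <- estimate_sd(m = mean(rng), a = rng[1], b = rng[2], n = 40)
    s_big <- estimate_sd(m = mean(rng), a = rng[1], b = rng[2], n = 200)
    expect_gte(s_mid, s_big)
  }
})

test_that("estimators are affine-equivariant", {
  set.seed(101)
  for (i in 1:25) {
    v <- sort(runif(3, 0, 100))
    a <- v[1]; m <- v[2]; b <- v[3]
    alpha <- runif(1, 0.1, 5); beta <- runif(1, -20, 20)
    expect_equal(estimate_mean_from_range(alpha * m + beta, alpha * a + beta,
                                          alpha * b + beta),
                 alpha * estimate_mean_from_range(m, a, b) + beta)
    n <- sample(c(8, 40, 200), 1)
    expect_equal(estimate_sd(alpha * m + beta, alpha * a + beta,
                             alpha * b + beta, n),
                 alpha * estimate_sd(m, a, b, n))
  }
})

test_that("range estimator is unbiased for symmetric data (Monte Carlo)", {
  set.seed(7)
  est <- replicate(1000, {
    x <- rnorm(15, mean = 50, sd = 5)
    estimate_mean_from_range(median(x), min(x), max(x))
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 50), 2 * mc_se)
})

test_that("zero-intercept conversion fit matches its normal equation", {
  # exact proportionality
  b <- c(1, 2, 5, 9)
  rec <- data.frame(subject_id = letters[1:4], blood_value = b,
                    urine_value = 2 * b, analyte_pair = "AAVal_AAMA",
                    smoking = "nonsmoker")
  cf <- fit_conversion_factor(rec, "AAVal_AAMA")
  expect_equal(cf$slope, 2)
  expect_equal(cf$r_squared, 1)
  # two-record closed form: (1*1 + 3*6) / (1 + 9)
  rec2 <- data.frame(subject_id = c("a", "b"), blood_value = c(1, 3),
                     urine_value = c(1, 6), analyte_pair = "AAVal_AAMA",
                     smoking = "smoker")
  expect_equal(fit_conversion_factor(rec2, "AAVal_AAMA")$slope, 1.9)
  # degenerate input
  rec3 <- rec
  rec3$blood_value <- 0
  expect_error(fit_conversion_factor(rec3, "AAVal_AAMA"),
               class = "acry_model_error")
})

test_that("conversion fit agrees with an independent no-intercept regression", {
  rec <- gen_dual_matrix(dual_matrix_scenario(seed = 33))
  for (pair in c("AAVal_AAMA", "GAVal_GAMA")) {
    sub <- rec[rec$analyte_pair == pair, ]
    cf <- fit_conversion_factor(rec, pair)
    ref <- summary(lm(urine_value ~ 0 + blood_value, data = sub))
    expect_equal(cf$slope, unname(ref$coefficients[1, 1]), tolerance = 1e-12)
    expect_equal(cf$se_slope, unname(ref$coefficients[1, 2]),
                 tolerance = 1e-12)
  }
})

test_that("blood-to-urine conversion is linear and matches worked examples", {
  fac <- fixed_conversion_factors()$AAVal_AAMA
  expect_equal(blood_to_urine(79.1, fac), 129.724)
  expect_equal(round(blood_to_urine(79.1, fac), 1), 129.7)
  expect_equal(blood_to_urine(26.8, fac), 43.952)
  expect_equal(blood_to_urine(0, fac), 0)
  x <- 12.3; y <- 4.56
  expect_equal(blood_to_urine(x + y, fac),
               blood_to_urine(x, fac) + blood_to_urine(y, fac))
  expect_error(blood_to_urine(-1, fac), class = "acry_domain_error")
})

test_that("relative error is a signed percent", {
  expect_equal(round(relative_error(59.04, 64.5), 2), -8.47)
  expect_equal(round(abs(relative_error(59.04, 64.5)), 1), 8.5)
  expect_equal(relative_error(5, 5), 0)
  expect_equal(round(relative_error(129.724, 107.3), 2), 20.9)
  expect_error(relative_error(1, 0), class = "acry_domain_error")
})

test_that("harmonization applies the inclusion rules in order", {
  studies <- fixture_studies()
  h <- harmonize(studies)
  panel <- h$panel
  excl <- h$exclusions

  # multi-year window resolved to its midpoint year
  tds <- panel[panel$study_id == "TDS" & panel$analyte == "AAMA", ]
  expect_equal(tds$year, 2008)
  expect_true(tds$multi_year)

  # 24 h urine records fall under the matrix/unit rule
  mu <- excl[excl$study_id == "MU" & excl$analyte == "AAMA", ]
  expect_true(all(mu$rule == 4))

  # overlap-flagged records fall under the exclusion-flag rule
  gs <- excl[excl$study_id == "GS", ]
  expect_true(all(gs$rule == 8))

  # median-only records with no range cannot be harmonized
  mb <- excl[excl$study_id == "MB", ]
  expect_true(all(mb$rule == 6))

  # glycidamide blood records are not converted by default
  expect_false(any(panel$provenance %in%
                     c("trans_matrix", "trans_matrix_plus_median") &
                     panel$analyte == "GAMA"))
})

test_that("the minimum-size rule keeps n = 6 and drops n = 5", {
  studies <- rbind(make_study(study_id = "FIVE", n = 5),
                   make_study(study_id = "SIX", n = 6))
  h <- harmonize(studies)
  expect_equal(h$panel$study_id, "SIX")
  expect_equal(h$exclusions$study_id, "FIVE")
  expect_equal(h$exclusions$rule, 2L)
})

test_that("mixed populations and unassignable years are dropped with their rules", {
  studies <- rbind(make_study(study_id = "MIX", smoking = "mixed"),
                   make_study(study_id = "NOYEAR", year_start = NA_real_,
                              year_end = NA_real_))
  h <- harmonize(studies)
  expect_equal(nrow(h$panel), 0)
  expect_equal(sort(h$exclusions$rule), c(1L, 3L))
})

test_that("LOD-bounded ranges are closed at zero and flagged", {
  rec <- make_study(study_id = "LODR", mean = NA_real_, median = 29,
                    max = 229, lod_unknown = TRUE)
  h <- harmonize(rec)
  expect_equal(h$panel$mean_ugL, (0 + 2 * 29 + 229) / 4)
  expect_true(h$panel$low_confidence)
  expect_equal(h$panel$provenance, "mean_from_median_range")
})

test_that("quartiles are preferred over the range when both are present", {
  rec <- make_study(study_id = "Q", mean = NA_real_, median = 20, q1 = 10,
                    q3 = 45, min = 1, max = 100)
  h <- harmonize(rec)
  expect_equal(h$panel$mean_ugL, 25)
  expect_equal(h$panel$provenance, "mean_from_quartiles")
})

test_that("glycidamide blood records convert only with an explicit factor", {
  rec <- make_study(study_id = "GA", matrix = "blood", analyte = "GAVal",
                    unit = "pmol_per_g_Hb", mean = 20)
  h_off <- harmonize(rec)
  expect_equal(nrow(h_off$panel), 0)
  expect_equal(h_off$exclusions$rule, 4L)
  h_on <- harmonize(rec, rules = harmonization_rules(apply_gama_trans_matrix = TRUE))
  expect_equal(h_on$panel$mean_ugL, 0.35 * 20)
  expect_equal(h_on$panel$analyte, "GAMA")
})

test_that("harmonization is idempotent on an already-harmonized panel", {
  panel <- harmonize(fixture_studies())$panel
  again <- harmonize(as_study_records(panel))
  expect_equal(nrow(again$exclusions), 0)
  expect_equal(again$panel$mean_ugL, panel$mean_ugL)
  expect_equal(again$panel$year, panel$year)
  expect_equal(again$panel$n, panel$n)
  expect_equal(again$panel$smoking, panel$smoking)
})
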