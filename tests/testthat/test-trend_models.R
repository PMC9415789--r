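test_that("two equally weighted points are interpolated exactly", {
  panel <- data.frame(study_id = c("a", "b", "c"), year = c(0, 1, 2),
                      mean_ugL = c(0, 1, 2), n = c(1, 1, 1))
  fit <- fit_weighted_mlr(panel, covariates = "year")
  expect_equal(unname(fit$coefficients["intercept"]), 0, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["year"]), 1, tolerance = 1e-12)
  expect_equal(fit$weighted_sse, 0, tolerance = 1e-20)
})

test_that("weighted fit matches the reference WLS implementation", {
  panel <- fixture_aama_panel()
  fit <- fit_weighted_mlr(panel, covariates = c("year", "mean_age", "pct_male"))
  keep <- complete.cases(panel[c("mean_ugL", "year", "mean_age", "pct_male")])
  ref <- lm(mean_ugL ~ year + mean_age + pct_male, data = panel[keep, ],
            weights = panel$n[keep])
  sref <- summary(ref)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sref$coefficients[, 2]),
               tolerance = 1e-8)
  expect_equal(unname(fit$p_value), unname(sref$coefficients[, 4]),
               tolerance = 1e-8)
})

test_that("coefficients minimize the weighted SSE (brute-force oracle)", {
  set.seed(5)
  for (rep in 1:3) {
    n <- 25
    panel <- data.frame(study_id = as.character(1:n),
                        year = runif(n, -5, 5),      # centered time scale
                        mean_age = runif(n, -2, 2),
                        mean_ugL = rnorm(n, 10, 4),
                        n = sample(10:200, n))
    fit <- fit_weighted_mlr(panel, covariates = c("year", "mean_age"))
    X <- cbind(1, panel$year, panel$mean_age)
    bf <- brute_force_wls(X, panel$mean_ugL, panel$n)
    expect_equal(unname(fit$coefficients), bf, tolerance = 1e-8)
  }
})

test_that("equal weights reduce WLS to OLS", {
  set.seed(8)
  panel <- data.frame(study_id = as.character(1:20), year = 1:20,
                      mean_ugL = rnorm(20, 50, 5), n = rep(7, 20))
  fit <- fit_weighted_mlr(panel, covariates = "year")
  ref <- lm(mean_ugL ~ year, data = panel)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-10)
})

test_that("replicating a record k times equals weighting it by k", {
  base <- data.frame(study_id = as.character(1:6), year = c(1, 2, 3, 4, 5, 6),
                     mean_ugL = c(3, 5, 4, 8, 7, 11), n = c(1, 1, 1, 1, 1, 3))
  reps <- base[c(1:5, 6, 6, 6), ]
  reps$n <- 1
  f_w <- fit_weighted_mlr(base, covariates = "year")
  f_r <- fit_weighted_mlr(reps, covariates = "year")
  expect_equal(f_w$coefficients, f_r$coefficients, tolerance = 1e-12)
  expect_equal(f_w$weighted_sse, f_r$weighted_sse, tolerance = 1e-12)
})

test_that("generated trends are recovered within 2 SE", {
  scn <- panel_scenario(years = 2001:2015, studies_per_year = 2,
                        n_range = c(100, 100), slope_pre = 2, slope_post = 2,
                        psi = NA, age_effect = -0.5, sex_effect = 0,
                        between_study_sd = 5, seed = 21)
  pan <- gen_panel(scn)$panel
  fit <- fit_weighted_mlr(pan, covariates = c("year", "mean_age"))
  expect_lt(abs(fit$coefficients["year"] - 2), 2 * fit$se["year"])
  expect_lt(abs(fit$coefficients["mean_age"] + 0.5), 2 * fit$se["mean_age"])
})

test_that("a constant covariate raises a collinearity error naming it", {
  panel <- data.frame(study_id = as.character(1:8), year = 1:8,
                      mean_age = rep(30, 8), mean_ugL = rnorm(8), n = 1:8)
  err <- tryCatch(fit_weighted_mlr(panel, covariates = c("year", "mean_age")),
                  error = identity)
  expect_s3_class(err, "acry_model_error")
  expect_match(conditionMessage(err), "mean_age")
})

test_that("residual diagnostics use the (i - 0.5)/n plotting positions", {
  panel <- data.frame(study_id = c("a", "b", "c", "d"), year = c(1, 2, 3, 4),
                      mean_ugL = c(1, 2, 3, 4), n = rep(1, 4))
  fit <- fit_weighted_mlr(panel, covariates = "year")  # perfect fit
  qq <- export_residual_diagnostics(fit)
  expect_equal(qq$std_residual, rep(0, 4))

  panel3 <- data.frame(study_id = c("a", "b", "c"), year = c(1, 2, 4),
                       mean_ugL = c(1, 3, 2), n = rep(1, 3))
  qq3 <- export_residual_diagnostics(fit_weighted_mlr(panel3, "year"))
  expect_equal(qq3$theoretical_quantile,
               qnorm(c(1 / 6, 3 / 6, 5 / 6)))
  expect_equal(qq3$std_residual, sort(qq3$std_residual))
})

test_that("normal residuals give a nearly linear Q-Q relation", {
  scn <- panel_scenario(years = 2001:2015, studies_per_year = 2, psi = NA,
                        slope_post = 2.1, n_range = c(100, 100),
                        between_study_sd = 6, seed = 14)
  pan <- gen_panel(scn)$panel
  fit <- fit_weighted_mlr(pan, covariates = c("year", "mean_age"))
  qq <- export_residual_diagnostics(fit)
  expect_gt(cor(qq$std_residual, qq$theoretical_quantile), 0.95)
})
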