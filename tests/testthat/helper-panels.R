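# Shared fixtures and independent oracles for the test suite.

fixture_studies <- function() {
  rbind(read_studies(acry_fixture("table1_published.csv")),
        read_studies(acry_fixture("table2_aligned.csv")))
}

fixture_aama_panel <- function() {
  trend_stratum(harmonize(fixture_studies())$panel)
}

# A minimal valid study record, overridable field by field.
make_study <- function(...) {
  rec <- data.frame(study_id = "T", country = "XX", region = "north",
                    year_start = 2010, year_end = 2010,
                    matrix = "spot_urine", smoking = "nonsmoker",
                    analyte = "AAMA", n = 50, mean = 10, median = NA_real_,
                    q1 = NA_real_, q3 = NA_real_, min = NA_real_,
                    max = NA_real_, sd = NA_real_, lod = NA_real_,
                    lod_unknown = FALSE, unit = "ug_per_L", mean_age = 30,
                    pct_male = 50, source = "published",
                    excluded_flag = FALSE,
                    exclusion_reason = NA_character_,
                    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# Independent brute-force weighted-SSE minimizer (BFGS with analytic
# gradient): never touches the package's QR path.
brute_force_wls <- function(X, y, w) {
  f <- function(b) sum(w * (y - drop(X %*% b))^2)
  g <- function(b) -2 * drop(t(X) %*% (w * (y - drop(X %*% b))))
  stats::optim(rep(0, ncol(X)), f, g, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))$par
}

# Fine-grid breakpoint oracle: minimize the broken-line weighted SSE over a
# 0.01-year grid, independent of the iterative estimator.
grid_psi_oracle <- function(x, y, w, by = 0.01) {
  grid <- seq(min(x) + by, max(x) - by, by = by)
  sse <- vapply(grid, function(p) {
    U <- pmax(x - p, 0)
    fit <- stats::lm.fit(cbind(1, x, U) * sqrt(w), y * sqrt(w))
    sum(fit$residuals^2)
  }, numeric(1))
  grid[which.min(sse)]
}
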