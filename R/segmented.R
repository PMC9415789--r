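# One-breakpoint segmented regression (iterative linearization with a grid
# safeguard) and a parametric-bootstrap test for the existence of a break.

# Weighted SSE of the broken-line model at a fixed breakpoint.
.seg_sse_at <- function(x, y, w, Z, psi) {
  U <- pmax(x - psi, 0)
  X <- cbind(1, x, U, Z)
  sw <- sqrt(w)
  fit <- stats::lm.fit(X * sw, y * sw)
  sum(fit$residuals^2)
}

.seg_grid_search <- function(x, y, w, Z, by = 0.05) {
  lo <- min(x); hi <- max(x)
  grid <- seq(lo + by, hi - by, by = by)
  sse <- vapply(grid, function(p) .seg_sse_at(x, y, w, Z, p), numeric(1))
  grid[which.min(sse)]
}

# The iterative linearization: augment the design with U = (t - psi)_+ and
# V = -1[t > psi]; after each weighted fit move psi by gamma_hat / b2_hat;
# stop when |gamma_hat| < tol. Returns the breakpoint, the convergence flag,
# the final gap, and the delta-method SE of psi.
.seg_iterate <- function(x, y, w, Z, psi, tol) {
  lo <- min(x); hi <- max(x)
  eps <- 1e-3 * (hi - lo)
  sw <- sqrt(w)
  gamma <- NA_real_
  for (iter in seq_len(100)) {
    U <- pmax(x - psi, 0)
    V <- -as.numeric(x > psi)
    X <- cbind(intercept = 1, year = x, U = U, V = V, Z)
    fit <- stats::lm.fit(X * sw, y * sw)
    cf <- fit$coefficients
    gamma <- unname(cf["V"])
    beta2 <- unname(cf["U"])
    if (is.na(gamma) || is.na(beta2) || abs(beta2) < 1e-12) {
      return(list(psi = psi, converged = FALSE, gamma = gamma,
                  se_psi = NA_real_))
    }
    if (abs(gamma) < tol) {
      df <- length(y) - fit$rank
      sigma2 <- sum(fit$residuals^2) / max(df, 1)
      R <- qr.R(fit$qr)
      xtxinv <- chol2inv(R)
      piv <- fit$qr$pivot
      xtxinv[piv, piv] <- xtxinv
      v_idx <- match("V", colnames(X))
      se_psi <- sqrt(sigma2 * xtxinv[v_idx, v_idx]) / abs(beta2)
      return(list(psi = psi, converged = TRUE, gamma = gamma,
                  se_psi = se_psi))
    }
    psi_new <- psi + gamma / beta2
    if (!is.finite(psi_new)) {
      return(list(psi = psi, converged = FALSE, gamma = gamma,
                  se_psi = NA_real_))
    }
    psi <- min(max(psi_new, lo + eps), hi - eps)
  }
  list(psi = psi, converged = FALSE, gamma = gamma, se_psi = NA_real_)
}

#' Fit a one-breakpoint segmented time-trend model
#'
#' Fits the broken-line model
#' `y = b0 + b1 * t + b2 * (t - psi)_+ (+ covariates)` by weighted least
#' squares, estimating the breakpoint `psi` by iterative linearization:
#' the design is augmented with `U = (t - psi)_+` and `V = -1[t > psi]`,
#' and after each fit the breakpoint moves by `gamma_hat / b2_hat` (the
#' coefficient of `V` over that of `U`), until `|gamma_hat| < 1e-6` or 100
#' iterations. The objective can have local kinks between observation
#' years, so the iterative solution is always checked against a grid
#' search at 0.05-year resolution over the interior of the year range: if
#' the grid finds a lower weighted SSE, the iteration restarts from the
#' grid optimum, and if it still will not converge there the grid optimum
#' itself is returned (method `"grid"`).
#'
#' @param panel Harmonized panel.
#' @param covariates Extra design columns beyond the broken line in year;
#'   default none (a univariate trend).
#' @param psi_init Starting breakpoint; default the midpoint of the year
#'   range. Must lie strictly inside the range.
#' @param weights Per-record weights; default study sizes `panel$n`.
#' @param response Panel column holding the response.
#' @param tol Convergence tolerance on the reparameterization gap.
#' @return An object of class `segmented_fit`: `psi`, `se_psi`,
#'   `slope_left`, `slope_right` (ug/L per year), `gamma_final`,
#'   `converged`, `method` (`"iterative"` or `"grid"`), coefficient vector,
#'   `weighted_sse`, `df_resid`, `n_obs`, and the data the model saw
#'   (needed by [test_breakpoint()]). `p_break` is `NA` until the bootstrap
#'   test is run.
#' @examples
#' pan <- gen_panel(panel_scenario(between_study_sd = 0, seed = 3))$panel
#' fit_segmented(pan)
#' @export
fit_segmented <- function(panel, covariates = character(0), psi_init = NULL,
                          weights = NULL, response = "mean_ugL", tol = 1e-6) {
  stopifnot(is.data.frame(panel))
  weights <- weights %||% panel$n
  use_cols <- c(response, "year", covariates)
  keep <- stats::complete.cases(panel[use_cols])
  panel <- panel[keep, , drop = FALSE]
  weights <- weights[keep]
  x <- panel$year
  y <- panel[[response]]
  if (length(unique(x)) < 5) {
    abort_acry("need at least 5 distinct year values for a breakpoint fit",
               "acry_model_error")
  }
  Z <- if (length(covariates)) as.matrix(panel[covariates]) else NULL
  lo <- min(x); hi <- max(x)
  psi0 <- psi_init %||% ((lo + hi) / 2)
  if (psi0 <= lo || psi0 >= hi) {
    abort_acry("psi_init must lie strictly inside the observed year range",
               "acry_config_error")
  }
  it <- .seg_iterate(x, y, weights, Z, psi0, tol)
  psi_grid <- .seg_grid_search(x, y, weights, Z, by = 0.05)
  sse_it <- if (it$converged) .seg_sse_at(x, y, weights, Z, it$psi) else Inf
  sse_gr <- .seg_sse_at(x, y, weights, Z, psi_grid)
  if (sse_gr < sse_it * (1 - 1e-10)) {
    it2 <- .seg_iterate(x, y, weights, Z, psi_grid, tol)
    sse_it2 <- if (it2$converged) .seg_sse_at(x, y, weights, Z, it2$psi) else Inf
    if (it2$converged && sse_it2 <= sse_gr) {
      it <- it2
      method <- "iterative"
    } else {
      it <- list(psi = psi_grid, converged = TRUE, gamma = NA_real_,
                 se_psi = NA_real_)
      method <- "grid"
    }
  } else {
    method <- "iterative"
  }
  psi <- it$psi
  # final fit of the broken line at the estimated breakpoint
  U <- pmax(x - psi, 0)
  Xf <- cbind(intercept = 1, year = x, U = U, Z)
  final <- .wls_fit(Xf, y, weights, check_rank = FALSE)
  cf <- final$coefficients
  structure(list(psi = psi, se_psi = it$se_psi,
                 slope_left = unname(cf["year"]),
                 slope_right = unname(cf["year"]) + unname(cf["U"]),
                 gamma_final = it$gamma, p_break = NA_real_,
                 converged = it$converged, method = method,
                 coefficients = cf, weighted_sse = final$weighted_sse,
                 df_resid = length(y) - final$rank - 1L,  # psi counts as a parameter
                 n_obs = length(y), n_boot = NA_integer_,
                 x = x, y = y, weights = weights, Z = Z,
                 covariates = covariates, response = response),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Segmented trend fit (%d records, %s)\n", x$n_obs, x$method))
  cat(sprintf("  breakpoint psi = %.2f (SE %s)\n", x$psi,
              ifelse(is.na(x$se_psi), "n/a", sprintf("%.3f", x$se_psi))))
  cat(sprintf("  slope before: %+.3f ug/L per year; after: %+.3f\n",
              x$slope_left, x$slope_right))
  if (!is.na(x$p_break)) {
    cat(sprintf("  bootstrap p(break) = %.4g (n_boot = %d)\n",
                x$p_break, x$n_boot))
  }
  invisible(x)
}

# Minimized broken-line weighted SSE used inside the bootstrap loop: same
# iterative-plus-grid strategy as the main fit, returning the best SSE found.
.boot_seg_sse <- function(x, y, w, Z, tol = 1e-6) {
  it <- .seg_iterate(x, y, w, Z, (min(x) + max(x)) / 2, tol)
  psi_grid <- .seg_grid_search(x, y, w, Z, by = 0.05)
  sse_gr <- .seg_sse_at(x, y, w, Z, psi_grid)
  best <- sse_gr
  if (it$converged) best <- min(best, .seg_sse_at(x, y, w, Z, it$psi))
  it2 <- .seg_iterate(x, y, w, Z, psi_grid, tol)
  if (it2$converged) best <- min(best, .seg_sse_at(x, y, w, Z, it2$psi))
  best
}

#' Parametric-bootstrap test for the existence of a breakpoint
#'
#' Tests the straight-line null against the one-breakpoint alternative.
#' The observed statistic is
#' `F = ((SSE_linear - SSE_segmented) / 2) / (SSE_segmented / df)`,
#' charging the segmented model its two extra parameters (the slope change
#' and the breakpoint location). Because `psi` is not identified under the
#' null, the reference distribution is built by a parametric bootstrap: the
#' no-breakpoint weighted linear model is refitted, `n_boot` response
#' vectors are simulated from it (normal errors with variance
#' `MSE / w_i`), and the statistic is recomputed on each. The p-value is
#' `(1 + #{F_boot >= F_obs}) / (n_boot + 1)`, so it can never fall below
#' `1 / (n_boot + 1)`.
#'
#' @param panel Harmonized panel the fit was made on (only used for its
#'   dimensions; the data stored in `fit` drive the test).
#' @param fit A converged [fit_segmented()] result.
#' @param n_boot Number of bootstrap replicates (>= 99).
#' @param seed Integer seed; fixed seeds give bit-reproducible p-values.
#' @return The `segmented_fit` with `p_break` and `n_boot` filled in.
#' @examples
#' pan <- gen_panel(panel_scenario(seed = 5))$panel
#' sf <- fit_segmented(pan)
#' sf <- test_breakpoint(pan, sf, n_boot = 99, seed = 1)
#' sf$p_break
#' @export
test_breakpoint <- function(panel, fit, n_boot = 499, seed = 1) {
  stopifnot(inherits(fit, "segmented_fit"), n_boot >= 99)
  if (!isTRUE(fit$converged) && fit$method != "grid") {
    abort_acry("segmented fit did not converge; refusing to bootstrap",
               "acry_model_error")
  }
  x <- fit$x; y <- fit$y; w <- fit$weights; Z <- fit$Z
  n <- length(y)
  Xlin <- cbind(intercept = 1, year = x, Z)
  lin <- .wls_fit(Xlin, y, w, check_rank = FALSE)
  p_lin <- lin$rank
  df_seg <- n - (p_lin + 2L)
  if (df_seg < 1) {
    abort_acry("too few records to test for a breakpoint", "acry_model_error")
  }
  f_stat <- function(yy) {
    l <- .wls_fit(Xlin, yy, w, check_rank = FALSE)
    sse_seg <- .boot_seg_sse(x, yy, w, Z)
    ((l$weighted_sse - sse_seg) / 2) / (sse_seg / df_seg)
  }
  sse_seg_obs <- min(fit$weighted_sse, .boot_seg_sse(x, y, w, Z))
  f_obs <- ((lin$weighted_sse - sse_seg_obs) / 2) / (sse_seg_obs / df_seg)
  sigma2 <- lin$weighted_sse / lin$df_resid
  sd_i <- sqrt(sigma2 / w)
  f_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      yb <- lin$fitted + stats::rnorm(n, 0, sd_i)
      f_stat(yb)
    }, numeric(1))
  })
  fit$p_break <- (1 + sum(f_boot >= f_obs)) / (n_boot + 1)
  fit$n_boot <- as.integer(n_boot)
  fit$f_obs <- f_obs
  fit
}
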