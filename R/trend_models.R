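# Study-size-weighted linear trend model and residual diagnostics.

# Weighted least squares on a prebuilt design matrix. Returns coefficients,
# covariance pieces and the weighted SSE. X and y are on the original scale;
# weights w with var(y_i) proportional to 1/w_i.
.wls_fit <- function(X, y, w, check_rank = TRUE) {
  sw <- sqrt(w)
  Xs <- X * sw
  ys <- y * sw
  qrx <- qr(Xs)
  if (check_rank && qrx$rank < ncol(Xs)) {
    dropped <- colnames(Xs)[qrx$pivot[(qrx$rank + 1):ncol(Xs)]]
    abort_acry(sprintf("design is rank deficient (collinear column: %s)",
                       paste(dropped, collapse = ", ")), "acry_model_error")
  }
  beta <- qr.coef(qrx, ys)
  fitted <- drop(X %*% beta)
  res_w <- sw * (y - fitted)
  sse <- sum(res_w^2)
  df <- length(y) - qrx$rank
  R <- qr.R(qrx)
  # unpivot (X'WX)^-1
  xtxinv <- chol2inv(R)
  piv <- qrx$pivot
  xtxinv[piv, piv] <- xtxinv
  list(coefficients = beta, fitted = fitted, weighted_residuals = res_w,
       weighted_sse = sse, df_resid = df, xtx_inv = xtxinv, rank = qrx$rank)
}

.build_design <- function(panel, covariates) {
  X <- cbind(intercept = rep(1, nrow(panel)))
  for (cv in covariates) {
    if (!cv %in% names(panel)) {
      abort_acry(sprintf("covariate '%s' not found in panel", cv),
                 "acry_data_error")
    }
    X <- cbind(X, panel[[cv]])
  }
  colnames(X) <- c("intercept", covariates)
  X
}

#' Fit the study-size-weighted multiple linear trend model
#'
#' Regresses study-level mean concentrations (ug/L) on calendar year and
#' optional population covariates (mean age in years, percent male), with
#' weights equal to the number of participants behind each mean: larger
#' studies pin the trend down more precisely, so each record contributes
#' proportionally to its sample size. Coefficients minimize the weighted sum
#' of squares `sum(w_i (y_i - x_i' beta)^2)`; standard errors come from the
#' weighted information matrix with the error variance estimated as
#' weighted SSE / residual df, and p-values from a two-sided Student t test
#' on `n_obs - n_params` df.
#'
#' Records missing a requested covariate are dropped before fitting and
#' listed in the `dropped` element of the result.
#'
#' @param panel Harmonized panel (rows = study-year means).
#' @param covariates Character vector of panel columns entering the design
#'   after the intercept; default `"year"` only.
#' @param response Panel column holding the response (default `mean_ugL`).
#' @param weights Per-record weights; default the study sizes `panel$n`.
#' @return An object of class `trend_fit`: coefficient table
#'   (`coefficients`, `se`, `t_stat`, `p_value` as named vectors),
#'   `weighted_sse`, `df_resid`, `residuals` (weighted, i.e. scaled by
#'   `sqrt(w)`), `fitted`, `n_obs`, and the model frame used.
#' @examples
#' scn <- panel_scenario(seed = 11)
#' pan <- gen_panel(scn)$panel
#' fit_weighted_mlr(pan, covariates = c("year", "mean_age"))
#' @export
fit_weighted_mlr <- function(panel, covariates = "year",
                             response = "mean_ugL", weights = NULL) {
  stopifnot(is.data.frame(panel), nrow(panel) >= 1)
  weights <- weights %||% panel$n
  if (any(weights <= 0)) {
    abort_acry("all weights must be positive", "acry_data_error")
  }
  use_cols <- c(response, covariates)
  keep <- stats::complete.cases(panel[use_cols])
  dropped <- panel$study_id[!keep]
  panel <- panel[keep, , drop = FALSE]
  weights <- weights[keep]
  n <- nrow(panel)
  p <- length(covariates) + 1L
  if (n <= p) {
    abort_acry(sprintf("need more observations (%d) than parameters (%d)",
                       n, p), "acry_data_error")
  }
  X <- .build_design(panel, covariates)
  y <- panel[[response]]
  fit <- .wls_fit(X, y, weights)
  sigma2 <- fit$weighted_sse / fit$df_resid
  se <- sqrt(sigma2 * diag(fit$xtx_inv))
  names(se) <- names(fit$coefficients)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(abs(tval), df = fit$df_resid, lower.tail = FALSE)
  structure(list(coefficients = fit$coefficients, se = se, t_stat = tval,
                 p_value = pval, weighted_sse = fit$weighted_sse,
                 df_resid = fit$df_resid,
                 residuals = fit$weighted_residuals, fitted = fit$fitted,
                 n_obs = n, covariates = covariates, response = response,
                 weights = weights, model_frame = panel, dropped = dropped),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Weighted linear trend model (%d records, df = %d)\n",
              x$n_obs, x$df_resid))
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t_stat,
                    p = x$p_value)
  print(round(tab, 4))
  if (length(x$dropped)) {
    cat(sprintf("dropped (missing covariates): %s\n",
                paste(x$dropped, collapse = ", ")))
  }
  invisible(x)
}

#' Residual diagnostics for a weighted trend fit
#'
#' Standardizes the weighted residuals by the weighted root mean square
#' error and pairs them, sorted ascending, with theoretical normal
#' quantiles at plotting positions `(i - 0.5) / n`, ready for a Q-Q plot or
#' normality check.
#'
#' @param fit A `trend_fit`.
#' @return Data frame with columns `std_residual` and
#'   `theoretical_quantile`, sorted by residual.
#' @export
export_residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  r <- fit$residuals
  if (length(r) < 3) {
    abort_acry("need at least 3 residuals for diagnostics", "acry_data_error")
  }
  mse <- fit$weighted_sse / fit$df_resid
  std <- if (mse > 0) r / sqrt(mse) else r * 0
  n <- length(std)
  data.frame(std_residual = sort(std),
             theoretical_quantile = stats::qnorm((seq_len(n) - 0.5) / n))
}
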