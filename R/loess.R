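# Locally weighted polynomial smoothing with a tricube kernel and prior
# (study-size) weights.

#' LOESS smoothing of the yearly-mean trend
#'
#' Local polynomial regression: at each evaluation point the
#' `ceiling(span * n)` nearest observations (in year) receive tricube
#' kernel weights `(1 - (d/h)^3)^3`, which are multiplied by the per-record
#' prior weights (study sizes), and a polynomial of the requested degree is
#' fitted by weighted least squares; the smoothed value is that local
#' polynomial evaluated at the point. Because each local fit is an exact
#' weighted least-squares solve, the smoother reproduces any global
#' polynomial of its own degree exactly, and centering the local design at
#' the evaluation point makes the curve invariant to shifting the time axis.
#'
#' Optional robustness iterations downweight outliers by Tukey bisquare
#' weights on the residuals (0 iterations by default).
#'
#' @param x Observation times (years).
#' @param y Responses (mean ug/L).
#' @param w Prior weights, e.g. study sizes; default all 1.
#' @param span Neighborhood fraction in (0, 1].
#' @param degree Local polynomial degree (0, 1 or 2).
#' @param grid_x Evaluation grid; default 101 points over `range(x)`.
#' @param robustness_iters Number of bisquare re-weighting passes.
#' @return Object of class `loess_fit`: `span`, `degree`, `grid_x`,
#'   `fitted`, `se_fitted`, `robustness_iters`, plus `fitted_at_x` (the
#'   smooth evaluated at the data points).
#' @examples
#' x <- 2001:2020
#' y <- 40 + 2 * (x - 2001) + rnorm(20)
#' fit_loess(x, y, span = 0.75, degree = 2)
#' @export
fit_loess <- function(x, y, w = NULL, span = 0.75, degree = 2,
                      grid_x = NULL, robustness_iters = 0) {
  n <- length(x)
  stopifnot(length(y) == n, n >= degree + 2, span > 0, span <= 1,
            degree %in% 0:2)
  w <- w %||% rep(1, n)
  if (ceiling(span * n) < degree + 1) {
    abort_acry("span window holds fewer points than the local polynomial needs",
               "acry_model_error")
  }
  grid_x <- grid_x %||% seq(min(x), max(x), length.out = 101)
  rw <- rep(1, n)  # robustness weights
  fit_at <- function(x0) {
    d <- abs(x - x0)
    q <- ceiling(span * n)
    h <- sort(d, partial = q)[q]
    kern <- if (h > 0) ifelse(d < h, (1 - (d / h)^3)^3, 0) else as.numeric(d == 0)
    ww <- kern * w * rw
    use <- ww > 0
    if (sum(use) < degree + 1) {
      abort_acry(sprintf("fewer than %d points with positive weight near %.3g",
                         degree + 1, x0), "acry_model_error")
    }
    xc <- x[use] - x0
    X <- stats::poly(xc, degree = max(degree, 1), raw = TRUE, simple = TRUE)
    X <- cbind(1, X)[, seq_len(degree + 1), drop = FALSE]
    sw <- sqrt(ww[use])
    fit <- stats::lm.fit(X * sw, y[use] * sw)
    # smoother vector l(x0): fitted value = l %*% y[use]
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    val <- cf[1]
    xtxinv <- tryCatch({
      R <- qr.R(fit$qr)
      inv <- chol2inv(R)
      piv <- fit$qr$pivot
      inv[piv, piv] <- inv
      inv
    }, error = function(e) NULL)
    lvec <- rep(0, n)
    if (!is.null(xtxinv)) {
      l_use <- drop((xtxinv %*% t(X * ww[use]))[1, ])
      lvec[use] <- l_use
    }
    list(value = unname(val), l = lvec)
  }
  run_pass <- function() {
    at_x <- lapply(x, fit_at)
    list(fitted_at_x = vapply(at_x, `[[`, numeric(1), "value"))
  }
  pass <- run_pass()
  if (robustness_iters > 0) {
    for (k in seq_len(robustness_iters)) {
      r <- y - pass$fitted_at_x
      s <- stats::median(abs(r))
      rw <- if (s > 0) pmax(0, (1 - (r / (6 * s))^2))^2 else rep(1, n)
      pass <- run_pass()
    }
  }
  res <- y - pass$fitted_at_x
  df_local <- max(n - (degree + 1), 1)
  sigma2 <- sum(w * res^2) / df_local
  at_grid <- lapply(grid_x, fit_at)
  fitted <- vapply(at_grid, `[[`, numeric(1), "value")
  se_fitted <- vapply(at_grid, function(g) {
    sqrt(sigma2 * sum(g$l^2 / w))
  }, numeric(1))
  structure(list(span = span, degree = degree, grid_x = grid_x,
                 fitted = fitted, se_fitted = se_fitted,
                 robustness_iters = robustness_iters,
                 fitted_at_x = pass$fitted_at_x, x = x, y = y, weights = w),
            class = "loess_fit")
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf("LOESS fit: span %.2f, degree %d, %d data points, %d grid points\n",
              x$span, x$degree, length(x$x), length(x$grid_x)))
  peak <- x$grid_x[which.max(x$fitted)]
  cat(sprintf("  curve maximum at x = %.2f (fitted %.2f)\n",
              peak, max(x$fitted)))
  invisible(x)
}
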