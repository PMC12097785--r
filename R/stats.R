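## Brain-behavior association statistics: Pearson and partial correlations
## with covariate adjustment, Benjamini-Hochberg FDR, the minimum detectable
## correlation from the Fisher-z power approximation, and an OLS wrapper for
## the supplemental multiple-regression analysis.

association_row_ <- function(predictor, outcome, r, n, n_cov,
                             covariates = character(0)) {
  df <- n - 2L - n_cov
  if (df < 1) stop("not enough observations for the covariate set")
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  data.frame(predictor = predictor, outcome = outcome, r = r, p = p,
             df = df, n = n,
             covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Pearson correlation with a two-sided p-value
#'
#' `t = r * sqrt((n-2)/(1-r^2))` against `t(n-2)`.
#'
#' @param x,y numeric vectors (finite, `n >= 4`).
#' @param predictor,outcome names carried into the result row.
#' @return one-row `data.frame`: predictor, outcome, r, p, df, n, covariates.
#' @export
pearson_with_p <- function(x, y, predictor = "x", outcome = "y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  association_row_(predictor, outcome, r, n, 0L)
}

covariate_design_ <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && !ncol(covariates)))
    return(matrix(1, n, 1))
  cv <- as.data.frame(covariates)
  for (j in seq_along(cv)) if (is.character(cv[[j]])) cv[[j]] <- factor(cv[[j]])
  M <- stats::model.matrix(~ ., data = cv)   # site -> k-1 indicator columns
  if (qr(M)$rank < ncol(M)) stop("rank-deficient covariate design")
  M
}

#' Partial correlation with covariate adjustment
#'
#' The Pearson correlation of the OLS residuals of `x` and `y` on the
#' covariates (plus intercept); categorical covariates are expanded into
#' indicator columns. Degrees of freedom are reduced by the number of
#' covariate columns. With no covariates this reduces exactly to
#' [pearson_with_p()].
#'
#' @param x,y numeric vectors.
#' @param covariates `data.frame` (or vector/matrix) of covariates; factors
#'   and character columns become indicators.
#' @inheritParams pearson_with_p
#' @return one-row `data.frame` as in [pearson_with_p()].
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                predictor = "x", outcome = "y") {
  n <- length(x)
  M <- covariate_design_(covariates, n)
  if (ncol(M) == 1) {
    out <- pearson_with_p(x, y, predictor, outcome)
    return(out)
  }
  rx <- stats::lm.fit(M, x)$residuals
  ry <- stats::lm.fit(M, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero residual variance after covariate adjustment")
  r <- stats::cor(rx, ry)
  cn <- setdiff(colnames(M), "(Intercept)")
  association_row_(predictor, outcome, r, n, length(cn), cn)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values (monotone by construction) and the rejection
#' set at level `alpha`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list: `q` (adjusted values), `reject` (logical), `alpha`.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha, alpha = alpha)
}

#' Minimum detectable correlation (Fisher-z approximation)
#'
#' Solves `atanh(rho) * sqrt(n - 3) = z_{1-alpha/2} + z_{power}` for the
#' smallest correlation magnitude detectable with the target power;
#' monotone decreasing in `n`.
#'
#' @param n sample size (`>= 5`).
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.80).
#' @param two_sided two-sided test (default TRUE).
#' @return the minimum detectable `|rho|`.
#' @export
min_detectable_r <- function(n, alpha = 0.05, power = 0.80,
                             two_sided = TRUE) {
  if (n < 5) stop("need n >= 5")
  if (power <= alpha / 2 || power >= 1) stop("power unreachable for these settings")
  za <- stats::qnorm(1 - if (two_sided) alpha / 2 else alpha)
  zb <- stats::qnorm(power)
  tanh((za + zb) / sqrt(n - 3))
}

#' Ordinary least squares regression
#'
#' Thin wrapper returning the coefficient table (estimate, SE, t, p) and
#' R-squared. An intercept is always included.
#'
#' @param y response vector.
#' @param X predictor `data.frame`/matrix (no intercept column).
#' @return list: `coefficients` (`data.frame`), `r_squared`, `fit` (the
#'   underlying `lm` object).
#' @export
ols_regression <- function(y, X = NULL) {
  if (is.null(X)) {
    fit <- stats::lm(y ~ 1)
  } else {
    d <- as.data.frame(X)
    if (qr(stats::model.matrix(~ ., data = d))$rank < ncol(stats::model.matrix(~ ., data = d)))
      stop("rank-deficient design")
    d$.y <- y
    fit <- stats::lm(.y ~ ., data = d)
  }
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  list(coefficients = co, r_squared = sm$r.squared, fit = fit)
}

#' Batch association analysis with FDR correction
#'
#' Computes (partial) correlations for every predictor-outcome pair in one
#' FDR family and appends BH q-values and rejections.
#'
#' @param data `data.frame` holding predictors, outcomes and covariates.
#' @param predictors,outcomes column names.
#' @param covariates covariate column names (NULL for plain Pearson).
#' @param alpha FDR level (default 0.05).
#' @return `data.frame` of association rows with `q` and `significant`.
#' @export
associate <- function(data, predictors, outcomes, covariates = NULL,
                      alpha = 0.05) {
  cv <- if (length(covariates)) data[, covariates, drop = FALSE] else NULL
  rows <- list()
  for (pr in predictors) for (oc in outcomes)
    rows[[paste(pr, oc)]] <- partial_correlation(
      data[[pr]], data[[oc]], cv, predictor = pr, outcome = oc)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  adj <- fdr_bh(out$p, alpha = alpha)
  out$q <- adj$q
  out$significant <- adj$reject
  out
}
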