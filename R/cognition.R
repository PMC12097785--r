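## Cognitive-domain derivation: Horn's parallel analysis for factor
## retention, principal-axis exploratory factor analysis, varimax rotation,
## Thurstone regression-method factor scores, and the overall-cognition
## composite (the average of the five domain scores).

#' Horn's parallel analysis
#'
#' Counts how many leading eigenvalues of the observed correlation matrix
#' exceed the chosen quantile of the rank-matched eigenvalues from `n_iter`
#' random normal datasets of the same shape. Counting is consecutive from
#' the first eigenvalue.
#'
#' @param data subjects x tests numeric matrix/data.frame (complete cases).
#' @param n_iter number of random datasets (default 1000).
#' @param quantile null quantile compared against (default 0.95).
#' @param seed optional seed for the null datasets.
#' @return suggested number of factors (integer). Attributes `observed` and
#'   `threshold` carry the two eigenvalue profiles.
#' @export
parallel_analysis <- function(data, n_iter = 1000, quantile = 0.95,
                              seed = NULL) {
  X <- as.matrix(data)
  if (anyNA(X)) stop("parallel_analysis requires complete cases")
  n <- nrow(X); p <- ncol(X)
  if (n < p) warning("fewer subjects than tests; eigen spectrum is rank-deficient")
  obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  null_eigs <- with_seed_(seed, {
    t(vapply(seq_len(n_iter), function(i) {
      R <- stats::cor(matrix(stats::rnorm(n * p), n, p))
      eigen(R, symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p)))
  })
  thr <- apply(null_eigs, 2, stats::quantile, probs = quantile, names = FALSE)
  above <- obs > thr
  k <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  structure(as.integer(k), observed = obs, threshold = thr)
}

## squared multiple correlations as starting communalities
smc_ <- function(R) {
  Ri <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-8, nrow(R))))
  pmin(pmax(1 - 1 / diag(Ri), 0), 1)
}

#' Principal-axis exploratory factor analysis
#'
#' Iterated principal-axis factoring: starting from squared-multiple-
#' correlation communalities, repeatedly eigendecomposes the reduced
#' correlation matrix (communalities on the diagonal) until the
#' communalities stabilize. Heywood cases (communality > 1) are clipped to 1
#' with a warning. Standardization is internal; supplying `R` directly
#' factors a known correlation matrix.
#'
#' @param data subjects x tests matrix (ignored if `R` given).
#' @param n_factors number of factors (default 5).
#' @param R optional tests x tests correlation matrix.
#' @param max_iter,tol iteration control.
#' @return list of class `factor_model`: `loadings` (unrotated),
#'   `communalities`, `uniquenesses`, `rotation`, `eigenvalues` (of `R`),
#'   `n_factors`, `R`, `rmsr`, `converged`.
#' @export
efa_fit <- function(data = NULL, n_factors = 5, R = NULL,
                    max_iter = 200, tol = 1e-8) {
  if (is.null(R)) {
    X <- as.matrix(data)
    X <- X[stats::complete.cases(X), , drop = FALSE]
    R <- stats::cor(X)
  }
  p <- ncol(R)
  if (n_factors < 1 || n_factors >= p) stop("need 1 <= n_factors < n_tests")
  vnames <- colnames(R)
  h2 <- smc_(R)
  conv <- FALSE
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(lam), n_factors)
    h2new <- rowSums(L^2)
    if (any(h2new > 1)) {
      warning("Heywood case: communality > 1 clipped to 1")
      h2new <- pmin(h2new, 1)
    }
    if (max(abs(h2new - h2)) < tol) { h2 <- h2new; conv <- TRUE; break }
    h2 <- h2new
  }
  rownames(L) <- vnames
  colnames(L) <- paste0("F", seq_len(n_factors))
  resid <- R - (L %*% t(L) + diag(1 - h2, p))
  rmsr <- sqrt(mean(resid[upper.tri(resid)]^2))
  structure(list(loadings = L, communalities = h2,
                 uniquenesses = 1 - h2, rotation = "none",
                 eigenvalues = eigen(R, symmetric = TRUE,
                                     only.values = TRUE)$values,
                 n_factors = as.integer(n_factors), R = R, rmsr = rmsr,
                 converged = conv),
            class = "factor_model")
}

## flip column signs so the largest-magnitude loading is positive, and order
## columns by decreasing sum of squared loadings
canonicalize_loadings_ <- function(L) {
  sgn <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  sgn[sgn == 0] <- 1
  L <- sweep(L, 2, sgn, `*`)
  L[, order(colSums(L^2), decreasing = TRUE), drop = FALSE]
}

#' Varimax rotation
#'
#' Kaiser-normalized orthogonal varimax ([stats::varimax()]); communalities
#' are preserved. Column signs are fixed so each factor's largest-magnitude
#' loading is positive and columns are ordered by decreasing sum of squared
#' loadings.
#'
#' @param model a `factor_model` from [efa_fit()], or a plain loading matrix.
#' @return rotated object of the same kind.
#' @export
varimax_rotate <- function(model) {
  L <- if (inherits(model, "factor_model")) model$loadings else as.matrix(model)
  if (ncol(L) < 2) stop("varimax needs >= 2 factors")
  rot <- stats::varimax(L, normalize = TRUE)
  Lr <- canonicalize_loadings_(L %*% rot$rotmat)
  if (!inherits(model, "factor_model")) return(Lr)
  model$loadings <- Lr
  model$rotation <- "varimax"
  model
}

#' Regression-method (Thurstone) factor scores
#'
#' `scores = Z %*% solve(R) %*% Lambda` on the standardized data; score
#' column means are zero by construction. A singular correlation matrix is
#' ridge-regularized with a warning.
#'
#' @param data subjects x tests matrix on the model's variable set.
#' @param model a `factor_model` (rotated or not).
#' @return subjects x factors score matrix.
#' @export
factor_scores_regression <- function(data, model) {
  X <- as.matrix(data)
  if (!is.null(rownames(model$loadings)) && !is.null(colnames(X))) {
    if (!all(rownames(model$loadings) %in% colnames(X)))
      stop("data columns do not match the model's variable set")
    X <- X[, rownames(model$loadings), drop = FALSE]
  }
  Z <- scale(X)
  W <- tryCatch(solve(model$R, model$loadings), error = function(e) {
    warning("singular correlation matrix; ridge-regularizing")
    solve(model$R + diag(1e-6, ncol(model$R)), model$loadings)
  })
  S <- Z %*% W
  colnames(S) <- colnames(model$loadings)
  S
}

#' Overall cognition composite
#'
#' The per-subject average of the five factor scores. Missing scores are an
#' error: the composite is never averaged over fewer factors.
#'
#' @param scores subjects x 5 factor-score matrix.
#' @return numeric vector of per-subject composites.
#' @export
overall_cognition <- function(scores) {
  S <- as.matrix(scores)
  if (ncol(S) != 5) stop("overall cognition expects exactly 5 factor scores")
  if (anyNA(S)) stop("missing factor score; refusing to average over fewer factors")
  rowMeans(S)
}

#' Simple imputation hook for the test battery
#'
#' Complete-case analysis is the default elsewhere; this optional hook
#' fills missing test scores with the column mean.
#'
#' @param data subjects x tests matrix.
#' @param method `"none"` (drop incomplete rows) or `"mean"`.
#' @return completed matrix.
#' @export
impute_tests <- function(data, method = c("none", "mean")) {
  method <- match.arg(method)
  X <- as.matrix(data)
  if (method == "none") return(X[stats::complete.cases(X), , drop = FALSE])
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[!miss, j])
  }
  X
}

#' Fit the full cognition stage
#'
#' EFA (principal axis) + varimax + regression scores + overall composite,
#' with factors labeled by the domain of their highest-loading test when the
#' test names carry domain prefixes (as the synthetic battery does).
#'
#' @param tests subjects x tests data (a `data.frame` with a `subject_id`
#'   column, or a plain matrix).
#' @param n_factors number of factors (default 5).
#' @return list: `model` (rotated `factor_model`), `scores`,
#'   `overall` (vector), `table` (`data.frame` with subject ids, factor
#'   scores and `overall_cognition`).
#' @export
fit_cognition <- function(tests, n_factors = 5) {
  if (is.data.frame(tests) && "subject_id" %in% names(tests)) {
    ids <- tests$subject_id
    X <- as.matrix(tests[, setdiff(names(tests), "subject_id")])
  } else {
    X <- as.matrix(tests)
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("subj_%03d", seq_len(nrow(X)))
  }
  model <- varimax_rotate(efa_fit(X, n_factors = n_factors))
  # label factors by the domain prefix of their top-loading test
  top <- rownames(model$loadings)[apply(abs(model$loadings), 2, which.max)]
  lab <- sub("_[0-9]+$", "", top)
  if (!anyDuplicated(lab)) colnames(model$loadings) <- lab
  scores <- factor_scores_regression(X, model)
  overall <- if (ncol(scores) == 5) overall_cognition(scores) else rowMeans(scores)
  tab <- data.frame(subject_id = ids, scores, overall_cognition = overall,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(tab) <- NULL
  list(model = model, scores = scores, overall = overall, table = tab)
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise Tucker phi after optimally matching columns (all
#' permutations; intended for small factor counts) and resolving signs.
#'
#' @param A,B tests x factors loading matrices with equal dimensions.
#' @return per-factor congruence (of B's columns matched to A's), in the
#'   matched order of A's columns.
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)))
  k <- ncol(A)
  phi <- abs(crossprod(A, B) /
               sqrt(colSums(A^2) %o% colSums(B^2)))
  perms <- permutations_(k)
  best <- NULL; best_val <- -Inf
  for (i in seq_len(nrow(perms))) {
    v <- phi[cbind(seq_len(k), perms[i, ])]
    if (sum(v) > best_val) { best_val <- sum(v); best <- v }
  }
  best
}

permutations_ <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- matrix(seq_len(k)[-i][sub], nrow(sub), k - 1)
    out <- rbind(out, cbind(i, rest))
  }
  out
}
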