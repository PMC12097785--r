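test_that("pearson_with_p matches the t-formula and its limits", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(pearson_with_p(x, x)$r, 1)

  # exactly orthogonal construction: r = 0, p = 1
  y <- rnorm(50)
  y <- as.numeric(residuals(lm(y ~ x)))
  res0 <- pearson_with_p(x, y)
  expect_equal(res0$r, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-10)

  # agrees with cor.test on arbitrary data
  z <- rnorm(50) + 0.4 * x
  mine <- pearson_with_p(x, z)
  ct <- cor.test(x, z)
  expect_equal(mine$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ct$p.value, tolerance = 1e-12)
  expect_equal(mine$df, unname(ct$parameter))

  expect_error(pearson_with_p(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_with_p(1:3, 3:1), "n >= 4")
})

test_that("the t-formula reproduces the published r/p pairing at n = 146", {
  # published headline: r = 0.233 with p printed as 0.004 at n = 146
  n <- 146; r <- 0.233
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t), n - 2)
  expect_lt(abs(p - 0.004), 0.001)
  # and the weakest reported significant metric: r = 0.164 -> p = 0.048
  r2 <- 0.164
  p2 <- 2 * pt(-abs(r2 * sqrt((n - 2) / (1 - r2^2))), n - 2)
  expect_equal(round(p2, 3), 0.048)
})

test_that("partial correlation reduces, matches the recursion, kills confounds", {
  set.seed(2)
  x <- rnorm(200); y <- 0.3 * x + rnorm(200)

  # empty covariate set: identical to pearson_with_p
  plain <- pearson_with_p(x, y)
  part0 <- partial_correlation(x, y, NULL)
  expect_equal(part0$r, plain$r, tolerance = 1e-12)
  expect_equal(part0$p, plain$p, tolerance = 1e-12)

  # single-covariate recursion formula oracle
  c1 <- rnorm(200)
  xx <- x + 0.5 * c1; yy <- y + 0.7 * c1
  pc <- partial_correlation(xx, yy, data.frame(c = c1))
  rxy <- cor(xx, yy); rxc <- cor(xx, c1); ryc <- cor(yy, c1)
  oracle <- (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2))
  expect_equal(pc$r, oracle, tolerance = 1e-10)
  expect_equal(pc$df, 200 - 3)

  # planted shared confound: marginal r > 0, partial r ~ 0
  set.seed(3)
  n <- 1000
  cf <- rnorm(n)
  x2 <- cf + rnorm(n); y2 <- cf + rnorm(n)
  expect_gt(pearson_with_p(x2, y2)$r, 0.3)
  expect_lt(abs(partial_correlation(x2, y2, data.frame(cf))$r),
            3 / sqrt(n))

  # categorical covariates expand to k-1 indicators and df drops accordingly
  site <- sample(LETTERS[1:4], 200, replace = TRUE)
  psite <- partial_correlation(x, y, data.frame(site = site,
                                                ct = rnorm(200)))
  expect_equal(psite$df, 200 - 2 - 4)

  expect_error(partial_correlation(x, y, data.frame(a = c1, b = 2 * c1)),
               "rank")
})

test_that("BH correction follows the step-up rule", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(out$reject))          # p(i) <= i * 0.05 / 4 for all i
  expect_equal(out$q, c(0.04, 0.04, 0.04, 0.04))

  null <- fdr_bh(rep(1, 5))
  expect_false(any(null$reject))
  expect_equal(null$q, rep(1, 5))

  expect_equal(fdr_bh(0.03)$q, 0.03)    # m = 1: q = p
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # q is monotone in p
  p <- c(0.001, 0.3, 0.04, 0.9, 0.02)
  q <- fdr_bh(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("minimum detectable correlation matches power claims", {
  # the published a priori power analysis: n = 146 -> 0.23 at two decimals
  expect_equal(round(min_detectable_r(146, 0.05, 0.80), 2), 0.23)
  # monotone decreasing in n, vanishing for very large samples
  ns <- c(20, 50, 146, 500, 10000)
  vals <- vapply(ns, min_detectable_r, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 0.03)

  # at power 0.5 the formula's rho gives ~50% rejection in a Monte-Carlo
  # power oracle (t-test on draws from the bivariate normal)
  n <- 200
  rho <- min_detectable_r(n, 0.05, 0.5)
  set.seed(42)
  reps <- 200000
  rej <- 0
  for (chunk in 1:10) {
    X <- matrix(rnorm(n * (reps / 10)), n)
    Y <- rho * X + sqrt(1 - rho^2) * matrix(rnorm(n * (reps / 10)), n)
    cx <- X - rep(colMeans(X), each = n)
    cy <- Y - rep(colMeans(Y), each = n)
    r <- colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    rej <- rej + sum(abs(t) > qt(0.975, n - 2))
  }
  expect_lt(abs(rej / reps - 0.5), 0.005)

  expect_error(min_detectable_r(3), "n >= 5")
  expect_error(min_detectable_r(100, power = 1), "unreachable")
})

test_that("OLS matches the normal equations and the correlation t-test", {
  set.seed(5)
  x <- rnorm(60)
  y_exact <- 2 + 3 * x
  fit_exact <- suppressWarnings(ols_regression(y_exact, data.frame(x)))
  expect_equal(fit_exact$r_squared, 1)

  y <- rnorm(60)
  expect_equal(ols_regression(y)$coefficients$estimate, mean(y))

  # random fixture vs explicit normal-equations solve
  X <- matrix(rnorm(180), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  yy <- X %*% c(1, -2, 0.5) + rnorm(60)
  fit <- ols_regression(as.numeric(yy), as.data.frame(X))
  M <- cbind(1, X)
  beta <- solve(t(M) %*% M, t(M) %*% yy)
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)

  # single standardized predictor: coefficient p equals correlation p
  xs <- as.numeric(scale(x))
  fit1 <- ols_regression(y, data.frame(xs))
  expect_equal(fit1$coefficients$p[2], pearson_with_p(xs, y)$p,
               tolerance = 1e-10)

  expect_error(ols_regression(y, data.frame(a = x, b = 2 * x)), "rank")
})

test_that("associate applies one FDR family across all pairs", {
  set.seed(6)
  d <- data.frame(s1 = rnorm(80), s2 = rnorm(80))
  d$cog <- 0.5 * d$s1 + rnorm(80)
  d$site <- sample(c("A", "B"), 80, replace = TRUE)
  out <- associate(d, c("s1", "s2"), "cog", covariates = "site")
  expect_equal(nrow(out), 2)
  expect_equal(out$q, fdr_bh(out$p)$q)
  expect_true(all(out$q >= out$p - 1e-15))
  expect_true(all(out$covariates == "siteB"))
})
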