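test_that("standardized OLS reduces to Pearson r for one predictor", {
  set.seed(1)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  fit <- fitStandardizedOls(y, cbind(amp = x))
  tab <- coefTable(fit)
  expect_equal(tab$beta, cor(x, y), tolerance = 1e-12)
  expect_equal(tab$partial_r, cor(x, y), tolerance = 1e-12)
})

test_that("partial correlations equal marginal ones for orthogonal designs", {
  # exactly orthogonal predictors by QR
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(120), 40, 3)))
  colnames(Q) <- c("a", "b", "c")
  y <- 0.8 * Q[, 1] - 0.5 * Q[, 2] + rnorm(40, 0, 0.3)
  fit <- fitStandardizedOls(y, Q)
  tab <- coefTable(fit)
  ys <- zscore(y)
  for (j in 1:3) {
    marg <- cor(ys, zscore(Q[, j]))
    # residualization on orthogonal others changes x_j only in scale
    expect_equal(sign(tab$partial_r[j]), sign(marg))
    expect_equal(abs(tab$partial_r[j]) >= abs(marg) - 1e-9, TRUE)
  }
  # exact linear response: |r| = 1 and residuals vanish
  yy <- 2 * Q[, 1] - Q[, 2] + 0.5 * Q[, 3]
  fit2 <- suppressWarnings(fitStandardizedOls(yy, Q))  # exact fit by design
  expect_true(all(abs(coefTable(fit2)$partial_r) > 1 - 1e-6))
  expect_lt(max(abs(fit2@residuals)), 1e-10)
})

test_that("standardized beta and partial r share sign; affine rescaling is absorbed", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  colnames(X) <- paste0("x", 1:4)
  y <- X %*% c(0.5, -0.3, 0.2, 0) + rnorm(50)
  f1 <- fitStandardizedOls(y, X)
  tab <- coefTable(f1)
  expect_true(all(sign(tab$beta) == sign(tab$partial_r)))
  X2 <- sweep(sweep(X, 2, c(2, 30, 0.1, 5), "*"), 2, c(1, -7, 0, 100), "+")
  f2 <- fitStandardizedOls(y, X2)
  expect_equal(coefTable(f2)$beta, tab$beta, tolerance = 1e-9)
  expect_equal(coefTable(f2)$partial_r, tab$partial_r, tolerance = 1e-9)
})

test_that("degenerate regression inputs raise explicit errors", {
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3); colnames(X) <- c("a", "b", "c")
  y <- rnorm(10)
  expect_error(fitStandardizedOls(y[1:4], X[1:4, ]), "too few")
  Xd <- cbind(X, d = X[, 1])
  expect_error(fitStandardizedOls(y, Xd), "rank")
  expect_error(vif(Xd), "collinearity")
})

test_that("no-intercept summation regression equals the closed form", {
  x <- c(1, 2, 3, 4, 6)
  suppressWarnings({  # exact fits by design
    expect_equal(coefTable(fitSummationRegression(0.653 * x, x))$beta, 0.653)
    expect_equal(coefTable(fitSummationRegression(x, x))$beta, 1)
  })
  set.seed(5)
  xs <- runif(60, 1, 10)
  ys <- 0.7 * xs + abs(rnorm(60, 0, 0.3))
  fit <- fitSummationRegression(ys, xs)
  expect_equal(coefTable(fit)$beta, sum(xs * ys) / sum(xs^2),
               tolerance = 1e-12)
  expect_error(fitSummationRegression(c(1, 2, 3), rep(0, 3)), "zero")
  expect_error(fitSummationRegression(c(-1, 1, 2), c(1, 2, 3)),
               "non-negative")
})

test_that("mixed model matches pooled OLS when groups do not differ", {
  set.seed(6)
  n <- 120
  g <- rep(c("a", "b", "c"), length.out = n)
  x <- rnorm(n); e <- rnorm(n)
  # remove all between-group structure so the random-intercept variance is
  # exactly zero and the mixed fit collapses onto pooled least squares
  x <- x - ave(x, g); e <- e - ave(e, g)
  y <- 0.5 * x + e
  fit <- fitMixedModel(y, cbind(slope = x), g)
  pooled <- lm(y ~ zscore(x))
  expect_equal(coefTable(fit)$beta, unname(coef(pooled)[2]),
               tolerance = 1e-3)
  expect_true(fit@converged)
})

test_that("mixed model recovers a known slope with random intercepts", {
  set.seed(7)
  n <- 300
  g <- rep(1:6, each = 50)
  u <- rnorm(6, 0, 1)[g]
  x <- rnorm(n)
  y <- 0.5 * x + u + rnorm(n, 0, 0.5)
  fit <- fitMixedModel(y, cbind(slope = x), g)
  tab <- coefTable(fit)
  # beta is per SD of x; with sd(x) ~ 1 the recovered slope should cover 0.5
  se <- abs(tab$beta / qnorm(tab$p_value / 2, lower.tail = FALSE))
  expect_gt(0.5, tab$beta - 2.1 * se)
  expect_lt(0.5, tab$beta + 2.1 * se)
})

test_that("per-group shifts of the response leave mixed-model slopes unchanged", {
  set.seed(8)
  x <- rnorm(90); g <- rep(c("a", "b", "c"), each = 30)
  y <- 0.4 * x + rnorm(90, 0, 0.2)
  y2 <- y + c(a = 0, b = 5, c = -3)[g]
  f1 <- fitMixedModel(y, cbind(slope = x), g)
  f2 <- fitMixedModel(y2, cbind(slope = x), g)
  expect_equal(coefTable(f2)$beta, coefTable(f1)$beta, tolerance = 1e-2)
})

test_that("Bonferroni correction caps at one and is identity for m = 1", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_equal(bonferroni(0.123, 1), 0.123)
  expect_error(bonferroni(1.2), "0, 1")
})

test_that("variance inflation factors match the R-squared identity", {
  set.seed(9)
  # orthogonal to each other and to the intercept
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(200), 50, 4))))[, -1]
  colnames(Q) <- paste0("q", 1:4)
  expect_equal(unname(vif(Q)), rep(1, 4), tolerance = 1e-9)
  Z <- matrix(rnorm(150), 50, 3)
  X <- cbind(a = Z[, 1], b = Z[, 1] * 0.8 + Z[, 2] * 0.6, c = Z[, 3])
  v <- vif(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-9)
  }
  expect_true(all(v >= 1))
})

test_that("Welch t from summaries follows the pooled-SEM formula", {
  expect_equal(welchTFromSummary(5, 1, 5, 2), 0)
  set.seed(10)
  for (rep in 1:10) {
    m <- rnorm(2, 0, 5); s <- runif(2, 0.5, 3)
    expect_equal(welchTFromSummary(m[1], s[1], m[2], s[2]),
                 (m[1] - m[2]) / sqrt(s[1]^2 + s[2]^2))
  }
  expect_error(welchTFromSummary(1, 0, 2, 0), "positive")
})

test_that("model comparison bands follow the stated thresholds", {
  set.seed(11)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  fit <- fitStandardizedOls(y, cbind(x = x))
  same <- compareModels(fit, fit)
  expect_equal(same@deltaAIC, 0)
  expect_equal(same@evidenceAIC, "both supported")
  # adding a pure-noise predictor on null data can lower the AIC by at most
  # the 2-unit parameter penalty; over seeds the mean penalty is positive
  deltas <- replicate(40, {
    yn <- rnorm(60)
    z <- rnorm(60)
    fa <- fitStandardizedOls(yn, cbind(x = x))
    fb <- fitStandardizedOls(yn, cbind(x = x, z = z))
    fb@aic - fa@aic  # signed: B minus A
  })
  expect_true(all(deltas <= 2 + 1e-9))
  expect_gt(mean(deltas), 0)
  # bands: construct fits with known AIC/BIC gaps
  fA <- fit; fB <- fit
  fB@aic <- fit@aic + 4; fB@bic <- fit@bic + 4
  cmp <- compareModels(fA, fB)
  expect_equal(cmp@evidenceAIC, "some evidence")
  expect_equal(cmp@evidenceAIC, "some evidence")
  fB@aic <- fit@aic + 8; fB@bic <- fit@bic + 6.5
  cmp2 <- compareModels(fA, fB)
  expect_equal(cmp2@evidenceAIC, "strong evidence")
  expect_equal(cmp2@evidenceBIC, "strong evidence")
  expect_equal(cmp2@winnerAIC, "A")
  fitShort <- fitStandardizedOls(y[1:30], cbind(x = x[1:30]))
  expect_error(compareModels(fit, fitShort), "different numbers")
})

test_that("information criteria favor true predictors, BIC more sternly", {
  set.seed(12)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.4 * x1 + rnorm(n)
  f1 <- fitStandardizedOls(y, cbind(x1 = x1))
  f2 <- fitStandardizedOls(y, cbind(x1 = x1, x2 = x2))
  f0 <- fitStandardizedOls(y, cbind(x2 = x2))
  expect_lt(f1@aic, f0@aic)   # true predictor helps
  expect_lt(f1@bic, f0@bic)
  # BIC penalizes the superfluous predictor harder than AIC
  expect_gt((f2@bic - f1@bic) - (f2@aic - f1@aic), 0)
})

test_that("regression p-values hold their nominal type-I error", {
  set.seed(13)
  hits <- replicate(1000, {
    x <- rnorm(30); y <- rnorm(30)
    coefTable(fitStandardizedOls(y, cbind(x = x)))$p_value < 0.05
  })
  expect_equal(mean(hits), 0.05, tolerance = 0.4)  # i.e. within +-0.02
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("the Q-Q normality index separates normal from skewed residuals", {
  set.seed(14)
  rn <- qqNormality(rnorm(500))
  expect_gt(rn, 0.995)
  re <- qqNormality(rexp(500))
  expect_lt(re, rn)
  expect_error(qqNormality(rep(1, 20)), "constant")
  expect_error(qqNormality(rnorm(5)), "at least 10")
})
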