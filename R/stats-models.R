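#' @include AllClasses.R AllGenerics.R preprocessing.R
NULL

.asPredictorMatrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

.newFit <- function(method, formula, n, coefs, aic, bic, vif = numeric(0),
                    residuals = numeric(0), converged = TRUE) {
  new("PhosFit", method = method, formula = formula, n = as.integer(n),
      coefficients = coefs, aic = aic, bic = bic, vif = vif,
      residuals = residuals, converged = converged)
}

#' Bonferroni correction
#'
#' Adjusts p-values for multiple comparisons: \eqn{min(1, p m)}.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param m number of comparisons in the family. Defaults to the number of
#'   p-values supplied.
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R^2_j)} from regressing predictor j on the others
#' (with intercept). Used to verify that the multiple-regression predictors
#' carry minimal multicollinearity.
#'
#' @param X predictor matrix or data.frame (>= 2 columns).
#' @return Named vector of VIFs.
#' @export
vif <- function(X) {
  X <- .asPredictorMatrix(X)
  p <- ncol(X)
  if (p < 2) return(setNames(rep(1, p), colnames(X)))
  out <- vapply(seq_len(p), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- 1 - sum(resid(fit)^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-10)
      stop("perfect collinearity: VIF is infinite for ", colnames(X)[j])
    1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(X))
}

# Partial correlation of y with each predictor, by residualization: correlate
# the residuals of y and of X_j after regressing each on the remaining
# predictors (equivalently the t-statistic transform r = t/sqrt(t^2 + df)).
.partialR <- function(y, X) {
  p <- ncol(X)
  if (p == 1) return(cor(y, X[, 1]))
  vapply(seq_len(p), function(j) {
    others <- X[, -j, drop = FALSE]
    ry <- resid(lm(y ~ others))
    rx <- resid(lm(X[, j] ~ others))
    cor(ry, rx)
  }, numeric(1))
}

#' Standardized multiple regression with partial correlations
#'
#' Fits ordinary least squares on the z-scored response and z-scored
#' predictors, so the coefficients are standardized regression weights
#' (\eqn{\beta}), and reports for each predictor the partial correlation
#' (residualization convention), the two-sided p-value and its Bonferroni
#' adjustment. This is the within-participant analysis of the battery.
#'
#' @param y response vector.
#' @param X predictor matrix or data.frame (already-standardized predictors
#'   are fine: z-scoring is idempotent up to affine rescaling).
#' @param intercept include an intercept (default TRUE; it is ~0 after
#'   standardization and is not reported).
#' @param bonferroniM size of the comparison family for the adjusted
#'   p-values. Defaults to the number of predictors.
#' @return A [PhosFit-class].
#' @examples
#' set.seed(1)
#' x <- rnorm(30); y <- 0.5 * x + rnorm(30)
#' fit <- fitStandardizedOls(y, cbind(amp = x))
#' coefTable(fit)  # beta equals the Pearson correlation for one predictor
#' @export
fitStandardizedOls <- function(y, X, intercept = TRUE, bonferroniM = NULL) {
  X <- .asPredictorMatrix(X)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("y and X have different lengths")
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  if (n <= p + 1)
    stop("too few observations: need n > p + 1 (n = ", n, ", p = ", p, ")")
  if (qr(cbind(1, X))$rank < p + 1)
    stop("rank-deficient predictor matrix (collinear or constant predictor)")
  ys <- zscore(y)
  Xs <- apply(X, 2, zscore)
  fit <- if (intercept) lm(ys ~ Xs) else lm(ys ~ 0 + Xs)
  sm <- summary(fit)$coefficients
  rows <- if (intercept) seq_len(p) + 1L else seq_len(p)
  pv <- sm[rows, 4]
  m <- if (is.null(bonferroniM)) p else bonferroniM
  coefs <- data.frame(term = colnames(X), beta = unname(sm[rows, 1]),
                      partial_r = .partialR(ys, Xs),
                      p_value = unname(pv),
                      p_bonferroni = unname(bonferroni(pv, m)))
  .newFit("ols", paste0("z(y) ~ ", paste(colnames(X), collapse = " + ")),
          n, coefs, AIC(fit), BIC(fit),
          vif = if (p > 1) vif(X) else numeric(0),
          residuals = unname(resid(fit)))
}

#' No-intercept summation regression
#'
#' Regresses a paired-electrode shape descriptor on the sum of the two
#' corresponding single-electrode descriptors, without an intercept (a zero
#' predictor must imply a zero percept): \eqn{\beta = \sum xy / \sum x^2}.
#' A slope strictly between 0.5 and 1 means paired percepts are larger than
#' the average, but smaller than the sum, of their single-electrode
#' counterparts, which is the linear-summation signature.
#'
#' @param y paired-electrode descriptor values (non-negative).
#' @param x sum-of-singles descriptor values (non-negative, not all zero).
#' @return A [PhosFit-class]; the \code{coefficients} table has one row with
#'   the slope, the Pearson correlation as \code{partial_r}, and its p-value.
#' @export
fitSummationRegression <- function(y, x) {
  if (length(y) != length(x)) stop("x and y must have equal length")
  if (length(y) < 3) stop("need at least 3 observations")
  if (any(x < 0) || any(y < 0)) stop("descriptor values must be non-negative")
  if (all(x == 0)) stop("predictor is identically zero")
  fit <- lm(y ~ 0 + x)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = "sum_of_singles", beta = unname(sm[1, 1]),
                      partial_r = cor(x, y), p_value = unname(sm[1, 4]),
                      p_bonferroni = unname(sm[1, 4]))
  out <- .newFit("summation", "y ~ 0 + sum_of_singles", length(y), coefs,
                 AIC(fit), BIC(fit), residuals = unname(resid(fit)))
  out
}

#' Linear mixed-effects model with a participant random intercept
#'
#' The across-participant analysis: fixed effects for the (z-scored) stimulus
#' and neuroanatomical predictors, a random intercept per group
#' (participant). Fitted by REML via lme4; p-values use Satterthwaite degrees
#' of freedom, and the per-predictor partial correlation is obtained from the
#' t statistic, \eqn{r = t / \sqrt{t^2 + df}}. AIC/BIC are computed from the
#' maximum-likelihood refit so fixed-effect structures are comparable across
#' models.
#'
#' @param y response vector.
#' @param X predictor matrix or data.frame.
#' @param group grouping factor (>= 2 levels).
#' @param REML fit criterion for the reported estimates. Default TRUE.
#'   Singular fits (zero estimated between-group variance) are legitimate
#'   and reduce to pooled least squares.
#' @param bonferroniM comparison-family size. Defaults to the number of
#'   predictors.
#' @return A [PhosFit-class]; an error with optimizer diagnostics is raised
#'   if the fit does not converge.
#' @export
fitMixedModel <- function(y, X, group, REML = TRUE, bonferroniM = NULL) {
  X <- .asPredictorMatrix(X)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("need at least 2 groups for a mixed model")
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  # predictors are standardized; the response keeps its scale so that
  # per-group shifts are absorbed by the random intercepts and leave the
  # slopes unchanged
  dat <- data.frame(.y = y, apply(X, 2, zscore), .g = group)
  terms <- colnames(X)
  fml <- as.formula(paste(".y ~", paste(terms, collapse = " + "),
                          "+ (1 | .g)"))
  fit <- suppressMessages(lmerTest::lmer(fml, data = dat, REML = REML))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (any(grepl("failed to converge", msgs)))
    stop("mixed model did not converge: ", paste(msgs, collapse = "; "))
  sm <- summary(fit)$coefficients
  rows <- match(terms, rownames(sm))
  tval <- sm[rows, "t value"]
  dfree <- sm[rows, "df"]
  pv <- sm[rows, "Pr(>|t|)"]
  m <- if (is.null(bonferroniM)) length(terms) else bonferroniM
  coefs <- data.frame(term = terms, beta = unname(sm[rows, "Estimate"]),
                      partial_r = unname(tval / sqrt(tval^2 + dfree)),
                      p_value = unname(pv),
                      p_bonferroni = unname(bonferroni(pv, m)))
  ml <- lme4::refitML(fit)
  .newFit("mixed",
          paste0("y ~ ", paste(terms, collapse = " + "), " + (1 | group)"),
          length(y), coefs, AIC(ml), BIC(ml),
          vif = if (length(terms) > 1) vif(X) else numeric(0),
          residuals = unname(resid(fit)))
}

#' Welch's t statistic from summary statistics
#'
#' Compares two group means given only their means and standard errors:
#' \eqn{t = (m_1 - m_2) / \sqrt{sem_1^2 + sem_2^2}}. Used to compare stimulus
#' and neuroanatomical parameters (e.g. electrode-fovea distances) across
#' participants when only summary tables are available.
#'
#' @param m1,m2 group means.
#' @param sem1,sem2 standard errors of the means (non-negative, not both 0).
#' @return The t statistic.
#' @examples
#' welchTFromSummary(2168.8, 227.4, 2136.2, 173.1)  # ~0.114
#' @export
welchTFromSummary <- function(m1, sem1, m2, sem2) {
  if (any(c(sem1, sem2) < 0)) stop("standard errors must be non-negative")
  if (all(sem1 == 0) && all(sem2 == 0))
    stop("at least one standard error must be positive")
  (m1 - m2) / sqrt(sem1^2 + sem2^2)
}

.evidenceBand <- function(delta, some, strong) {
  if (delta < 2) "both supported"
  else if (delta < strong) "some evidence"
  else "strong evidence"
}

#' Compare two models by AIC and BIC
#'
#' Computes the AIC and BIC differences between two fits of the same response
#' (e.g. phosphene number as a function of along-axon distance vs
#' between-axon distance, each plus the same additional factors) and applies
#' the conventional qualitative bands: a difference below 2 supports both
#' models; 2 <= dAIC < 7 (2 <= dBIC < 6) is some evidence, and dAIC >= 7
#' (dBIC >= 6) strong evidence, against the higher-scoring model.
#'
#' @param fitA,fitB [PhosFit-class] objects fitted to the same response
#'   (equal n is enforced).
#' @param labels model names. Default c("A", "B").
#' @return A [ModelComparison-class].
#' @export
compareModels <- function(fitA, fitB, labels = c("A", "B")) {
  stopifnot(is(fitA, "PhosFit"), is(fitB, "PhosFit"))
  if (fitA@n != fitB@n)
    stop("models were fitted to different numbers of observations")
  aic <- setNames(c(fitA@aic, fitB@aic), labels)
  bic <- setNames(c(fitA@bic, fitB@bic), labels)
  dA <- abs(diff(aic)); dB <- abs(diff(bic))
  new("ModelComparison", labels = labels, aic = aic, bic = bic,
      deltaAIC = unname(dA), deltaBIC = unname(dB),
      winnerAIC = labels[which.min(aic)], winnerBIC = labels[which.min(bic)],
      evidenceAIC = .evidenceBand(dA, 2, 7),
      evidenceBIC = .evidenceBand(dB, 2, 6))
}

#' Quantile-quantile normality index of residuals
#'
#' Correlation between the sorted residuals and the corresponding theoretical
#' normal quantiles; values near 1 indicate approximately normal residuals
#' (the numeric summary of a Q-Q plot).
#'
#' @param residuals numeric vector, n >= 10, non-constant.
#' @return The quantile-quantile correlation.
#' @export
qqNormality <- function(residuals) {
  n <- length(residuals)
  if (n < 10) stop("need at least 10 residuals")
  if (.popSd(residuals) == 0) stop("residuals are constant")
  cor(sort(residuals), qnorm(ppoints(n)))
}

#' Accessors for fitted models
#'
#' \code{coefTable()} returns the per-predictor table (beta, partial r,
#' p-values); \code{modelAIC()}/\code{modelBIC()} the information criteria.
#'
#' @param x a [PhosFit-class].
#' @rdname coefTable
#' @export
setMethod("coefTable", "PhosFit", function(x) x@coefficients)

#' @rdname coefTable
#' @export
setMethod("modelAIC", "PhosFit", function(x) x@aic)

#' @rdname coefTable
#' @export
setMethod("modelBIC", "PhosFit", function(x) x@bic)

setMethod("show", "PhosFit", function(object) {
  cat("PhosFit (", object@method, "): ", object@formula, "\n", sep = "")
  cat("  n =", object@n, " AIC =", round(object@aic, 3),
      " BIC =", round(object@bic, 3), "\n")
  tab <- object@coefficients
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  if (object@method == "summation") {
    b <- object@coefficients$beta[1]
    if (b > 0.5 && b < 1)
      cat("  slope in (0.5, 1): paired percepts larger than the average,",
          "smaller than the sum, of the singles\n")
  }
  if (length(object@vif))
    cat("  max VIF:", round(max(object@vif), 2), "\n")
})

setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison:", paste(object@labels, collapse = " vs "), "\n")
  cat("  AIC:", paste(sprintf("%s = %.3f", object@labels, object@aic),
                      collapse = ", "),
      " dAIC =", round(object@deltaAIC, 3), "->", object@evidenceAIC,
      "( favors", object@winnerAIC, ")\n")
  cat("  BIC:", paste(sprintf("%s = %.3f", object@labels, object@bic),
                      collapse = ", "),
      " dBIC =", round(object@deltaBIC, 3), "->", object@evidenceBIC,
      "( favors", object@winnerBIC, ")\n")
})
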