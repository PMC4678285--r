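#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. When the smaller sample
#' has at most 8 observations and the pooled data are tie-free, the exact
#' two-sided p-value is used (full permutation distribution of the U
#' statistic); otherwise the normal approximation with tie correction and
#' continuity correction is applied.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact p-value;
#'   `NULL` (default) selects automatically as described above.
#' @return A one-row data frame of class `"test_result"` with columns
#'   `statistic` (U for the first sample), `p`, `method`, `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- min(length(x), length(y)) <= 8 && !ties
  if (exact && ties) stop("exact p-values are unavailable with ties")
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = !exact))
  structure(data.frame(statistic = unname(ht$statistic),
                       p = ht$p.value,
                       method = if (exact) "mann-whitney exact"
                                else "mann-whitney normal approximation",
                       n_x = length(x), n_y = length(y),
                       stringsAsFactors = FALSE),
            class = c("test_result", "data.frame"))
}

#' Welch two-sample t-test
#'
#' Unpaired two-sided t-test assuming unequal variances
#' (Welch-Satterthwaite degrees of freedom). The degenerate case where both
#' samples have zero variance is resolved by convention: equal means give
#' p = 1, unequal means give p = 0 with method flagged `"degenerate"`.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @return A one-row `"test_result"` data frame (`statistic` = t, `p`,
#'   `method`, `n_x`, `n_y`).
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(structure(data.frame(statistic = if (eq) 0 else Inf,
                                p = if (eq) 1 else 0,
                                method = "welch t (degenerate)",
                                n_x = length(x), n_y = length(y),
                                stringsAsFactors = FALSE),
                     class = c("test_result", "data.frame")))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  structure(data.frame(statistic = unname(ht$statistic), p = ht$p.value,
                       method = "welch t",
                       n_x = length(x), n_y = length(y),
                       stringsAsFactors = FALSE),
            class = c("test_result", "data.frame"))
}

# shared regression-result assembler
regression_rows <- function(coefs, predictors, outcome_label, n_obs, model) {
  rows <- lapply(predictors, function(pr) {
    est <- coefs[pr, , drop = TRUE]
    p <- est[4]
    se <- est[2]
    if (!is.finite(p) || se == 0) p <- 1e-12  # exact-fit floor
    data.frame(predictor_label = pr, outcome_label = outcome_label,
               beta = est[1], se = se, p = max(p, 1e-12),
               n_obs = n_obs, model = model,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("regression_result", "data.frame")
  out
}

#' Ordinary least-squares regression panel
#'
#' Fits linear models of a continuous outcome on one or more predictors with
#' an intercept always included. With `univariate = TRUE` (the default) each
#' predictor is fit in its own simple regression; otherwise a single
#' multivariable model is fit. Standard errors come from the residual
#' variance and p-values are two-sided from the t distribution; exact fits
#' (zero residual variance) are reported with the floor p = 1e-12.
#'
#' @param outcome Numeric response.
#' @param predictors Data frame (or named list) of numeric predictors.
#' @param univariate Fit each predictor separately (default `TRUE`).
#' @return A `"regression_result"` data frame with one row per predictor:
#'   `predictor_label`, `outcome_label`, `beta`, `se`, `p`, `n_obs`, `model`.
#' @export
ols_fit <- function(outcome, predictors, univariate = TRUE) {
  predictors <- as.data.frame(predictors)
  outcome_label <- deparse(substitute(outcome))[1]
  if (!nrow(predictors) || nrow(predictors) != length(outcome))
    stop("outcome and predictors must have matching lengths")
  const <- vapply(predictors, function(v) stats::var(v, na.rm = TRUE) == 0, logical(1))
  if (any(const))
    stop("constant predictor(s): ", paste(names(predictors)[const], collapse = ", "))
  if (length(outcome) <= ncol(predictors) + 1L)
    stop("need more observations than predictors plus intercept")
  if (univariate) {
    out <- lapply(names(predictors), function(pr) {
      fit <- stats::lm(outcome ~ x, data = data.frame(outcome = outcome,
                                                      x = predictors[[pr]]))
      co <- suppressWarnings(summary(fit))$coefficients  # exact fits handled below
      rownames(co)[rownames(co) == "x"] <- pr
      regression_rows(co, pr, outcome_label, length(fit$residuals), "ols univariate")
    })
    out <- do.call(rbind, out)
    class(out) <- c("regression_result", "data.frame")
    return(out)
  }
  dat <- cbind(.outcome = outcome, predictors)
  fit <- stats::lm(.outcome ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear predictor(s): ",
         paste(bad, collapse = ", "))
  }
  co <- summary(fit)$coefficients
  regression_rows(co, setdiff(rownames(co), "(Intercept)"),
                  outcome_label, length(fit$residuals), "ols multivariate")
}

#' Logistic regression panel
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `glm`) of a binary outcome on one or more predictors, with
#' Wald standard errors and two-sided p-values. Complete separation
#' (divergent coefficients or boundary fitted probabilities) raises an
#' error rather than returning unstable estimates.
#'
#' @inheritParams ols_fit
#' @param outcome Binary (0/1 or logical) response with both classes present.
#' @return A `"regression_result"` data frame, one row per predictor.
#' @export
logistic_fit <- function(outcome, predictors, univariate = TRUE) {
  outcome <- as.numeric(outcome)
  predictors <- as.data.frame(predictors)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary")
  if (length(unique(outcome)) < 2L)
    stop("outcome is constant: both classes must be present")
  fit_one <- function(df, label_map, model) {
    fit <- suppressWarnings(
      stats::glm(.outcome ~ ., data = df, family = stats::binomial(),
                 control = stats::glm.control(maxit = 100, epsilon = 1e-10)))
    cf <- stats::coef(fit)[-1]
    mu <- stats::fitted(fit)
    if (!fit$converged || any(abs(cf) > 15) ||
        any(mu < 1e-8) || any(mu > 1 - 1e-8))
      stop("complete (or quasi-complete) separation detected; ",
           "logistic coefficients are not estimable")
    co <- summary(fit)$coefficients
    rownames(co) <- c("(Intercept)", label_map)
    regression_rows(co, label_map, ".binary", length(outcome), model)
  }
  if (univariate) {
    out <- lapply(names(predictors), function(pr)
      fit_one(data.frame(.outcome = outcome, x = predictors[[pr]]),
              pr, "logistic univariate"))
    out <- do.call(rbind, out)
    class(out) <- c("regression_result", "data.frame")
    return(out)
  }
  fit_one(cbind(data.frame(.outcome = outcome), predictors),
          names(predictors), "logistic multivariate")
}

#' Holm step-down multiple-testing correction
#'
#' Orders the p-values ascending and compares the i-th smallest against
#' `alpha / (k - i + 1)`, stopping at the first failure; every hypothesis
#' before the stop is rejected. Controls the family-wise error rate at
#' `alpha` without the full Bonferroni power loss.
#'
#' @param p Named (or unnamed) numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level (default 0.05).
#' @param method `"holm"` (default) or `"BH"` (Benjamini-Hochberg step-up,
#'   controlling the false discovery rate instead).
#' @return Data frame with columns `label`, `p`, `p_adjusted`, `reject`, in
#'   the input order.
#' @export
holm_bonferroni <- function(p, alpha = 0.05, method = c("holm", "BH")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  labels <- if (is.null(names(p))) paste0("h", seq_along(p)) else names(p)
  adj <- stats::p.adjust(p, method = method)
  data.frame(label = labels, p = as.numeric(p), p_adjusted = adj,
             reject = adj <= alpha, stringsAsFactors = FALSE)
}

#' Apply multiple-testing correction within families
#'
#' Splits a result table by its family key and applies [holm_bonferroni()]
#' independently within each family, never mixing families. The intended
#' family key for the dose-metric regressions is
#' (delivery group, structure, blood analyte), so the five V5-V25 levels of
#' one structure against one analyte form one family.
#'
#' @param results Data frame with at least columns `family` and `p`.
#' @param alpha Level per family (default 0.05).
#' @param method `"holm"` (default) or `"BH"`.
#' @return `results` with columns `p_adjusted` and `reject` appended
#'   (original row order preserved).
#' @export
family_correction <- function(results, alpha = 0.05, method = c("holm", "BH")) {
  method <- match.arg(method)
  if (!all(c("family", "p") %in% names(results)))
    stop("results must have 'family' and 'p' columns")
  results$p_adjusted <- NA_real_
  results$reject <- NA
  for (fam in unique(results$family)) {
    idx <- which(results$family == fam)
    dec <- holm_bonferroni(results$p[idx], alpha = alpha, method = method)
    results$p_adjusted[idx] <- dec$p_adjusted
    results$reject[idx] <- dec$reject
  }
  results
}
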