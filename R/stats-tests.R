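#' Mann-Whitney U test (two-sided)
#'
#' Two-sample rank test of the group comparisons (CCFA ratio, CV) between
#' AMD fellow and control eyes.  Uses the exact null distribution when the
#' combined sample size is at most `exact_threshold` and there are no ties,
#' otherwise the normal approximation with tie and continuity correction
#' (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param exact_threshold Combined-n switchover to the approximation
#'   (default 20).
#' @return A `ccfa_test` object: `statistic` (U for `x`), `p_value`
#'   (two-sided), `n_per_group`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 20L) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample must contain at least two observations")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exact_threshold && !ties
  ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_per_group = c(length(x), length(y)),
                 method = if (exact) "exact" else "normal approximation",
                 test = "Mann-Whitney U"),
            class = "ccfa_test")
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Paired within-eye test (abnormal vs normal FAF region, thinner vs
#' thicker side).  Zero differences are dropped; the exact distribution is
#' used when at most `exact_threshold` nonzero differences remain and their
#' absolute values are untied.
#'
#' @param paired_diffs Numeric vector of paired differences.
#' @param exact_threshold Switchover to the normal approximation
#'   (default 15).
#' @return A `ccfa_test` object.
#' @export
wilcoxon_signed_rank <- function(paired_diffs, exact_threshold = 15L) {
  d <- paired_diffs[!is.na(paired_diffs)]
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("all paired differences are zero: signed-rank test undefined")
  if (length(d) < 2L)
    stop("fewer than two nonzero paired differences")
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- length(d) <= exact_threshold && !ties
  ht <- stats::wilcox.test(d, exact = exact, correct = TRUE)
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_per_group = length(d),
                 method = if (exact) "exact" else "normal approximation",
                 test = "Wilcoxon signed-rank"),
            class = "ccfa_test")
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by minimum-likelihood summation over all tables with
#' the observed margins (the convention of [stats::fisher.test()] and most
#' statistical packages); one-sided alternatives are also available.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A `ccfa_test` object; `statistic` is the conditional odds-ratio
#'   estimate.
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L)))
    stop("table must be a 2x2 matrix")
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate margin: every row and column total must be positive")
  ht <- stats::fisher.test(table, alternative = alternative)
  structure(list(statistic = unname(ht$estimate), p_value = ht$p.value,
                 n_per_group = rowSums(table),
                 method = paste("exact,", alternative),
                 test = "Fisher exact"),
            class = "ccfa_test")
}

#' @export
print.ccfa_test <- function(x, ...) {
  cat(sprintf("%s test (%s): statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$method, x$statistic, x$p_value,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' ROC curve with Youden-index cutoff
#'
#' Computes the AUC by the rank (Mann-Whitney) formulation, giving half
#' credit to ties, and derives the cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1.  Candidate cutoffs are midpoints
#' between consecutive distinct scores; ties in J are broken toward higher
#' specificity (fewer test-positives).  The test-positive rule per metric:
#' direction `"less-than"` calls scores below the cutoff positive (CCFA
#' ratio), `"greater-equal"` calls scores at or above the cutoff positive
#' (CV of the CCFA ratio).
#'
#' @param scores Numeric marker values.
#' @param labels Binary class labels (1/TRUE = positive class, e.g. AMD
#'   fellow eye).
#' @param direction `"greater-equal"` or `"less-than"`.
#' @return An object of class `roc_result`: `auc`, `cutoff`, `direction`,
#'   `youden`, `sensitivity`, `specificity`.
#' @export
roc_with_cutoff <- function(scores, labels,
                            direction = c("greater-equal", "less-than")) {
  direction <- match.arg(direction)
  lab <- as.integer(as.logical(labels))
  if (length(scores) != length(lab)) stop("scores and labels differ in length")
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  oriented <- if (direction == "less-than") -scores else scores
  r <- rank(oriented)
  auc <- (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  u <- sort(unique(oriented))
  cand <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else u
  best <- NULL
  for (t in cand) {
    sens <- sum(oriented >= t & lab == 1L) / n1
    spec <- sum(oriented < t & lab == 0L) / n0
    j <- sens + spec - 1
    # strict improvement, or equal J with higher specificity (larger t)
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec))
      best <- list(t = t, j = j, sens = sens, spec = spec)
  }
  cutoff <- if (direction == "less-than") -best$t else best$t
  structure(list(auc = auc, cutoff = cutoff, direction = direction,
                 youden = best$j, sensitivity = best$sens,
                 specificity = best$spec, n_per_class = c(n1, n0)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  rule <- if (x$direction == "less-than") "<" else ">="
  cat(sprintf("ROC: AUC = %.3f; Youden cutoff: positive if score %s %.4g (J = %.3f)\n",
              x$auc, rule, x$cutoff, x$youden))
  invisible(x)
}

#' Age- and sex-adjusted logistic regression
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()], log-likelihood
#' convergence tolerance 1e-8) of a binary outcome on an exposure with
#' adjustment covariates (age and sex in the cohort analyses).  Reports the
#' exposure odds ratio with a 95% Wald confidence interval
#' `exp(coef +/- 1.96 * SE)`.  Complete or quasi-complete separation
#' (diverging coefficients) raises an explicit error rather than returning
#' a silently huge odds ratio.
#'
#' @param outcome Binary outcome vector (0/1 or logical).
#' @param exposure Exposure vector (binary or numeric).
#' @param covariates Optional data.frame of adjustment covariates.
#' @param exposure_name Label for the exposure term.
#' @return An object of class `logistic_fit`: per-term `coefficients`
#'   table, `odds_ratio`, `ci95`, `p_value` (exposure term), `n`, and the
#'   underlying `glm` in `$model`.
#' @export
logistic_adjusted <- function(outcome, exposure, covariates = NULL,
                              exposure_name = "exposure") {
  y <- as.integer(as.logical(outcome))
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations for a logistic fit")
  df <- data.frame(.y = y, .e = as.numeric(exposure))
  names(df)[2L] <- exposure_name
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      df[[nm]] <- if (is.character(v) || is.factor(v) || is.logical(v))
        as.numeric(as.factor(v)) - 1 else as.numeric(v)
    }
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (!fit$converged || max(abs(stats::coef(fit)), na.rm = TRUE) > 15 ||
      (sep_warn && co[exposure_name, "Std. Error"] > 50))
    stop("complete or quasi-complete separation detected: odds ratio not estimable")
  est <- co[exposure_name, "Estimate"]
  se <- co[exposure_name, "Std. Error"]
  structure(list(coefficients = co,
                 odds_ratio = exp(est),
                 ci95 = exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = co[exposure_name, "Pr(>|z|)"],
                 exposure = exposure_name, n = n, model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit (n = %d): OR[%s] = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$n, x$exposure, x$odds_ratio, x$ci95[1], x$ci95[2], x$p_value))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) stats::coef(object$model)

#' @export
predict.logistic_fit <- function(object, newdata = NULL, type = "response", ...) {
  stats::predict(object$model, newdata = newdata, type = type, ...)
}
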