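#' Cohort-level inference on quantified eyes
#'
#' Runs the full set of cohort analyses on a table of subject records:
#' group comparisons of CCFA ratio and CV (Mann-Whitney U), the FAF
#' 2x2 Fisher exact test, ROC curves with Youden cutoffs for both metrics,
#' dual-cutoff risk classification counts, age/sex-adjusted logistic odds
#' ratios (high-risk status vs group membership, and FAF abnormality /
#' vasculature asymmetry in both outcome directions, since either reading
#' of the adjusted model is defensible), within-eye paired Wilcoxon tests
#' for FAF regions and thicker/thinner sides, and RPE-volume side
#' comparisons.  Strata too small for a given analysis are skipped with a
#' logged reason rather than failing the whole report.
#'
#' @param records Data.frame with columns `id`, `group`
#'   (`amd_fellow`/`control`), `age`, `sex`, `faf_abnormal`,
#'   `asymmetric_vasculature`, `thicker_side`, `ccfa_ratio`, `cv`, and
#'   optionally `ccfa_faf_abnormal`, `ccfa_faf_normal`, `ccfa_thinner`,
#'   `ccfa_thicker`, `cv_thinner`, `cv_thicker`, `rpe_vol_thinner`,
#'   `rpe_vol_thicker`.
#' @param cutoffs Risk cutoffs, see [classify_risk()].
#' @param exact_threshold_mw,exact_threshold_wsr Exact-test switchovers
#'   passed to [mann_whitney_u()] and [wilcoxon_signed_rank()].
#' @return An object of class `cohort_result`.
#' @export
run_cohort_analysis <- function(records, cutoffs = c(ccfa = 58.5, cv = 0.165),
                                exact_threshold_mw = 20L,
                                exact_threshold_wsr = 15L) {
  req <- c("id", "group", "age", "sex", "faf_abnormal",
           "asymmetric_vasculature", "thicker_side", "ccfa_ratio", "cv")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records missing required columns: ", paste(miss, collapse = ", "))
  if (!all(records$group %in% c("amd_fellow", "control")))
    stop("group must be 'amd_fellow' or 'control'")

  amd <- records[records$group == "amd_fellow", , drop = FALSE]
  ctl <- records[records$group == "control", , drop = FALSE]
  if (nrow(amd) < 2L || nrow(ctl) < 2L)
    stop("need at least 2 subjects per group")

  skipped <- list()
  run <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      skipped[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  tests <- list()
  tests$group_ccfa <- run("group_ccfa",
    mann_whitney_u(amd$ccfa_ratio, ctl$ccfa_ratio, exact_threshold_mw))
  tests$group_cv <- run("group_cv",
    mann_whitney_u(amd$cv, ctl$cv, exact_threshold_mw))

  faf_table <- rbind(amd_fellow = c(faf_abnormal = sum(amd$faf_abnormal),
                                    faf_normal = sum(!amd$faf_abnormal)),
                     control = c(sum(ctl$faf_abnormal), sum(!ctl$faf_abnormal)))
  tests$faf_fisher <- run("faf_fisher", fisher_exact_2x2(faf_table))
  tests$faf_fisher_one_sided <- run("faf_fisher_one_sided",
    fisher_exact_2x2(faf_table, alternative = "greater"))

  is_amd <- records$group == "amd_fellow"
  roc <- list()
  roc$ccfa <- run("roc_ccfa",
    roc_with_cutoff(records$ccfa_ratio, is_amd, direction = "less-than"))
  roc$cv <- run("roc_cv",
    roc_with_cutoff(records$cv, is_amd, direction = "greater-equal"))

  high_risk <- unname(classify_risk(records$ccfa_ratio, records$cv, cutoffs))
  risk_counts <- table(group = records$group,
                       high_risk = factor(high_risk, levels = c(FALSE, TRUE)))

  covs <- data.frame(age = records$age, sex = records$sex)
  logistic <- list()
  logistic$group_on_highrisk <- run("logistic_group_on_highrisk",
    logistic_adjusted(is_amd, high_risk, covs, "high_risk"))
  logistic$highrisk_on_faf <- run("logistic_highrisk_on_faf",
    logistic_adjusted(high_risk, records$faf_abnormal, covs, "faf_abnormal"))
  logistic$highrisk_on_asym <- run("logistic_highrisk_on_asym",
    logistic_adjusted(high_risk, records$asymmetric_vasculature, covs,
                      "asymmetric_vasculature"))
  logistic$group_on_faf <- run("logistic_group_on_faf",
    logistic_adjusted(is_amd, records$faf_abnormal, covs, "faf_abnormal"))
  logistic$group_on_asym <- run("logistic_group_on_asym",
    logistic_adjusted(is_amd, records$asymmetric_vasculature, covs,
                      "asymmetric_vasculature"))

  paired <- list()
  has <- function(cols) all(cols %in% names(records))
  if (has(c("ccfa_faf_abnormal", "ccfa_faf_normal"))) {
    d <- amd$ccfa_faf_abnormal - amd$ccfa_faf_normal
    paired$faf_region_ccfa <- run("paired_faf_region_ccfa",
      wilcoxon_signed_rank(d[!is.na(d)], exact_threshold_wsr))
    paired$faf_eyes_vs_normal_eyes_ccfa <- run("faf_eyes_vs_normal_eyes_ccfa",
      mann_whitney_u(amd$ccfa_ratio[amd$faf_abnormal],
                     amd$ccfa_ratio[!amd$faf_abnormal], exact_threshold_mw))
  }
  if (has(c("ccfa_thinner", "ccfa_thicker"))) {
    d <- amd$ccfa_thinner - amd$ccfa_thicker
    paired$side_ccfa <- run("paired_side_ccfa",
      wilcoxon_signed_rank(d[!is.na(d)], exact_threshold_wsr))
    paired$asym_vs_sym_ccfa <- run("asym_vs_sym_ccfa",
      mann_whitney_u(amd$ccfa_ratio[amd$asymmetric_vasculature],
                     amd$ccfa_ratio[!amd$asymmetric_vasculature],
                     exact_threshold_mw))
  }
  if (has(c("cv_thinner", "cv_thicker"))) {
    d <- amd$cv_thinner - amd$cv_thicker
    paired$side_cv <- run("paired_side_cv",
      wilcoxon_signed_rank(d[!is.na(d)], exact_threshold_wsr))
    paired$asym_vs_sym_cv <- run("asym_vs_sym_cv",
      mann_whitney_u(amd$cv[amd$asymmetric_vasculature],
                     amd$cv[!amd$asymmetric_vasculature], exact_threshold_mw))
  }
  if (has(c("rpe_vol_thinner", "rpe_vol_thicker"))) {
    d <- amd$rpe_vol_thinner - amd$rpe_vol_thicker
    paired$side_rpe_volume <- run("paired_side_rpe_volume",
      wilcoxon_signed_rank(d[!is.na(d)], exact_threshold_wsr))
  }

  structure(list(tests = tests, roc = roc, paired = paired,
                 logistic = logistic,
                 faf_table = faf_table, risk_counts = risk_counts,
                 high_risk = high_risk, cutoffs = cutoffs,
                 n_per_group = c(amd_fellow = nrow(amd), control = nrow(ctl)),
                 skipped = skipped),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort_result: %d AMD fellow eyes vs %d controls\n",
              x$n_per_group[["amd_fellow"]], x$n_per_group[["control"]]))
  if (!is.null(x$tests$group_ccfa))
    cat(sprintf("  CCFA ratio group difference: p = %.4g\n",
                x$tests$group_ccfa$p_value))
  if (!is.null(x$tests$group_cv))
    cat(sprintf("  CV group difference:         p = %.4g\n",
                x$tests$group_cv$p_value))
  if (!is.null(x$tests$faf_fisher))
    cat(sprintf("  FAF 2x2 Fisher: p = %.4g (one-sided %.4g)\n",
                x$tests$faf_fisher$p_value,
                x$tests$faf_fisher_one_sided$p_value))
  if (!is.null(x$roc$ccfa))
    cat(sprintf("  ROC: AUC %.3f (CCFA, cutoff %.1f), %.3f (CV, cutoff %.3f)\n",
                x$roc$ccfa$auc, x$roc$ccfa$cutoff,
                x$roc$cv$auc, x$roc$cv$cutoff))
  cat(sprintf("  high risk (CCFA < %.1f & CV >= %.3f): %d of %d eyes\n",
              x$cutoffs[["ccfa"]], x$cutoffs[["cv"]],
              sum(x$high_risk), length(x$high_risk)))
  if (!is.null(x$logistic$group_on_highrisk)) {
    f <- x$logistic$group_on_highrisk
    cat(sprintf("  adjusted OR (AMD fellow | high risk): %.3f (95%% CI %.3f-%.3f)\n",
                f$odds_ratio, f$ci95[1], f$ci95[2]))
  }
  if (length(x$skipped))
    cat("  skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cohort_result <- function(object, ...) {
  ps <- c(vapply(object$tests, function(t) t$p_value %||% NA_real_, 1),
          vapply(object$paired, function(t) t$p_value %||% NA_real_, 1))
  out <- data.frame(analysis = names(ps), p_value = unname(ps))
  ors <- lapply(object$logistic, function(f)
    if (is.null(f)) c(NA, NA, NA, NA)
    else c(f$odds_ratio, f$ci95, f$p_value))
  or_tab <- do.call(rbind, ors)
  colnames(or_tab) <- c("odds_ratio", "ci_low", "ci_high", "p_value")
  structure(list(p_values = out, odds_ratios = as.data.frame(or_tab),
                 risk_counts = object$risk_counts,
                 skipped = object$skipped),
            class = "summary.cohort_result")
}

#' @export
print.summary.cohort_result <- function(x, ...) {
  cat("Analysis p-values:\n"); print(x$p_values, row.names = FALSE)
  cat("\nAdjusted odds ratios:\n"); print(round(x$odds_ratios, 4))
  cat("\nRisk classification:\n"); print(x$risk_counts)
  if (length(x$skipped)) {
    cat("\nSkipped analyses:\n")
    for (nm in names(x$skipped)) cat("  ", nm, ": ", x$skipped[[nm]], "\n", sep = "")
  }
  invisible(x)
}
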