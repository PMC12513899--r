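#' Study summary: the reported numerical facts of one study comparison
#'
#' A `study_summary` bundles everything a published report typically makes
#' available about a single t-test or ANOVA main-effect comparison: the
#' design, sample sizes, descriptive statistics, test statistic, degrees of
#' freedom, the p-value (exact or as a relative bound), and the alpha level
#' at which the original analysis was run. Every downstream operation --
#' effect-size recomputation, compatibility testing, replication planning --
#' starts from one of these objects, because raw data are rarely obtainable.
#'
#' @param design One of `"paired"`, `"independent"`, `"anova_between"`,
#'   `"anova_within"`, `"anova_mixed"`.
#' @param n1 Sample size: number of pairs (paired), group 1 size
#'   (independent), or total N (ANOVA designs).
#' @param n2 Group 2 size; independent design only.
#' @param mean1,mean2 Condition/group means, in the units of the dependent
#'   variable.
#' @param sd1,sd2 Condition/group standard deviations (must be positive).
#' @param mean_diff,sd_diff Mean and SD of paired difference scores. When
#'   absent for a paired design they are derived from `mean1`/`mean2`,
#'   `sd1`/`sd2` and `r_pairs` where possible.
#' @param r_pairs Correlation between paired measurements, in (-1, 1).
#' @param t_value,F_value Reported test statistic (at most one is used;
#'   `F_value` must be nonnegative).
#' @param df1,df2 Degrees of freedom. For t-based designs only `df1` is
#'   used; for F-tests `df1` is the effect df and `df2` the error df.
#' @param p_value Reported p-value in (0, 1].
#' @param p_bound How the p-value was reported: `"exact"`, `"lt_05"`,
#'   `"lt_01"` or `"lt_001"`. An exact `p_value` of 0 (the "p = 0.000"
#'   reporting artifact) is reinterpreted as the bound `"lt_001"`.
#' @param alpha Significance level of the original analysis, in (0, 1).
#' @param tail `"two_sided"` (default) or `"one_sided"`.
#'
#' @return An object of class `"study_summary"`.
#' @examples
#' study_summary("paired", n1 = 12, mean_diff = 1.4, sd_diff = 2.1)
#' study_summary("anova_between", n1 = 30, F_value = 6.2, df1 = 2, df2 = 27)
#' @export
study_summary <- function(design,
                          n1 = NULL, n2 = NULL,
                          mean1 = NULL, mean2 = NULL,
                          sd1 = NULL, sd2 = NULL,
                          mean_diff = NULL, sd_diff = NULL,
                          r_pairs = NULL,
                          t_value = NULL, F_value = NULL,
                          df1 = NULL, df2 = NULL,
                          p_value = NULL, p_bound = NULL,
                          alpha = 0.05,
                          tail = c("two_sided", "one_sided")) {
  design <- match.arg(design, c("paired", "independent", "anova_between",
                                "anova_within", "anova_mixed"))
  tail <- match.arg(tail)
  chk_count <- function(x, nm, min = 1L) {
    if (!is.null(x)) {
      if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
        stop(sprintf("'%s' must be a single count >= %d", nm, min),
             call. = FALSE)
    }
  }
  chk_count(n1, "n1", 2L)
  chk_count(n2, "n2", 2L)
  for (nm in c("sd1", "sd2", "sd_diff")) {
    v <- get(nm)
    if (!is.null(v) && (!is.finite(v) || v <= 0))
      stop(sprintf("'%s' must be positive", nm), call. = FALSE)
  }
  if (!is.null(r_pairs) && (!is.finite(r_pairs) || abs(r_pairs) >= 1))
    stop("'r_pairs' must lie strictly inside (-1, 1)", call. = FALSE)
  if (!is.null(F_value) && (!is.finite(F_value) || F_value < 0))
    stop("'F_value' must be a nonnegative number", call. = FALSE)
  if (!is.null(t_value) && !is.finite(t_value))
    stop("'t_value' must be finite", call. = FALSE)
  for (nm in c("df1", "df2")) {
    v <- get(nm)
    if (!is.null(v) && (!is.finite(v) || v <= 0))
      stop(sprintf("'%s' must be positive", nm), call. = FALSE)
  }
  if (!is.null(p_value)) {
    if (!is.finite(p_value) || p_value < 0 || p_value > 1)
      stop("'p_value' must lie in [0, 1]", call. = FALSE)
    if (p_value == 0) {          # "p = 0.000" reporting artifact
      p_value <- NULL
      p_bound <- "lt_001"
    }
  }
  if (!is.null(p_bound))
    p_bound <- match.arg(p_bound, c("exact", "lt_05", "lt_01", "lt_001"))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)

  has_means <- !is.null(mean1) && !is.null(mean2) &&
    !is.null(sd1) && !is.null(sd2) && !is.null(n1)
  has_diff <- !is.null(mean_diff) && !is.null(sd_diff) && !is.null(n1)
  if (is.null(t_value) && is.null(F_value) && !has_means && !has_diff &&
      is.null(p_value) && is.null(p_bound))
    stop("a study summary needs at least one of: a test statistic, ",
         "means and SDs with n, or a p-value / p-bound", call. = FALSE)

  structure(
    list(design = design, n1 = n1, n2 = n2,
         mean1 = mean1, mean2 = mean2, sd1 = sd1, sd2 = sd2,
         mean_diff = mean_diff, sd_diff = sd_diff, r_pairs = r_pairs,
         t_value = t_value, F_value = F_value, df1 = df1, df2 = df2,
         p_value = p_value, p_bound = p_bound,
         alpha = alpha, tail = tail),
    class = "study_summary")
}

#' Standardized effect size with uncertainty and provenance
#'
#' Container for one standardized effect estimate. `provenance` records how
#' the number was obtained, mirroring the practical reality of replication
#' work: some effects are taken from the report, some recomputed from the
#' reported statistics or shared data, and some can only be estimated
#' conservatively from a relative p-value.
#'
#' @param kind One of `"d_z"` (paired, SD of difference scores in the
#'   denominator), `"d_s"` (pooled-SD two-group), `"d_av"` (average-SD
#'   paired), `"g"` (Hedges-corrected d), `"partial_eta_sq"`.
#' @param value The estimate. `partial_eta_sq` must lie in \[0, 1\].
#' @param se Standard error (nonnegative). For `partial_eta_sq` the SE is
#'   carried on the Fisher-z scale of r = sqrt(eta); see [se_of_effect()].
#' @param ci_low,ci_high,ci_level Confidence bounds and level, if formed.
#' @param provenance `"reported"`, `"computed_from_data"` or `"estimated"`.
#' @return An object of class `"effect_size"`.
#' @export
effect_size <- function(kind, value, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        ci_level = NA_real_,
                        provenance = c("computed_from_data", "reported",
                                       "estimated")) {
  kind <- match.arg(kind, c("d_z", "d_s", "d_av", "g", "partial_eta_sq"))
  provenance <- match.arg(provenance)
  if (!is.finite(value))
    stop("effect size 'value' must be finite", call. = FALSE)
  if (kind == "partial_eta_sq" && (value < 0 || value > 1))
    stop("partial eta squared must lie in [0, 1]", call. = FALSE)
  if (!is.na(se) && se < 0)
    stop("'se' must be nonnegative", call. = FALSE)
  if (!is.na(ci_low) && !is.na(ci_high)) {
    if (ci_low > value + 1e-12 || ci_high < value - 1e-12)
      stop("confidence interval must bracket the estimate", call. = FALSE)
  }
  structure(
    list(kind = kind, value = value, se = se,
         ci_low = ci_low, ci_high = ci_high, ci_level = ci_level,
         provenance = provenance),
    class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> %s = %.4f", x$kind, x$value))
  if (!is.na(x$se)) cat(sprintf(" (SE %.4f)", x$se))
  if (!is.na(x$ci_low))
    cat(sprintf(", %g%% CI [%.4f, %.4f]", 100 * x$ci_level,
                x$ci_low, x$ci_high))
  cat(sprintf("  [%s]\n", x$provenance))
  invisible(x)
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> design=%s", x$design))
  if (!is.null(x$n1)) cat(sprintf(", n1=%d", as.integer(x$n1)))
  if (!is.null(x$n2)) cat(sprintf(", n2=%d", as.integer(x$n2)))
  if (!is.null(x$t_value)) cat(sprintf(", t=%.3f", x$t_value))
  if (!is.null(x$F_value)) cat(sprintf(", F=%.3f", x$F_value))
  if (!is.null(x$p_value)) cat(sprintf(", p=%.4g", x$p_value))
  if (!is.null(x$p_bound) && is.null(x$p_value))
    cat(sprintf(", p %s", sub("lt_", "< 0.", x$p_bound)))
  cat(sprintf(", alpha=%g (%s)\n", x$alpha, x$tail))
  invisible(x)
}

# total N of subjects contributing to a summary
total_n <- function(summary) {
  if (is.null(summary$n1)) stop("sample size missing", call. = FALSE)
  if (summary$design == "independent") {
    if (is.null(summary$n2)) stop("'n2' missing for independent design",
                                  call. = FALSE)
    summary$n1 + summary$n2
  } else {
    summary$n1
  }
}

is_t_design <- function(design) design %in% c("paired", "independent")
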