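#' Publication-bias/uncertainty-corrected effect size
#'
#' A published significant statistic is a draw from its sampling
#' distribution *conditional on having crossed the significance
#' threshold*, which inflates the published magnitude. The correction
#' inverts that selection: it finds the noncentrality parameter under
#' which the observed statistic sits at the `1 - assurance` quantile of
#' the significance-truncated noncentral distribution (t truncated
#' two-sided at the alpha critical value; F truncated at its upper
#' critical value), then maps the corrected noncentrality back to the
#' effect scale. `assurance = 0.5` gives the median-corrected
#' ("median-unbiased under selection") effect.
#'
#' When the observed statistic is too close to the critical value the
#' corrected noncentrality is driven to zero or below -- the signature
#' of publication bias too severe to correct -- and an error of class
#' `"PublicationBiasTooHigh"` is signalled, mirroring the "infinite
#' sample size" failure mode of this planning method.
#'
#' @param statistic Observed t (t designs) or F (ANOVA designs).
#' @param df Degrees of freedom of the t statistic, or the error df of
#'   the F statistic.
#' @param alpha Selection threshold of the original study (two-sided for
#'   t), in (0, 1).
#' @param assurance Quantile of the truncated distribution at which the
#'   observed statistic is assumed to sit; in (0, 1), default 0.5.
#' @param design Study design (determines the effect scale the corrected
#'   noncentrality is mapped to).
#' @param n1,n2 Sample sizes; for `"paired"` defaults to `df + 1`, for
#'   `"independent"` to equal groups of `(df + 2)/2`.
#' @param df1 Effect df for ANOVA designs (default 1).
#' @return An [effect_size()] with provenance `"estimated"`: kind `"d_z"`,
#'   `"d_s"` or `"partial_eta_sq"` according to the design.
#' @export
corrected_effect <- function(statistic, df, alpha = 0.05, assurance = 0.5,
                             design = c("paired", "independent",
                                        "anova_between", "anova_within",
                                        "anova_mixed"),
                             n1 = NULL, n2 = NULL, df1 = 1) {
  design <- match.arg(design)
  if (!is.finite(statistic)) stop("'statistic' must be finite", call. = FALSE)
  if (df < 1) stop("'df' must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || assurance <= 0 || assurance >= 1)
    stop("'alpha' and 'assurance' must lie in (0, 1)", call. = FALSE)

  bias_too_high <- function() {
    stop(structure(
      class = c("PublicationBiasTooHigh", "error", "condition"),
      list(message = paste0(
             "corrected noncentrality is not positive: the observed ",
             "statistic is consistent with selection alone, so the ",
             "bias-corrected effect (and the implied sample size) is ",
             "undefined"),
           call = NULL)))
  }

  if (is_t_design(design)) {
    tobs <- abs(statistic)
    crit <- stats::qt(1 - alpha / 2, df)
    if (tobs < crit)
      stop("the statistic is not significant at the stated alpha; ",
           "there is no selection event to correct for", call. = FALSE)
    # P(T <= t | |T| > crit) under noncentrality ncp
    ptrunc <- function(t, ncp) {
      lower_mass <- stats::pt(-crit, df, ncp)
      denom <- lower_mass + stats::pt(crit, df, ncp, lower.tail = FALSE)
      (lower_mass + pmax(0, stats::pt(t, df, ncp) - stats::pt(crit, df, ncp))) /
        denom
    }
    target <- 1 - assurance
    if (ptrunc(tobs, 0) <= target) bias_too_high()
    ncp <- solve_ncp(ptrunc, tobs, target, 0, tobs + 10)
    if (ncp <= 0) bias_too_high()
    if (design == "paired") {
      if (is.null(n1)) n1 <- df + 1
      es <- effect_size("d_z", sign(statistic) * ncp / sqrt(n1),
                        provenance = "estimated")
    } else {
      if (is.null(n1) || is.null(n2)) {
        n1 <- (df + 2) / 2; n2 <- n1
      }
      es <- effect_size("d_s", sign(statistic) * ncp * sqrt(1 / n1 + 1 / n2),
                        provenance = "estimated")
    }
  } else {
    Fobs <- statistic
    df2 <- df
    crit <- stats::qf(1 - alpha, df1, df2)
    if (Fobs < crit)
      stop("the statistic is not significant at the stated alpha; ",
           "there is no selection event to correct for", call. = FALSE)
    ptrunc <- function(f, ncp) {
      upper <- stats::pf(crit, df1, df2, ncp, lower.tail = FALSE)
      pmax(0, stats::pf(f, df1, df2, ncp) - stats::pf(crit, df1, df2, ncp)) /
        upper
    }
    target <- 1 - assurance
    if (ptrunc(Fobs, 0) <= target) bias_too_high()
    lam <- solve_ncp(ptrunc, Fobs, target, 0, 4 * (Fobs + 1) * df1 + 20)
    if (lam <= 0) bias_too_high()
    N <- df1 + df2 + 1                      # between-subjects bookkeeping
    es <- effect_size("partial_eta_sq", lam / (lam + N),
                      provenance = "estimated")
  }
  es
}

# achieved power of the design-appropriate test at a given effect and n.
# n is pairs (paired), per-group (independent), per-group (anova, k groups).
power_at_n <- function(effect, n, design, alpha = 0.05,
                       tail = "two_sided", k_groups = 3) {
  if (is_t_design(design)) {
    if (design == "paired") {
      df <- n - 1; ncp <- abs(effect) * sqrt(n)
    } else {
      df <- 2 * n - 2; ncp <- abs(effect) * sqrt(n / 2)
    }
    if (df < 1) return(0)
    if (tail == "two_sided") {
      crit <- stats::qt(1 - alpha / 2, df)
      stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
    } else {
      crit <- stats::qt(1 - alpha, df)
      stats::pt(crit, df, ncp, lower.tail = FALSE)
    }
  } else {
    eta <- abs(effect)
    if (eta >= 1) return(1)
    f2 <- eta / (1 - eta)
    N <- n * k_groups
    df1 <- k_groups - 1; df2 <- N - k_groups
    if (df2 < 1) return(0)
    crit <- stats::qf(1 - alpha, df1, df2)
    stats::pf(crit, df1, df2, ncp = f2 * N, lower.tail = FALSE)
  }
}

#' Smallest sample size reaching a target power
#'
#' Scans n upward against the exact noncentral-t (or noncentral-F) power
#' function and returns the smallest sample size whose power meets the
#' target. Sample sizes are whole units in the design's natural currency:
#' number of pairs (paired), per-group n (independent, balanced), or
#' per-group n (between-subjects ANOVA with `k_groups` groups; for
#' partial eta squared the noncentrality is `N f^2` with
#' `f^2 = eta / (1 - eta)`).
#'
#' @param es Effect size: an [effect_size()] or a plain number on the
#'   design's d scale (eta scale for ANOVA).
#' @param design Study design.
#' @param alpha Test size, in (0, 1).
#' @param power Target power, in (0, 1); default 0.95.
#' @param tail `"two_sided"` or `"one_sided"` (t designs).
#' @param k_groups Number of groups for ANOVA designs.
#' @param n_max Search cap; exceeding it is an explicit error.
#' @return Integer sample size (>= 2).
#' @examples
#' n_for_power(0.5, "paired", alpha = 0.05, power = 0.80)  # 34 pairs
#' @export
n_for_power <- function(es, design = c("paired", "independent",
                                       "anova_between", "anova_within",
                                       "anova_mixed"),
                        alpha = 0.05, power = 0.95,
                        tail = c("two_sided", "one_sided"),
                        k_groups = 3, n_max = 1e6) {
  design <- match.arg(design)
  tail <- match.arg(tail)
  effect <- if (inherits(es, "effect_size")) es$value else es
  if (!is.finite(effect) || abs(effect) == 0)
    stop("effect size must be nonzero: power never exceeds alpha at zero ",
         "effect", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("'alpha' and 'power' must lie in (0, 1)", call. = FALSE)
  pw <- function(n) power_at_n(effect, n, design, alpha, tail, k_groups)
  # bracket by doubling, then bisect: power is monotone nondecreasing in n
  hi <- 2L
  while (pw(hi) < power) {
    if (hi >= n_max)
      stop("sample-size search exceeded n_max = ", n_max, call. = FALSE)
    hi <- min(as.integer(n_max), hi * 2L)
  }
  lo <- max(2L, hi %/% 2L)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= power) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Safeguard sample size: power on the lower confidence limit
#'
#' Powers the replication on the lower confidence limit of the original
#' effect rather than its point estimate, guarding against the original's
#' estimation uncertainty. Requires a positive lower limit; a limit at or
#' below zero means no finite sample size can guarantee the target power
#' and is an error.
#'
#' @param es An [effect_size()] whose `ci_low` is set (see
#'   [ci_of_effect()]).
#' @inheritParams n_for_power
#' @return Integer sample size, always >= the point-estimate requirement
#'   when `ci_low < value`.
#' @export
n_safeguard <- function(es, design = "paired", alpha = 0.05, power = 0.95,
                        tail = "two_sided", k_groups = 3) {
  stopifnot(inherits(es, "effect_size"))
  if (is.na(es$ci_low))
    stop("'es' carries no confidence interval; run ci_of_effect() first",
         call. = FALSE)
  if (es$ci_low <= 0)
    stop("lower confidence limit is not positive; the safeguard plan is ",
         "undefined", call. = FALSE)
  n_for_power(es$ci_low, design, alpha = alpha, power = power, tail = tail,
              k_groups = k_groups)
}

power_plan <- function(method, alpha, target_power, n_required,
                       assurance = NA_real_, note = "") {
  structure(list(method = method, alpha = alpha, target_power = target_power,
                 assurance = assurance, n_required = as.integer(n_required),
                 note = note),
            class = "power_plan")
}

#' @export
print.power_plan <- function(x, ...) {
  cat(sprintf("<power_plan> method = %s, n = %d (alpha %g, target power %g)\n",
              x$method, x$n_required, x$alpha, x$target_power))
  if (nzchar(x$note)) cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

#' Replication sample size by the three-method cascade
#'
#' Plans the replication sample size the way a replication project does
#' when only the original report is available:
#' \enumerate{
#'   \item bias/uncertainty-corrected effect ([corrected_effect()]) fed to
#'     the power calculation -- skipped when the correction signals
#'     publication bias too high;
#'   \item otherwise the observed effect, using the lower confidence limit
#'     (safeguard) when a usable interval exists, else the point estimate;
#'   \item if the resulting n is still smaller than the original's, the
#'     original sample size is simply doubled.
#' }
#' The method actually used is recorded in the returned plan.
#'
#' @param original A [study_summary()] of the original study, sufficient
#'   to form its test statistic.
#' @param alpha Replication test size (default the original's alpha).
#' @param target_power Target power, default 0.95.
#' @param assurance Assurance level for the corrected method.
#' @param use_safeguard Prefer the lower confidence limit over the point
#'   estimate in step 2 when an interval with a positive lower limit is
#'   available.
#' @param k_groups ANOVA group count.
#' @return A `"power_plan"`: `method` is one of
#'   `"bias_uncertainty_corrected"`, `"safeguard_ci"`, `"point_estimate"`,
#'   `"doubled"`; `n_required` is in the design's natural unit (pairs /
#'   per-group n).
#' @export
plan_cascade <- function(original, alpha = NULL, target_power = 0.95,
                         assurance = 0.5, use_safeguard = TRUE,
                         k_groups = 3) {
  stopifnot(inherits(original, "study_summary"))
  if (is.null(alpha)) alpha <- original$alpha
  design <- original$design
  test <- run_test_from_summary(original)
  n_orig <- original$n1
  if (is.null(n_orig)) stop("original sample size required", call. = FALSE)
  if (design == "independent" && !is.null(original$n2))
    n_orig <- max(n_orig, original$n2)
  anova <- !is_t_design(design)
  if (anova) k_groups <- if (!is.null(original$df1)) original$df1 + 1 else k_groups
  # for ANOVA the cascade compares per-group n against per-group original n
  n_orig_unit <- if (anova) ceiling(n_orig / k_groups) else n_orig

  notes <- character(0)
  n_req <- NULL; method <- NULL

  corrected <- tryCatch(
    corrected_effect(test$statistic,
                     df = if (anova) test$df2 else test$df1,
                     alpha = original$alpha, assurance = assurance,
                     design = design,
                     n1 = original$n1, n2 = original$n2,
                     df1 = if (anova) test$df1 else 1),
    PublicationBiasTooHigh = function(e) {
      notes <<- c(notes, "bias/uncertainty correction undefined (publication bias too high)")
      NULL
    })
  if (!is.null(corrected)) {
    method <- "bias_uncertainty_corrected"
    n_req <- n_for_power(corrected, design, alpha = alpha,
                         power = target_power, tail = original$tail,
                         k_groups = k_groups)
  } else {
    es <- if (anova)
      peta_from_F(test$statistic, test$df1, test$df2)
    else
      d_from_t(test$statistic, design, n1 = original$n1, n2 = original$n2)
    used_safeguard <- FALSE
    if (use_safeguard) {
      es_ci <- tryCatch(ci_of_effect(es, original), error = function(e) NULL)
      if (!is.null(es_ci) && !is.na(es_ci$ci_low) && es_ci$ci_low > 0) {
        # a lower limit within rounding of zero can demand an unattainable
        # sample size; fall through to the point estimate in that case
        n_sg <- tryCatch(
          n_for_power(es_ci$ci_low, design, alpha = alpha,
                      power = target_power, tail = original$tail,
                      k_groups = k_groups),
          error = function(e) {
            notes <<- c(notes,
                        "safeguard limit too close to zero; using point estimate")
            NULL
          })
        if (!is.null(n_sg)) {
          method <- "safeguard_ci"
          n_req <- n_sg
          used_safeguard <- TRUE
        }
      }
    }
    if (!used_safeguard) {
      method <- "point_estimate"
      n_req <- n_for_power(es, design, alpha = alpha, power = target_power,
                           tail = original$tail, k_groups = k_groups)
    }
  }
  if (n_req < n_orig_unit) {
    notes <- c(notes, sprintf(
      "%s gave n = %d < original n = %d; original sample size doubled",
      method, n_req, n_orig_unit))
    method <- "doubled"
    n_req <- 2L * n_orig_unit
  }
  power_plan(method, alpha, target_power, n_req, assurance,
             note = paste(notes, collapse = "; "))
}

#' Power of a replication planned from the original's p-value
#'
#' Estimates the power a replication of size `n_replication` had, assuming
#' the original effect estimate (back-solved from its p-value at
#' `n_original`) -- or its bias/uncertainty-corrected version -- is the
#' truth. The gap between the two correction settings quantifies how
#' optimistic naive "power at the published effect" calculations are for
#' originals that only just reached significance.
#'
#' @param original_p Original two-sided p-value in (0, 1\]; p = 1 means a
#'   zero observed effect, for which the power equals alpha.
#' @param n_original,n_replication Sample sizes in the design's natural
#'   unit (pairs / per-group n).
#' @param design Study design (t designs).
#' @param alpha Test size of the replication.
#' @param correction `"none"` (power at the observed effect) or
#'   `"bias_uncertainty"` (power at the [corrected_effect()]).
#' @param assurance Assurance for the corrected variant.
#' @return Estimated power in (0, 1).
#' @export
replication_power <- function(original_p, n_original, n_replication,
                              design = c("paired", "independent"),
                              alpha = 0.05,
                              correction = c("none", "bias_uncertainty"),
                              assurance = 0.5) {
  design <- match.arg(design)
  correction <- match.arg(correction)
  if (!is.finite(original_p) || original_p <= 0 || original_p > 1)
    stop("'original_p' must lie in (0, 1]", call. = FALSE)
  df <- if (design == "paired") n_original - 1 else 2 * n_original - 2
  tobs <- stats::qt(1 - original_p / 2, df)
  if (correction == "none") {
    effect <- if (design == "paired") tobs / sqrt(n_original)
              else tobs * sqrt(2 / n_original)
    if (effect == 0) return(alpha)       # p = 1 boundary
  } else {
    n2 <- if (design == "independent") n_original else NULL
    es <- corrected_effect(tobs, df, alpha = alpha, assurance = assurance,
                           design = design, n1 = n_original, n2 = n2)
    effect <- es$value
  }
  power_at_n(effect, n_replication, design, alpha = alpha)
}
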