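#' Re-run a study's hypothesis test from its summary statistics
#'
#' Applies the same test the original report used, from summaries alone:
#' paired designs use `t = mean_diff / (sd_diff / sqrt(n))` with `df = n-1`
#' (difference-score mean/SD derived from the condition means, SDs and
#' pairwise correlation when not given directly); independent designs use
#' the pooled-variance t with `df = n1 + n2 - 2`; ANOVA designs take the
#' provided F and its degrees of freedom. The p-value comes from the
#' reference distribution at the summary's stated tail, and significance is
#' judged strictly (`p < alpha`) at the summary's alpha.
#'
#' @param summary A [study_summary()].
#' @return An object of class `"test_result"`: a list with `statistic`,
#'   `df1`, `df2` (ANOVA only), `p`, `direction` (`"positive"`,
#'   `"negative"` or `"undefined"`), `significant`, and `alpha`.
#' @export
run_test_from_summary <- function(summary) {
  stopifnot(inherits(summary, "study_summary"))
  design <- summary$design
  alpha <- summary$alpha

  if (is_t_design(design)) {
    if (design == "paired") {
      md <- summary$mean_diff; sdd <- summary$sd_diff
      if ((is.null(md) || is.null(sdd)) &&
          !is.null(summary$mean1) && !is.null(summary$mean2) &&
          !is.null(summary$sd1) && !is.null(summary$sd2) &&
          !is.null(summary$r_pairs)) {
        md <- summary$mean1 - summary$mean2
        sdd <- sqrt(summary$sd1^2 + summary$sd2^2 -
                      2 * summary$r_pairs * summary$sd1 * summary$sd2)
      }
      n <- summary$n1
      if (!is.null(md) && !is.null(sdd) && !is.null(n)) {
        t <- md / (sdd / sqrt(n)); df <- n - 1
      } else if (!is.null(summary$t_value)) {
        t <- summary$t_value
        df <- if (!is.null(summary$df1)) summary$df1 else n - 1
        if (is.null(df)) stop("cannot determine df for paired test", call. = FALSE)
      } else {
        stop("paired design needs mean_diff/sd_diff (or means, SDs and ",
             "r_pairs) with n, or a t_value", call. = FALSE)
      }
    } else {
      n1 <- summary$n1; n2 <- summary$n2
      if (!is.null(summary$mean1) && !is.null(summary$mean2) &&
          !is.null(summary$sd1) && !is.null(summary$sd2) &&
          !is.null(n1) && !is.null(n2)) {
        sp2 <- ((n1 - 1) * summary$sd1^2 + (n2 - 1) * summary$sd2^2) /
          (n1 + n2 - 2)
        t <- (summary$mean1 - summary$mean2) /
          sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- n1 + n2 - 2
      } else if (!is.null(summary$t_value)) {
        t <- summary$t_value
        df <- if (!is.null(summary$df1)) summary$df1 else n1 + n2 - 2
      } else {
        stop("independent design needs means/SDs with both n's, or a t_value",
             call. = FALSE)
      }
    }
    p <- if (summary$tail == "two_sided") 2 * stats::pt(-abs(t), df)
         else stats::pt(t, df, lower.tail = FALSE)
    direction <- if (t > 0) "positive" else if (t < 0) "negative" else "undefined"
    res <- list(statistic = t, df1 = df, df2 = NULL, p = p,
                direction = direction, significant = p < alpha, alpha = alpha)
  } else {
    Fv <- summary$F_value; df1 <- summary$df1; df2 <- summary$df2
    if (is.null(Fv) || is.null(df1) || is.null(df2))
      stop("ANOVA design needs F_value, df1 and df2", call. = FALSE)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    # direction only defined for a two-level main effect with stated means
    direction <- "undefined"
    if (df1 == 1 && !is.null(summary$mean1) && !is.null(summary$mean2)) {
      dmn <- summary$mean1 - summary$mean2
      if (dmn != 0) direction <- if (dmn > 0) "positive" else "negative"
    }
    res <- list(statistic = Fv, df1 = df1, df2 = df2, p = p,
                direction = direction, significant = p < alpha, alpha = alpha)
  }
  structure(res, class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  lab <- if (is.null(x$df2)) sprintf("t(%g) = %.3f", x$df1, x$statistic)
         else sprintf("F(%g, %g) = %.3f", x$df1, x$df2, x$statistic)
  cat(sprintf("<test_result> %s, p = %.4g, %ssignificant at alpha = %g\n",
              lab, x$p, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Remove extreme outliers by interquartile-range fences
#'
#' Single-pass Tukey-fence filter: values outside
#' `[Q1 - m*IQR, Q3 + m*IQR]` are dropped, with `m = 3` (the "extreme
#' outlier" convention) by default and quartiles by linear interpolation
#' (`stats::quantile` type 7). With fewer than four values quartiles are
#' not estimable, so the data pass through unchanged with a warning. The
#' filter is applied once, not iterated on the reduced sample.
#'
#' @param values Numeric vector.
#' @param multiplier Fence multiplier on the IQR (default 3).
#' @param type Quartile estimation type, passed to [stats::quantile()].
#' @return A list with `kept` (surviving values, original order) and
#'   `removed` (integer indices of dropped values).
#' @export
iqr_outlier_filter <- function(values, multiplier = 3, type = 7) {
  stopifnot(is.numeric(values))
  if (length(values) < 4L) {
    warning("fewer than 4 values; outlier filter not applied", call. = FALSE)
    return(list(kept = values, removed = integer(0)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - multiplier * iqr
  hi <- q[2] + multiplier * iqr
  out <- which(values < lo | values > hi)
  list(kept = if (length(out)) values[-out] else values, removed = out)
}

comparison_result <- function(z, alpha = 0.05) {
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(z = z, p_one_tailed = p, compatible = p > alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> z = %.3f, one-tailed p = %.4g: effects %s\n",
              x$z, x$p_one_tailed,
              if (x$compatible) "compatible" else "incompatible"))
  invisible(x)
}

#' Compatibility Z-test for two effect-size estimates
#'
#' Tests whether the original effect estimate is significantly larger than
#' the replication's:
#' `z = (d_original - d_replication) / sqrt(SE_original^2 + SE_replication^2)`,
#' with a one-tailed p-value `1 - Phi(z)`. The pair is judged compatible
#' when the one-tailed p exceeds 0.05 (fixed, regardless of the original
#' test's alpha).
#'
#' @param es_original,es_replication [effect_size()] objects of the same
#'   kind and orientation, both with positive `se`.
#' @return A `"comparison_result"`: list with `z`, `p_one_tailed`,
#'   `compatible`.
#' @export
z_compare <- function(es_original, es_replication) {
  stopifnot(inherits(es_original, "effect_size"),
            inherits(es_replication, "effect_size"))
  if (es_original$kind != es_replication$kind)
    stop("effect kinds differ ('", es_original$kind, "' vs '",
         es_replication$kind, "'); compare like with like", call. = FALSE)
  if (es_original$kind == "partial_eta_sq")
    stop("use fisherz_compare_peta() for partial eta squared", call. = FALSE)
  se_o <- es_original$se; se_r <- es_replication$se
  if (is.na(se_o) || is.na(se_r) || se_o <= 0 || se_r <= 0)
    stop("both effects need positive standard errors", call. = FALSE)
  comparison_result((es_original$value - es_replication$value) /
                      sqrt(se_o^2 + se_r^2))
}

#' Fisher-z compatibility test for partial eta squared
#'
#' Partial eta squared lives on a bounded scale, so the comparison is made
#' on the Fisher-z transform of `r = sqrt(eta_p^2)`:
#' `z = (atanh(r_o) - atanh(r_r)) / sqrt(1/(N_o - 3) + 1/(N_r - 3))`,
#' an approximation whose type-I error stays close to nominal under equal
#' population effects. One-tailed p and the 0.05 compatibility rule as in
#' [z_compare()].
#'
#' @param peta_original,peta_replication Partial eta squared values in
#'   \[0, 1), plain numbers or [effect_size()] objects.
#' @param N_original,N_replication Total sample sizes (> 3).
#' @return A `"comparison_result"`.
#' @export
fisherz_compare_peta <- function(peta_original, N_original,
                                 peta_replication, N_replication) {
  val <- function(x) if (inherits(x, "effect_size")) x$value else x
  eo <- val(peta_original); er <- val(peta_replication)
  if (eo < 0 || eo >= 1 || er < 0 || er >= 1)
    stop("partial eta squared must lie in [0, 1)", call. = FALSE)
  if (N_original <= 3 || N_replication <= 3)
    stop("both sample sizes must exceed 3", call. = FALSE)
  z <- (atanh(sqrt(eo)) - atanh(sqrt(er))) /
    sqrt(1 / (N_original - 3) + 1 / (N_replication - 3))
  comparison_result(z)
}

#' Four-way replication verdict
#'
#' Combines the replication's own test result, the direction agreement
#' with the original, and the effect-size compatibility test into one of
#' four verdicts:
#' \describe{
#'   \item{success}{replication significant, same direction, effects
#'     compatible}
#'   \item{practical_failure}{replication significant in the same
#'     direction, but its effect significantly smaller than the original's}
#'   \item{informative_failure}{replication not significant (or in the
#'     opposite direction) with incompatible effects; an
#'     opposite-direction significant replication is also classified here
#'     even when the magnitudes are compatible, since the direction
#'     reversal is itself informative}
#'   \item{inconclusive}{replication not significant but effects
#'     compatible}
#' }
#' Every combination of the three inputs maps to exactly one verdict.
#'
#' @param rep_test A `"test_result"` for the replication (or a logical
#'   significance flag).
#' @param same_direction Logical: did the replication effect point the
#'   same way as the original's?
#' @param comparison A `"comparison_result"` (or a logical compatibility
#'   flag).
#' @return A length-1 character of class `"replication_outcome"`: one of
#'   `"success"`, `"informative_failure"`, `"practical_failure"`,
#'   `"inconclusive"`.
#' @export
classify_outcome <- function(rep_test, same_direction, comparison) {
  significant <- if (inherits(rep_test, "test_result")) rep_test$significant
                 else isTRUE(rep_test)
  compatible <- if (inherits(comparison, "comparison_result"))
    comparison$compatible else isTRUE(comparison)
  stopifnot(is.logical(same_direction), length(same_direction) == 1L,
            !is.na(same_direction))
  verdict <- if (significant && same_direction) {
    if (compatible) "success" else "practical_failure"
  } else if (significant && !same_direction) {
    "informative_failure"
  } else {                       # replication not significant
    if (compatible) "inconclusive" else "informative_failure"
  }
  structure(verdict, class = "replication_outcome")
}

#' @export
print.replication_outcome <- function(x, ...) {
  cat("<replication_outcome>", unclass(x), "\n")
  invisible(x)
}

replication_verdicts <- c("success", "informative_failure",
                          "practical_failure", "inconclusive")
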