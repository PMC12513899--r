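#' Standardized mean difference from a t statistic
#'
#' Recomputes the design-appropriate Cohen's d from a reported t value and
#' sample size(s): `d_z = t / sqrt(n)` for paired designs (denominator the
#' SD of the difference scores) and `d_s = t * sqrt(1/n1 + 1/n2)` for two
#' independent groups (pooled-SD denominator). The sign of the effect
#' follows the sign of t.
#'
#' @param t Reported t statistic.
#' @param design `"paired"` or `"independent"`.
#' @param n1 Number of pairs (paired) or group 1 size (independent).
#' @param n2 Group 2 size (independent only).
#' @param provenance Provenance tag for the result; defaults to
#'   `"computed_from_data"` since the statistic is being inverted.
#' @return An [effect_size()] of kind `"d_z"` or `"d_s"` (SE unset; see
#'   [se_of_effect()]).
#' @examples
#' d_from_t(2.5, "paired", n1 = 25)          # d_z = 0.5
#' d_from_t(2.0, "independent", n1 = 8, n2 = 8)  # d_s = 1.0
#' @export
d_from_t <- function(t, design = c("paired", "independent"),
                     n1, n2 = NULL,
                     provenance = "computed_from_data") {
  design <- match.arg(design)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("'t' must be a single finite number", call. = FALSE)
  if (design == "paired") {
    if (missing(n1) || is.null(n1) || n1 < 2)
      stop("paired design needs n1 >= 2", call. = FALSE)
    effect_size("d_z", t / sqrt(n1), provenance = provenance)
  } else {
    if (missing(n1) || is.null(n1) || is.null(n2) || n1 < 2 || n2 < 2)
      stop("independent design needs n1 and n2, both >= 2", call. = FALSE)
    effect_size("d_s", t * sqrt(1 / n1 + 1 / n2), provenance = provenance)
  }
}

#' Average-SD standardized mean difference (Cohen's d_av)
#'
#' `d_av = (mean1 - mean2) / ((sd1 + sd2) / 2)`: the paired-design variant
#' whose denominator is the plain average of the two condition SDs rather
#' than the SD of the difference scores. Frequently the only effect size a
#' paired-design report prints, and not directly comparable to d_z.
#'
#' @param mean1,mean2 Condition means.
#' @param sd1,sd2 Condition SDs (positive).
#' @inheritParams d_from_t
#' @return An [effect_size()] of kind `"d_av"`.
#' @seealso [convert_dav_to_dz()]
#' @export
dav_from_means <- function(mean1, mean2, sd1, sd2, provenance = "computed_from_data") {
  if (!all(is.finite(c(mean1, mean2, sd1, sd2))))
    stop("means and SDs must be finite", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0)
    stop("SDs must be positive", call. = FALSE)
  effect_size("d_av", (mean1 - mean2) / ((sd1 + sd2) / 2),
              provenance = provenance)
}

#' Convert a reported d_av to the design-appropriate d_z
#'
#' A paired design calls for d_z (difference-score denominator), but d_av is
#' what many reports give. With the two condition SDs and the pairwise
#' correlation the conversion is exact:
#' `sd_diff = sqrt(sd1^2 + sd2^2 - 2 r sd1 sd2)`, then
#' `d_z = d_av * ((sd1 + sd2)/2) / sd_diff`.
#'
#' When `r_pairs` is not reported it defaults to 0.5 (which leaves
#' `d_z = d_av` for equal SDs) with a warning, since assuming independence
#' would distort the conversion more than a neutral middling correlation.
#'
#' @param d_av The reported d_av, either a number or an [effect_size()].
#' @param sd1,sd2 Condition SDs (positive).
#' @param r_pairs Correlation between the paired measurements, |r| < 1.
#' @return An [effect_size()] of kind `"d_z"`.
#' @export
convert_dav_to_dz <- function(d_av, sd1, sd2, r_pairs = NULL) {
  val <- if (inherits(d_av, "effect_size")) d_av$value else d_av
  prov <- if (inherits(d_av, "effect_size")) d_av$provenance else "computed_from_data"
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  if (is.null(r_pairs)) {
    warning("'r_pairs' not supplied; assuming r = 0.5", call. = FALSE)
    r_pairs <- 0.5
  }
  if (abs(r_pairs) >= 1)
    stop("'r_pairs' must lie strictly inside (-1, 1)", call. = FALSE)
  sd_diff2 <- sd1^2 + sd2^2 - 2 * r_pairs * sd1 * sd2
  if (sd_diff2 <= .Machine$double.eps * (sd1^2 + sd2^2))
    stop("difference-score SD is zero; d_av -> d_z conversion undefined",
         call. = FALSE)
  effect_size("d_z", val * ((sd1 + sd2) / 2) / sqrt(sd_diff2),
              provenance = prov)
}

#' Hedges small-sample bias correction
#'
#' `g = d * (1 - 3 / (4 df - 1))`. The uncorrected standardized mean
#' difference overestimates its population value in small samples; the
#' correction factor shrinks the magnitude, vanishing as df grows.
#'
#' @param d An [effect_size()] of a d-family kind, or a plain number.
#' @param df Degrees of freedom of the underlying test (>= 2).
#' @return An [effect_size()] of kind `"g"`.
#' @export
hedges_correction <- function(d, df) {
  val <- if (inherits(d, "effect_size")) d$value else d
  prov <- if (inherits(d, "effect_size")) d$provenance else "computed_from_data"
  if (!is.finite(df) || df < 2) stop("'df' must be >= 2", call. = FALSE)
  effect_size("g", val * (1 - 3 / (4 * df - 1)), provenance = prov)
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F df1 / (F df1 + df2)`: the share of effect-plus-error
#' variance attributed to the tested ANOVA effect, recoverable from the
#' printed F test alone. Equals `SS_effect / (SS_effect + SS_error)`.
#'
#' @param F_value Nonnegative F statistic.
#' @param df1 Effect degrees of freedom.
#' @param df2 Error degrees of freedom.
#' @inheritParams d_from_t
#' @return An [effect_size()] of kind `"partial_eta_sq"`, in \[0, 1).
#' @export
peta_from_F <- function(F_value, df1, df2, provenance = "computed_from_data") {
  if (!is.finite(F_value) || F_value < 0)
    stop("'F_value' must be a nonnegative number", call. = FALSE)
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  effect_size("partial_eta_sq", F_value * df1 / (F_value * df1 + df2),
              provenance = provenance)
}

#' Standard error of a standardized effect size
#'
#' Fills the `se` field with the large-sample (delta-method) standard error
#' used by the compatibility Z-test:
#' \describe{
#'   \item{d_z}{`sqrt(1/n + d^2/(2n))`, n the number of pairs}
#'   \item{d_s / g}{`sqrt((n1+n2)/(n1 n2) + d^2/(2(n1+n2)))`}
#'   \item{partial_eta_sq}{`1/sqrt(N-3)` on the Fisher-z scale of
#'     `r = sqrt(eta_p^2)`, N the total sample size}
#' }
#' These approximate the sampling SD of the bias-corrected estimator; the
#' `variant = "small_sample"` option multiplies the d-family SE by
#' `sqrt(df/(df-2))`, which tracks the raw (uncorrected) estimator's spread
#' more closely at small n.
#'
#' @param es An [effect_size()].
#' @param summary The [study_summary()] the effect came from (supplies n's).
#' @param variant `"large_sample"` (default) or `"small_sample"`.
#' @return The effect size with `se` filled in.
#' @export
se_of_effect <- function(es, summary,
                         variant = c("large_sample", "small_sample")) {
  stopifnot(inherits(es, "effect_size"), inherits(summary, "study_summary"))
  variant <- match.arg(variant)
  d <- es$value
  kind <- es$kind
  if (kind == "d_av")
    stop("no SE defined for d_av; convert to d_z first ",
         "(see convert_dav_to_dz)", call. = FALSE)
  if (kind == "partial_eta_sq") {
    N <- total_n(summary)
    if (N <= 3) stop("total sample size must exceed 3 for the Fisher-z SE",
                     call. = FALSE)
    es$se <- 1 / sqrt(N - 3)
    return(es)
  }
  if (kind == "d_z" || (kind == "g" && summary$design == "paired")) {
    n <- summary$n1
    if (is.null(n) || n < 2) stop("paired design needs n1 >= 2", call. = FALSE)
    se <- sqrt(1 / n + d^2 / (2 * n))
    df <- n - 1
  } else {                                   # d_s, or g from two groups
    n1 <- summary$n1; n2 <- summary$n2
    if (is.null(n1) || is.null(n2) || n1 < 2 || n2 < 2)
      stop("independent design needs n1 and n2, both >= 2", call. = FALSE)
    se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
    df <- n1 + n2 - 2
  }
  if (variant == "small_sample") {
    if (df <= 2) stop("small-sample SE needs df > 2", call. = FALSE)
    se <- se * sqrt(df / (df - 2))
  }
  es$se <- se
  es
}

# solve for the noncentrality parameter ncp such that
# pdist(stat; ncp) == prob, where pdist is monotone decreasing in ncp.
# Returns `lower` if even the lower endpoint gives too small a probability.
solve_ncp <- function(pdist, stat, prob, lower, upper, tol = 1e-8) {
  # pt/pf with ncp warn about ~1e-12 precision loss in extreme tails;
  # immaterial at the tolerances used here
  f <- function(ncp) suppressWarnings(pdist(stat, ncp)) - prob
  if (f(lower) < 0) return(lower)
  while (f(upper) > 0) {
    lower <- upper
    upper <- 2 * abs(upper) + 10
    if (upper > 1e6) stop("noncentrality search failed to bracket",
                          call. = FALSE)
  }
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

#' Confidence interval for a standardized effect size
#'
#' Forms the CI by inverting the noncentral distribution of the test
#' statistic (the pivot method): the bounds are the noncentrality
#' parameters at which the observed statistic sits at the upper/lower
#' tail quantiles, mapped back to the effect scale. For
#' `partial_eta_sq` the noncentral-F inversion is used and the lower
#' bound is floored at 0; its default level is 90% (matching the
#' one-sided logic of the F test), while d-family effects default to a
#' 95% two-sided interval.
#'
#' @param es An [effect_size()] of kind d_z, d_s, g or partial_eta_sq.
#' @param summary The originating [study_summary()].
#' @param level Confidence level in (0, 1); `NULL` picks the kind-specific
#'   default (0.95 d-family, 0.90 eta).
#' @return The effect size with `ci_low`, `ci_high`, `ci_level` filled in.
#' @export
ci_of_effect <- function(es, summary, level = NULL) {
  stopifnot(inherits(es, "effect_size"), inherits(summary, "study_summary"))
  if (is.null(level))
    level <- if (es$kind == "partial_eta_sq") 0.90 else 0.95
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)", call. = FALSE)
  tail_lo <- (1 - level) / 2
  tail_hi <- 1 - tail_lo

  if (es$kind == "partial_eta_sq") {
    df1 <- summary$df1; df2 <- summary$df2
    if (is.null(df1) || is.null(df2))
      stop("df1 and df2 required for a partial eta squared CI", call. = FALSE)
    eta <- es$value
    if (eta >= 1) stop("partial eta squared of 1 has no finite CI", call. = FALSE)
    Fobs <- eta * df2 / ((1 - eta) * df1)
    pF <- function(stat, ncp) stats::pf(stat, df1, df2, ncp = ncp)
    lam_hi <- solve_ncp(pF, Fobs, tail_lo, 0, 4 * (Fobs + 1) * df1 + 20)
    lam_lo <- solve_ncp(pF, Fobs, tail_hi, 0, 4 * (Fobs + 1) * df1 + 20)
    to_eta <- function(lam) lam / (lam + df1 + df2 + 1)
    es$ci_low <- max(0, to_eta(lam_lo))
    es$ci_high <- to_eta(lam_hi)
  } else if (es$kind %in% c("d_z", "d_s", "g")) {
    paired <- summary$design == "paired"
    if (paired) {
      n <- summary$n1
      if (is.null(n) || n < 2) stop("paired design needs n1 >= 2", call. = FALSE)
      mult <- 1 / sqrt(n); df <- n - 1
    } else {
      n1 <- summary$n1; n2 <- summary$n2
      if (is.null(n1) || is.null(n2))
        stop("independent design needs n1 and n2", call. = FALSE)
      mult <- sqrt(1 / n1 + 1 / n2); df <- n1 + n2 - 2
    }
    J <- if (es$kind == "g") 1 - 3 / (4 * df - 1) else 1
    tobs <- es$value / (J * mult)
    pT <- function(stat, ncp) stats::pt(stat, df, ncp = ncp)
    span <- abs(tobs) + 10
    ncp_hi <- solve_ncp(pT, tobs, tail_lo, -span, span)
    ncp_lo <- solve_ncp(pT, tobs, tail_hi, -span, span)
    es$ci_low <- ncp_lo * mult * J
    es$ci_high <- ncp_hi * mult * J
  } else {
    stop("no CI method for effect kind '", es$kind, "'", call. = FALSE)
  }
  es$ci_level <- level
  # numerical guard: inversion can land epsilon-outside at the boundary
  es$ci_low <- min(es$ci_low, es$value)
  es$ci_high <- max(es$ci_high, es$value)
  es
}

#' Smallest plausible effect size from a relative p-value bound
#'
#' Many reports give only "p < 0.05" (or 0.01, 0.001). The most
#' conservative effect consistent with such a bound places the test
#' statistic exactly at the bound's critical value, so the returned
#' magnitude is a lower envelope: any exact p strictly below the bound
#' implies a larger effect. With `p_bound = "exact"` the statistic is
#' back-solved from the reported p, which reproduces the statistic-based
#' computation exactly.
#'
#' @param p_bound `"lt_05"`, `"lt_01"`, `"lt_001"` or `"exact"`.
#' @param summary A [study_summary()] carrying the design, sample sizes,
#'   degrees of freedom, tail, and (for `"exact"`) the p-value.
#' @return An [effect_size()] with provenance `"estimated"` (kind d_z, d_s
#'   or partial_eta_sq according to the design).
#' @export
es_from_p_bound <- function(p_bound = c("lt_05", "lt_01", "lt_001", "exact"),
                            summary) {
  p_bound <- match.arg(p_bound)
  stopifnot(inherits(summary, "study_summary"))
  design <- summary$design

  if (is_t_design(design)) {
    df <- summary$df1
    if (is.null(df))
      df <- if (design == "paired") {
        if (is.null(summary$n1)) stop("df or n required", call. = FALSE)
        summary$n1 - 1
      } else {
        if (is.null(summary$n1) || is.null(summary$n2))
          stop("df or both n's required", call. = FALSE)
        summary$n1 + summary$n2 - 2
      }
    p <- switch(p_bound,
                lt_05 = 0.05, lt_01 = 0.01, lt_001 = 0.001,
                exact = summary$p_value)
    if (is.null(p)) stop("exact p-bound requires 'p_value'", call. = FALSE)
    tcrit <- if (summary$tail == "two_sided") stats::qt(1 - p / 2, df)
             else stats::qt(1 - p, df)
    es <- d_from_t(tcrit, design, n1 = summary$n1, n2 = summary$n2,
                   provenance = "estimated")
  } else {
    df1 <- summary$df1; df2 <- summary$df2
    if (is.null(df1) || is.null(df2))
      stop("df1 and df2 required for an F-based bound", call. = FALSE)
    p <- switch(p_bound,
                lt_05 = 0.05, lt_01 = 0.01, lt_001 = 0.001,
                exact = summary$p_value)
    if (is.null(p)) stop("exact p-bound requires 'p_value'", call. = FALSE)
    Fcrit <- stats::qf(1 - p, df1, df2)
    es <- peta_from_F(Fcrit, df1, df2, provenance = "estimated")
  }
  if (p_bound == "exact") es$provenance <- "computed_from_data"
  es
}
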