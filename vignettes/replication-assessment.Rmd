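---
title: "Assessing replications from reported summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing replications from reported summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliscore)
```

## The problem

Replication projects in fields with poor data-sharing norms — sports and
exercise science being a prominent example — rarely get raw data from
original authors. What they reliably have is what the published report
prints: sample sizes, condition means and SDs, a t or F statistic with (or
without) degrees of freedom, and a p-value that may only be stated as a
bound ("p < .05"). repliscore implements a complete replication-assessment
pipeline on exactly that information, and pairs it with a
publication-bias-aware simulator so that every inferential step can be
validated by Monte Carlo without any external data.

The pipeline, per study pair:

1. re-run the replication's hypothesis test from summaries
   (`run_test_from_summary()`), at the original study's alpha, after an
   extreme-outlier screen when raw replication values are available
   (`iqr_outlier_filter()`);
2. recompute the design-appropriate standardized effect size for both
   studies (`d_from_t()`, `peta_from_F()`, and the `d_av` to `d_z`
   conversion), with standard errors (`se_of_effect()`) and
   noncentrality-based confidence intervals (`ci_of_effect()`);
3. compare the two effects with a one-tailed compatibility Z-test
   (`z_compare()`; `fisherz_compare_peta()` for ANOVA effects);
4. classify the pair into a four-way verdict (`classify_outcome()`);
5. aggregate verdicts and magnitude changes over the whole project
   (`aggregate_project()`).

## Effect sizes and their uncertainty

Three Cohen's d variants differ only in the denominator: `d_z` uses the SD
of the paired difference scores, `d_s` the pooled SD of two independent
groups, `d_av` the plain average of two condition SDs. Only `d_z` and
`d_s` are the design-appropriate inputs to the compatibility test; a
reported `d_av` is converted via the difference-score SD,

$$ \mathrm{SD}_\mathrm{diff} = \sqrt{sd_1^2 + sd_2^2 - 2 r\, sd_1 sd_2},
\qquad d_z = d_{av}\,\frac{(sd_1+sd_2)/2}{\mathrm{SD}_\mathrm{diff}}, $$

which needs the pairwise correlation \(r\). When \(r\) is unreported the
package assumes \(r = 0.5\) — the value at which \(d_z = d_{av}\) for
equal SDs — and warns, because assuming independence (\(r = 0\)) distorts
the conversion more than a neutral middling correlation. For ANOVA main
effects the effect size is partial eta squared,
\(\hat\eta^2_p = F\,df_1/(F\,df_1 + df_2)\).

**Standard errors.** The compatibility test needs a standard error for
each effect, and reports never print one. The package uses the
large-sample delta-method family:
\(\mathrm{SE}(d_z) = \sqrt{1/n + d^2/2n}\),
\(\mathrm{SE}(d_s) = \sqrt{(n_1+n_2)/n_1 n_2 + d^2/2(n_1+n_2)}\),
and for partial eta squared the Fisher-z-scale variance \(1/(N-3)\) of
\(\operatorname{atanh}\sqrt{\eta^2_p}\). Alternative small-sample variants
exist; `se_of_effect(variant = "small_sample")` multiplies the d-family SE
by \(\sqrt{df/(df-2)}\). A point worth being precise about: the raw
estimator \(\hat d = t/\sqrt{n}\) is biased upward by the factor
\(1/J\), \(J = 1 - 3/(4\,df - 1)\), and its sampling SD is inflated by
the same factor, so the large-sample SE tracks the spread of the
*bias-corrected* (Hedges) estimator. At \(n = 20\), \(d = 0.5\) the
large-sample SE sits within about 3% of the Monte Carlo SD of the
corrected estimator but about 6% below that of the raw one; the package's
simulation tests therefore validate the SE against the corrected
estimator's spread.

**Confidence intervals** come from inverting the noncentral t (or F)
distribution of the test statistic — the pivot construction — rather than
from a normal approximation, so they are asymmetric where they should be
and respect the \([0,1)\) boundary of \(\eta^2_p\) (whose lower limit is
floored at 0). Defaults: 95% two-sided for the d family, 90% for
\(\eta^2_p\), the convention matching the one-sided logic of the F test.

**Conservative estimation from p-value bounds.** When a report gives only
"p < .05" with no statistic, `es_from_p_bound()` places the statistic at
the bound's critical value and converts. This is a deliberate lower
envelope: any exact p below the bound implies a larger magnitude, so
downstream compatibility tests lean toward finding the original *smaller*
— a conservative direction when the question is whether original effects
were inflated. Such effects carry `provenance = "estimated"`. A reported
"p = 0.000" is treated as the bound p < .001.

## The compatibility test and the four-way verdict

Two effect estimates of the same kind are compared with

$$ z = \frac{d_\mathrm{original} - d_\mathrm{replication}}
            {\sqrt{SE^2_\mathrm{original} + SE^2_\mathrm{replication}}}, $$

read against a one-tailed normal threshold at 0.05: the question is
whether the original effect is significantly *larger*, not merely
different. For partial eta squared the same comparison runs on the
Fisher-z transform of \(r = \sqrt{\eta^2_p}\) with variance
\(1/(N-3)\) per study — an approximation, but one whose empirical type-I
error stays within [0.04, 0.06] at nominal 0.05 in this package's
simulations (equal population effects, N = 30 vs 60). The compatibility
alpha is fixed at 0.05 one-tailed regardless of the original test's
alpha.

The verdict combines three binaries — replication significance (strict
`p < alpha`, at the original's alpha), direction agreement, and
compatibility:

| significant | same direction | compatible | verdict |
|---|---|---|---|
| yes | yes | yes | success |
| yes | yes | no  | practical_failure |
| yes | no  | any | informative_failure |
| no  | any | yes | inconclusive |
| no  | any | no  | informative_failure |

Two cells deserve comment, because the verbal definitions in common use
do not enumerate them. A significant replication in the *opposite*
direction is classified `informative_failure` even when the magnitudes
are compatible: the direction reversal is the informative finding, and
calling such a pair a success or merely inconclusive would be
indefensible. And direction for omnibus F tests with more than two levels
is undefined, so `same_direction` defaults to `TRUE` there — the verdict
then rests on significance and compatibility alone.

## Planning replication sample sizes

`plan_cascade()` reproduces the three-method planning cascade replication
projects use when only the original report exists:

1. **Bias/uncertainty-corrected** (`corrected_effect()`): a published
   significant statistic is a draw from its sampling distribution
   *truncated at the significance threshold*. The correction solves for
   the noncentrality under which the observed statistic sits at the
   `1 - assurance` quantile of that truncated distribution (default
   assurance 0.5: median-corrected). When the observed statistic is close
   enough to the critical value that the solution is non-positive, the
   method has no output — the observation is explainable by selection
   alone — and a `PublicationBiasTooHigh` condition is signalled.
2. **Observed effect**: power on the original's effect estimate, using
   the lower confidence limit when it is usefully positive (the safeguard
   plan), else the point estimate.
3. **Doubling**: if the resulting n is still below the original's, the
   original sample size is doubled. This step always succeeds, which is
   exactly its danger: `replication_power()` shows that for an original
   with p = 0.03 at n = 17, a doubled replication has corrected power far
   below any 95% target. The package asserts this as an inequality
   (< 0.90) rather than a point value, because the corrected power
   depends on the assurance convention.

Sample-size searches run on exact noncentral-t/F power functions
(bracketing by doubling, then bisection; cap \(10^6\) with an explicit
error). Sample sizes are whole units in the design's natural currency —
pairs, or per-group n (balanced) — and ANOVA power uses
\(\lambda = N f^2\) with \(f^2 = \eta^2/(1-\eta^2)\).

## What the simulator emulates — and what it does not

`simulate_project()` generates the situation the pipeline is built for:

- **Designs** allocated exactly by largest remainder over the configured
  mix (default 10 paired / 1 independent / 14 three-group ANOVA out of
  25, the composition of the project pool this package models).
- **Small originals**: total sample sizes `4 + Poisson(13)`, mean 17.
- **Publication-bias selection**: candidate originals (true effect,
  sample size, data) are redrawn until one is significant at 0.05; only
  that one is "published". Selection therefore distorts both the observed
  and the true-effect distribution of the pool, as it does in a real
  literature.
- **True effects** drawn from Normal(0.2, 0.2) truncated at 0 on the d
  scale. This is a calibration choice, not an empirical estimate: under
  it, selected originals mostly show "large" observed effects while true
  effects are modest, matching the qualitative signature of a
  significance-filtered literature. ANOVA effects use the two-group
  equivalence \(f = d/2\) spread over symmetric group means.
- **Replication sizes** by doubling (default) or the full cascade; the
  replication shares the original's true effect and design and is *not*
  selection-filtered.
- **Reproducibility**: one root seed; per-study child seeds are drawn up
  front, so studies are independent and a project is a pure function of
  its configuration.

Real data differ in ways the simulator deliberately ignores: outcomes are
not exactly normal, factorial designs are collapsed to the tested main
effect, within-subject ANOVA structure is not modelled (ANOVA studies are
simulated between-subjects with 3 groups), questionable research
practices beyond significance selection (p-hacking, optional stopping)
are absent, and true original and replication effects are identical
rather than heterogeneous. Passing Monte Carlo tests therefore validates
the pipeline's statistics under its stated assumptions; it does not
certify any empirical replication rate.

Under the default configuration, regression to the mean is strong: across
simulated projects well over 70% of pairs (about 95% under the default
calibration) show a smaller replication magnitude, with a median
percentage decrease around 70–80% — the same order as published
replication projects report, though this agreement reflects the
calibration's realism, not a fitted quantity.

## Numerical choices and degenerate inputs

- Quantile convention for the outlier fences: linear interpolation
  (`stats::quantile` type 7), multiplier 3 ("extreme" fences); both are
  parameters. Fewer than 4 values pass through with a warning; the filter
  is single-pass.
- Noncentrality root-finding: bisection via `uniroot` to absolute
  tolerance 1e-8 on the probability scale, with doubling bracket
  expansion; the known sub-1e-12 precision warnings of R's noncentral
  CDFs in extreme tails are suppressed inside the solver.
- Significance is strict (`p < alpha`): a p exactly at alpha is not
  significant.
- `d_av` to `d_z` conversion errors when the difference-score variance is
  numerically zero (r at 1 with equal SDs).
- Zero effect in a power calculation is an error (power never exceeds
  alpha); p = 1 in `replication_power()` is the zero-effect boundary and
  returns alpha.
- Project tables serialise missing optional fields as empty cells and
  read them back as `NA`, never 0; parse failures name the row and
  column.

## Problem sizes used in validation

The package's tests validate SEs against 20,000-replicate Monte Carlo
SDs, CI coverage over 5,000 replicates, type-I error of both
compatibility tests over 10,000 null replicates, and the
regression-to-the-mean behaviour over 5,000 simulated 25-study projects;
`scripts/acceptance.R` recomputes the headline quantities over 2,000
projects (50,000 pairs). These sizes keep each Monte Carlo standard error
at least an order of magnitude below the tolerance it checks.
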