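#' Configuration for the study-pair simulator
#'
#' Collects every knob of the synthetic replication project in one place.
#' The defaults emulate the study pool the assessment pipeline is built
#' for: a 25-study project composed of 10 paired-design, 1 independent
#' two-group and 14 ANOVA studies; small originals (sample sizes
#' `4 + Poisson(13)`, mean 17); originals admitted to the pool only when
#' their own test is significant at 0.05 (publication-bias selection);
#' replication sample sizes set by doubling the original's; true effects
#' drawn from a Normal(0.2, 0.2) on the d scale, truncated at zero --
#' a stand-in calibration under which the selected originals mostly show
#' "large" observed effects, as replication pools drawn from a published
#' literature do.
#'
#' @param n_studies Number of original/replication pairs.
#' @param design_mix Named proportions over `paired`, `independent`,
#'   `anova` (must sum to 1).
#' @param true_effect_mean,true_effect_sd Mean and SD of the true-effect
#'   distribution on the d scale; `true_effect_sd = 0` gives a point
#'   mass. Draws are truncated at `true_effect_min`.
#' @param true_effect_min Lower truncation of the true-effect draw.
#' @param n_original_min,n_original_lambda Original sample sizes are
#'   `n_original_min + Poisson(n_original_lambda)` (defaults 4 + 13,
#'   mean 17).
#' @param selection_alpha Significance threshold an original must beat to
#'   enter the pool, in (0, 1).
#' @param planning `"doubled"` (replication n = 2 x original n) or
#'   `"cascade"` ([plan_cascade()] per study).
#' @param r_pairs Correlation between paired measurements.
#' @param k_groups Group count for ANOVA studies.
#' @param seed Integer seed; fixes the entire simulated project.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_studies = 25,
                       design_mix = c(paired = 10 / 25, independent = 1 / 25,
                                      anova = 14 / 25),
                       true_effect_mean = 0.2, true_effect_sd = 0.2,
                       true_effect_min = 0,
                       n_original_min = 4, n_original_lambda = 13,
                       selection_alpha = 0.05,
                       planning = c("doubled", "cascade"),
                       r_pairs = 0.5, k_groups = 3,
                       seed = 1L) {
  planning <- match.arg(planning)
  if (!all(c("paired", "independent", "anova") %in% names(design_mix)))
    stop("'design_mix' must be named over paired/independent/anova",
         call. = FALSE)
  design_mix <- design_mix[c("paired", "independent", "anova")]
  if (abs(sum(design_mix) - 1) > 1e-8)
    stop("'design_mix' must sum to 1", call. = FALSE)
  if (selection_alpha <= 0 || selection_alpha >= 1)
    stop("'selection_alpha' must lie in (0, 1)", call. = FALSE)
  if (abs(r_pairs) >= 1) stop("'r_pairs' must lie in (-1, 1)", call. = FALSE)
  if (n_original_min < 4) stop("'n_original_min' must be >= 4", call. = FALSE)
  structure(list(n_studies = as.integer(n_studies), design_mix = design_mix,
                 true_effect_mean = true_effect_mean,
                 true_effect_sd = true_effect_sd,
                 true_effect_min = true_effect_min,
                 n_original_min = n_original_min,
                 n_original_lambda = n_original_lambda,
                 selection_alpha = selection_alpha, planning = planning,
                 r_pairs = r_pairs, k_groups = as.integer(k_groups),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# exact integer allocation of a proportion vector by largest remainder
allocate_designs <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
  }
  rep(names(mix), times = base)
}

draw_true_effect <- function(config) {
  if (config$true_effect_sd == 0) return(config$true_effect_mean)
  repeat {
    x <- stats::rnorm(1, config$true_effect_mean, config$true_effect_sd)
    if (x >= config$true_effect_min) return(x)
  }
}

#' Simulate one study and summarise it
#'
#' Draws normal-theory raw data with a known standardized true effect and
#' returns both the raw outcomes and the [study_summary()] recomputed from
#' the draws (so the summary carries ordinary sampling error, exactly as a
#' published table would):
#' \describe{
#'   \item{paired}{bivariate normal measurements with unit variances,
#'     correlation `r_pairs`, and mean difference
#'     `true_effect * sqrt(2 (1 - r_pairs))`, i.e. `true_effect` on the
#'     d_z scale}
#'   \item{independent}{two unit-variance groups separated by
#'     `true_effect` pooled SDs (d_s scale)}
#'   \item{anova}{`k_groups` equal groups, means spaced symmetrically so
#'     Cohen's f is `true_effect / 2` (the two-group d-to-f equivalence),
#'     implying the corresponding population partial eta squared}
#' }
#'
#' @param design `"paired"`, `"independent"` or `"anova"`.
#' @param true_effect Population effect on the d scale.
#' @param n Sample size: pairs, per-group n, or per-group n respectively.
#' @param r_pairs Pairwise correlation (paired design).
#' @param k_groups ANOVA group count.
#' @param alpha Alpha recorded in the summary.
#' @return A list with `summary` (a [study_summary()]), `data` (the raw
#'   draws), `design` and `true_effect`. Uses the current RNG state.
#' @export
simulate_study <- function(design = c("paired", "independent", "anova"),
                           true_effect, n, r_pairs = 0.5, k_groups = 3,
                           alpha = 0.05) {
  design <- match.arg(design)
  if (n < 2) stop("'n' must be at least 2 per cell", call. = FALSE)
  if (abs(r_pairs) >= 1) stop("'r_pairs' must lie in (-1, 1)", call. = FALSE)

  if (design == "paired") {
    delta <- true_effect * sqrt(2 * (1 - r_pairs))
    x1 <- stats::rnorm(n)
    x2 <- r_pairs * x1 + sqrt(1 - r_pairs^2) * stats::rnorm(n) + delta
    diffs <- x2 - x1
    summary <- study_summary(
      "paired", n1 = n,
      mean1 = mean(x2), mean2 = mean(x1),
      sd1 = stats::sd(x2), sd2 = stats::sd(x1),
      mean_diff = mean(diffs), sd_diff = stats::sd(diffs),
      r_pairs = stats::cor(x1, x2),
      df1 = n - 1, alpha = alpha)
    data <- cbind(x1 = x1, x2 = x2)
  } else if (design == "independent") {
    g1 <- stats::rnorm(n)
    g2 <- stats::rnorm(n, mean = true_effect)
    summary <- study_summary(
      "independent", n1 = n, n2 = n,
      mean1 = mean(g2), mean2 = mean(g1),
      sd1 = stats::sd(g2), sd2 = stats::sd(g1),
      df1 = 2 * n - 2, alpha = alpha)
    data <- list(g1 = g1, g2 = g2)
  } else {
    k <- k_groups
    f <- true_effect / 2
    # symmetric group means scaled so the population Cohen's f equals f
    mu <- seq(-1, 1, length.out = k)
    mu <- if (f > 0) mu * f / sqrt(mean((mu - mean(mu))^2)) else mu * 0
    g <- rep(seq_len(k), each = n)
    y <- stats::rnorm(n * k) + mu[g]
    gm <- vapply(split(y, g), mean, numeric(1))
    N <- n * k
    ssb <- n * sum((gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    df1 <- k - 1; df2 <- N - k
    Fv <- (ssb / df1) / (ssw / df2)
    summary <- study_summary(
      "anova_between", n1 = N, F_value = Fv, df1 = df1, df2 = df2,
      alpha = alpha)
    data <- list(group = g, y = y)
  }
  list(summary = summary, data = data, design = design,
       true_effect = true_effect)
}

#' Simulate an original study subject to significance selection
#'
#' Publication bias, operationalised: candidate originals (design, true
#' effect, sample size and data all freshly drawn) are generated until one
#' is significant at `selection_alpha`, and only that one is "published".
#' The number of discarded candidates is returned, as is the true effect,
#' so downstream code can pair the original with a replication of the
#' same underlying effect.
#'
#' @param config A [sim_config()].
#' @param design Fix the candidate design (`"paired"`, `"independent"`,
#'   `"anova"`); by default each candidate's design is drawn from
#'   `config$design_mix`.
#' @param max_attempts Hard cap on rejection sampling (default 1e5).
#' @return A list as from [simulate_study()], plus `n` (the drawn sample
#'   size), `attempts` (candidates discarded before acceptance) and
#'   `test` (the accepted original's `"test_result"`).
#' @export
simulate_original_with_selection <- function(config, design = NULL,
                                             max_attempts = 1e5) {
  stopifnot(inherits(config, "sim_config"))
  fixed_design <- design
  for (attempt in seq_len(max_attempts)) {
    design <- if (is.null(fixed_design))
      sample(names(config$design_mix), 1, prob = config$design_mix)
    else fixed_design
    true_effect <- draw_true_effect(config)
    n_total <- config$n_original_min + stats::rpois(1, config$n_original_lambda)
    n <- switch(design,
                paired = n_total,
                independent = max(2L, round(n_total / 2)),
                anova = max(2L, round(n_total / config$k_groups)))
    study <- simulate_study(design, true_effect, n,
                            r_pairs = config$r_pairs,
                            k_groups = config$k_groups,
                            alpha = config$selection_alpha)
    test <- run_test_from_summary(study$summary)
    if (test$p < config$selection_alpha) {
      study$n <- n
      study$attempts <- attempt - 1L
      study$test <- test
      return(study)
    }
  }
  stop("no significant original found in ", max_attempts,
       " attempts; selection configuration is pathological", call. = FALSE)
}

# run the full assessment pipeline on one simulated original/replication pair
assess_pair <- function(orig, rep, k_groups) {
  to <- orig$test
  tr <- run_test_from_summary(rep$summary)
  if (orig$design == "anova") {
    es_o <- peta_from_F(to$statistic, to$df1, to$df2)
    es_r <- peta_from_F(tr$statistic, tr$df1, tr$df2)
    es_o <- se_of_effect(es_o, orig$summary)
    es_r <- se_of_effect(es_r, rep$summary)
    cmp <- fisherz_compare_peta(es_o, total_n(orig$summary),
                                es_r, total_n(rep$summary))
    same_direction <- TRUE                 # omnibus: direction undefined
  } else {
    es_o <- d_from_t(to$statistic, orig$design,
                     n1 = orig$summary$n1, n2 = orig$summary$n2)
    es_r <- d_from_t(tr$statistic, rep$design,
                     n1 = rep$summary$n1, n2 = rep$summary$n2)
    es_o <- se_of_effect(es_o, orig$summary)
    es_r <- se_of_effect(es_r, rep$summary)
    # orient both effects so the original points positive
    flip <- if (es_o$value < 0) -1 else 1
    es_o$value <- flip * es_o$value
    es_r$value <- flip * es_r$value
    cmp <- z_compare(es_o, es_r)
    same_direction <- es_r$value > 0
  }
  outcome <- classify_outcome(tr, same_direction, cmp)
  list(test_rep = tr, es_o = es_o, es_r = es_r, cmp = cmp,
       same_direction = same_direction, outcome = outcome)
}

#' Simulate a whole replication project
#'
#' Generates `n_studies` original/replication pairs -- originals passed
#' through significance selection, replication sample sizes set by the
#' configured planning rule, replications drawn from the *same* true
#' effect -- and runs the full assessment pipeline (re-test, effect-size
#' recomputation, compatibility test, four-way verdict) on each pair.
#'
#' The project's design composition is fixed, not resampled: the design
#' mix is allocated over `n_studies` by largest remainder, so the default
#' configuration always yields 10 paired, 1 independent and 14 ANOVA
#' studies, and selection rejection operates within each study's design.
#'
#' One root seed drives everything: per-study child seeds are drawn up
#' front, so each study's stream is independent of the others and the
#' project is a pure function of its configuration.
#'
#' @param config A [sim_config()].
#' @return A `"project_table"`: a data frame with one row per pair (see
#'   [project_columns()] for the schema).
#' @export
simulate_project <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  study_seeds <- sample.int(.Machine$integer.max - 1L, config$n_studies)
  designs <- allocate_designs(config$design_mix, config$n_studies)
  disciplines <- c("biomechanics", "psychology", "physiology", "nutrition",
                   "injury_prevention")
  rows <- vector("list", config$n_studies)
  for (i in seq_len(config$n_studies)) {
    set.seed(study_seeds[i])
    orig <- simulate_original_with_selection(config, design = designs[i])
    discipline <- sample(disciplines, 1)

    if (config$planning == "doubled") {
      plan <- power_plan("doubled", config$selection_alpha, 0.95,
                         2L * orig$n)
    } else {
      plan <- tryCatch(
        plan_cascade(orig$summary, alpha = config$selection_alpha,
                     k_groups = config$k_groups),
        error = function(e)
          power_plan("doubled", config$selection_alpha, 0.95, 2L * orig$n,
                     note = paste("cascade failed:",
                                  conditionMessage(e))))
    }
    rep <- simulate_study(orig$design, orig$true_effect, plan$n_required,
                          r_pairs = config$r_pairs,
                          k_groups = config$k_groups,
                          alpha = config$selection_alpha)
    a <- assess_pair(orig, rep, config$k_groups)
    rows[[i]] <- list(
      study_id = sprintf("sim-%03d", i),
      discipline = discipline,
      design = orig$summary$design,
      n_original = total_n(orig$summary),
      n_replication = total_n(rep$summary),
      true_effect = orig$true_effect,
      es_kind = a$es_o$kind,
      es_original = a$es_o$value,
      se_original = a$es_o$se,
      es_replication = a$es_r$value,
      se_replication = a$es_r$se,
      p_original = orig$test$p,
      p_replication = a$test_rep$p,
      rep_significant = a$test_rep$significant,
      same_direction = a$same_direction,
      z_comparison = a$cmp$z,
      p_comparison = a$cmp$p_one_tailed,
      compatible = a$cmp$compatible,
      outcome = unclass(a$outcome),
      pct_decrease = pct_decrease(a$es_o, a$es_r),
      plan_method = plan$method,
      selection_attempts = orig$attempts)
  }
  cols <- names(rows[[1]])
  tab <- lapply(cols, function(cl)
    unlist(lapply(rows, `[[`, cl), use.names = FALSE))
  names(tab) <- cols
  tab <- structure(tab, row.names = seq_len(config$n_studies),
                   class = c("project_table", "data.frame"))
  tab
}
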