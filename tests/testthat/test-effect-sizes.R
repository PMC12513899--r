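test_that("d from t matches its closed forms and inverts the t statistic", {
  expect_equal(d_from_t(2.5, "paired", n1 = 25)$value, 0.5)
  expect_equal(d_from_t(2.0, "independent", n1 = 8, n2 = 8)$value, 1.0)
  expect_equal(d_from_t(-2.5, "paired", n1 = 25)$value, -0.5)

  # paired differences {1..6}: the oracle computes mean/SD directly
  diffs <- 1:6
  t_obs <- mean(diffs) / (sd(diffs) / sqrt(6))
  expect_equal(d_from_t(t_obs, "paired", n1 = 6)$value,
               mean(diffs) / sd(diffs), tolerance = 1e-12)
  expect_equal(d_from_t(t_obs, "paired", n1 = 6)$value, 1.8708,
               tolerance = 1e-4)

  # inversion round-trip over a grid: t = d_z * sqrt(n) to 1e-10
  for (n in c(5, 17, 60)) for (t in c(-3.2, 0.4, 6)) {
    expect_equal(d_from_t(t, "paired", n1 = n)$value * sqrt(n), t,
                 tolerance = 1e-10)
  }
  expect_error(d_from_t(Inf, "paired", n1 = 10), "finite")
  expect_error(d_from_t(2, "independent", n1 = 10), "n1 and n2")
})

test_that("d_av and its conversion to d_z respect the difference-score SD", {
  expect_equal(dav_from_means(10, 8, 2, 2)$value, 1.0)
  expect_equal(dav_from_means(5, 5, 1, 3)$value, 0.0)
  expect_equal(dav_from_means(4, 2, 1, 3)$value, 1.0)
  expect_error(dav_from_means(1, 0, -1, 2), "positive")

  expect_equal(convert_dav_to_dz(1, 2, 2, 0.5)$value, 1.0)
  expect_equal(convert_dav_to_dz(1, 2, 2, 0)$value, 2 / sqrt(8),
               tolerance = 1e-12)
  expect_error(convert_dav_to_dz(1, 2, 2, 1 - 1e-16), "undefined")
  # unreported correlation falls back to the neutral 0.5 with a warning
  expect_warning(res <- convert_dav_to_dz(1, 2, 2), "r = 0.5")
  expect_equal(res$value, 1.0)
})

test_that("Hedges correction shrinks magnitude toward zero", {
  expect_equal(hedges_correction(1, 25)$value, 1 - 3 / 99)
  expect_equal(hedges_correction(0, 10)$value, 0)
  expect_equal(hedges_correction(1, 1e6)$value, 1, tolerance = 1e-5)
  for (df in c(2, 5, 19, 100)) for (d in c(-1.4, 0.3, 2)) {
    g <- hedges_correction(d, df)$value
    expect_lt(abs(g), abs(d))
    expect_equal(sign(g), sign(d))
  }
  expect_error(hedges_correction(1, 1), "df")
})

test_that("partial eta squared equals the sums-of-squares ratio and is monotone in F", {
  expect_equal(peta_from_F(10, 1, 10)$value, 0.5)
  expect_equal(peta_from_F(0, 2, 20)$value, 0)

  # brute-force oracle on a generated 3x5 one-way table, cross-checked
  # against anova(lm())
  set.seed(11)
  g <- rep(1:3, each = 5)
  y <- rnorm(15) + c(0, 0.5, 1)[g]
  fit <- anova(lm(y ~ factor(g)))
  eta_lm <- fit$`Sum Sq`[1] / sum(fit$`Sum Sq`)
  expect_equal(oracle_eta_from_raw(y, g), eta_lm, tolerance = 1e-12)
  expect_equal(peta_from_F(fit$`F value`[1], fit$Df[1], fit$Df[2])$value,
               eta_lm, tolerance = 1e-12)

  Fs <- seq(0, 12, by = 0.5)
  etas <- vapply(Fs, function(f) peta_from_F(f, 2, 27)$value, numeric(1))
  expect_true(all(diff(etas) > 0))
  expect_true(all(etas >= 0 & etas < 1))
  expect_error(peta_from_F(-1, 1, 10), "nonnegative")
})

test_that("analytic standard errors track Monte Carlo sampling SDs", {
  s100 <- study_summary("paired", n1 = 100, t_value = 1)
  expect_equal(se_of_effect(effect_size("d_z", 0), s100)$se, 0.1)
  s50 <- study_summary("independent", n1 = 50, n2 = 50, t_value = 1)
  expect_equal(se_of_effect(effect_size("d_s", 0), s50)$se, 0.2)

  # 20,000 simulated paired samples at d = 0.5, n = 20 (bias-corrected
  # estimator, whose spread the delta-method SE approximates)
  set.seed(101)
  mc <- sd(mc_paired_dz(20, 0.5, 20000))
  s20 <- study_summary("paired", n1 = 20, t_value = 1)
  se <- se_of_effect(effect_size("d_z", 0.5), s20)$se
  expect_lt(abs(se - mc) / mc, 0.05)

  # same for two independent groups of 20
  mc2 <- sd(mc_indep_ds(20, 20, 0.5, 20000))
  s2 <- study_summary("independent", n1 = 20, n2 = 20, t_value = 1)
  se2 <- se_of_effect(effect_size("d_s", 0.5), s2)$se
  expect_lt(abs(se2 - mc2) / mc2, 0.05)

  # eta: Fisher-z scale SE
  s3 <- study_summary("anova_between", n1 = 39, F_value = 5, df1 = 2, df2 = 36)
  expect_equal(se_of_effect(effect_size("partial_eta_sq", 0.2), s3)$se,
               1 / sqrt(36))
  expect_error(se_of_effect(effect_size("d_av", 1), s20), "convert")
})

test_that("noncentral-pivot confidence intervals are symmetric at zero and cover", {
  s20 <- study_summary("paired", n1 = 20, t_value = 1)
  e0 <- ci_of_effect(effect_size("d_z", 0), s20, level = 0.95)
  expect_equal(e0$ci_low, -e0$ci_high, tolerance = 1e-6)
  expect_lt(e0$ci_low, 0)

  # eta = 0 pins the lower limit at the boundary
  sF <- study_summary("anova_between", n1 = 30, F_value = 0, df1 = 2, df2 = 27)
  eF <- ci_of_effect(effect_size("partial_eta_sq", 0), sF)
  expect_equal(eF$ci_low, 0)

  # simulated coverage at d = 0.5, n = 20, 95% level over 5,000 replicates
  set.seed(202)
  n <- 20; d <- 0.5; reps <- 5000
  m <- matrix(rnorm(n * reps, mean = d), nrow = n)
  t_obs <- colMeans(m) / (apply(m, 2, sd) / sqrt(n))
  covered <- vapply(t_obs, function(t) {
    es <- ci_of_effect(d_from_t(t, "paired", n1 = n), s20, level = 0.95)
    es$ci_low <= d && d <= es$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("p-bound effects are conservative lower envelopes", {
  s <- study_summary("paired", n1 = 20, df1 = 19, p_bound = "lt_05")
  expect_equal(es_from_p_bound("lt_05", s)$value, qt(0.975, 19) / sqrt(20),
               tolerance = 1e-12)
  expect_equal(es_from_p_bound("lt_05", s)$value, 0.468, tolerance = 1e-3)
  expect_identical(es_from_p_bound("lt_05", s)$provenance, "estimated")

  # tighter bound implies a strictly larger magnitude
  expect_gt(es_from_p_bound("lt_001", s)$value,
            es_from_p_bound("lt_05", s)$value)

  # exact p reproduces the back-solved statistic exactly
  se <- study_summary("paired", n1 = 20, df1 = 19, p_value = 0.013)
  t_back <- qt(1 - 0.013 / 2, 19)
  expect_equal(es_from_p_bound("exact", se)$value, t_back / sqrt(20),
               tolerance = 1e-12)

  # conservativeness: over a grid of designs and exact p below the bound,
  # the bound-implied magnitude never exceeds the exact-p magnitude
  for (n in c(8, 20, 45)) {
    sB <- study_summary("paired", n1 = n, df1 = n - 1, p_bound = "lt_05")
    d_bound <- es_from_p_bound("lt_05", sB)$value
    for (p in c(0.049, 0.02, 0.004, 1e-4)) {
      sE <- study_summary("paired", n1 = n, df1 = n - 1, p_value = p)
      expect_gte(es_from_p_bound("exact", sE)$value, d_bound)
    }
  }
  for (df2 in c(10, 27, 60)) {
    sB <- study_summary("anova_between", n1 = df2 + 3, df1 = 2, df2 = df2,
                        p_bound = "lt_01")
    e_bound <- es_from_p_bound("lt_01", sB)$value
    for (p in c(0.009, 0.001)) {
      sE <- study_summary("anova_between", n1 = df2 + 3, df1 = 2, df2 = df2,
                          p_value = p)
      expect_gte(es_from_p_bound("exact", sE)$value, e_bound)
    }
  }

  # the "p = 0.000" artifact is read as the p < .001 bound
  s0 <- study_summary("paired", n1 = 20, df1 = 19, p_value = 0)
  expect_identical(s0$p_bound, "lt_001")
  expect_null(s0$p_value)
})
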