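test_that("summary-based tests reproduce direct computations on raw data", {
  # null paired case
  s0 <- run_test_from_summary(
    study_summary("paired", n1 = 10, mean_diff = 0, sd_diff = 2))
  expect_equal(s0$statistic, 0)
  expect_equal(s0$p, 1)

  # paired differences {1..6}
  s <- run_test_from_summary(
    study_summary("paired", n1 = 6, mean_diff = 3.5, sd_diff = sd(1:6)))
  expect_equal(s$statistic, 4.583, tolerance = 1e-3)
  expect_equal(s$df1, 5)
  expect_equal(s$p, 2 * pt(-s$statistic, 5), tolerance = 1e-12)
  expect_equal(s$p, 0.0059, tolerance = 1e-2)

  # round-trip against t.test() on raw draws
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(14); y <- rnorm(14, 0.6)
    tt <- t.test(y, x, paired = TRUE)
    mine <- run_test_from_summary(study_summary(
      "paired", n1 = 14, mean_diff = mean(y - x), sd_diff = sd(y - x)))
    expect_equal(mine$p, tt$p.value, tolerance = 1e-8)
    expect_equal(mine$statistic, unname(tt$statistic), tolerance = 1e-8)

    a <- rnorm(12); b <- rnorm(15, 0.5)
    tt2 <- t.test(b, a, var.equal = TRUE)
    mine2 <- run_test_from_summary(study_summary(
      "independent", n1 = 15, n2 = 12,
      mean1 = mean(b), mean2 = mean(a), sd1 = sd(b), sd2 = sd(a)))
    expect_equal(mine2$p, tt2$p.value, tolerance = 1e-8)

    g <- rep(1:3, each = 6); yy <- rnorm(18) + g / 3
    fit <- anova(lm(yy ~ factor(g)))
    mine3 <- run_test_from_summary(study_summary(
      "anova_between", n1 = 18, F_value = fit$`F value`[1],
      df1 = fit$Df[1], df2 = fit$Df[2]))
    expect_equal(mine3$p, fit$`Pr(>F)`[1], tolerance = 1e-8)
  }

  # significance is strict: p exactly at alpha is not significant
  n <- 15; tcrit <- qt(0.975, n - 1)
  at <- run_test_from_summary(study_summary(
    "paired", n1 = n, mean_diff = tcrit / sqrt(n), sd_diff = 1))
  expect_equal(at$p, 0.05, tolerance = 1e-12)
  expect_false(at$significant)
  above <- run_test_from_summary(study_summary(
    "paired", n1 = n, mean_diff = (tcrit + 1e-6) / sqrt(n), sd_diff = 1))
  expect_true(above$significant)
})

test_that("IQR outlier filter removes only values beyond the extreme fences", {
  res <- iqr_outlier_filter(c(1:10, 100))
  expect_identical(res$removed, 11L)
  expect_identical(res$kept, as.numeric(1:10))
  # oracle under the linear-interpolation quartile convention
  q <- quantile(c(1:10, 100), c(0.25, 0.75), type = 7, names = FALSE)
  expect_true(100 > q[2] + 3 * (q[2] - q[1]))

  same <- iqr_outlier_filter(rep(5, 8))
  expect_length(same$removed, 0)
  expect_identical(same$kept, rep(5, 8))

  expect_warning(small <- iqr_outlier_filter(c(1, 2, 300)), "fewer than 4")
  expect_identical(small$kept, c(1, 2, 300))

  # single pass: no re-filtering of the reduced sample
  x <- c(rep(0, 4), 10, 1000)
  once <- iqr_outlier_filter(x, multiplier = 3)
  again <- iqr_outlier_filter(once$kept, multiplier = 3)
  expect_lte(length(once$removed), length(once$removed) + length(again$removed))
  expect_identical(once$kept, x[setdiff(seq_along(x), once$removed)])
})

test_that("compatibility Z-test matches the normal oracle and is antisymmetric", {
  eq <- z_compare(effect_size("d_z", 0.4, se = 0.2),
                  effect_size("d_z", 0.4, se = 0.2))
  expect_equal(eq$z, 0)
  expect_equal(eq$p_one_tailed, 0.5)
  expect_true(eq$compatible)

  cmp <- z_compare(effect_size("d_z", 0.9, se = 0.3),
                   effect_size("d_z", 0.3, se = 0.1))
  z_oracle <- (0.9 - 0.3) / sqrt(0.3^2 + 0.1^2)
  expect_equal(cmp$z, z_oracle, tolerance = 1e-6)
  expect_equal(cmp$p_one_tailed, 1 - pnorm(z_oracle), tolerance = 1e-6)
  expect_false(cmp$compatible)

  set.seed(5)
  for (i in 1:20) {
    a <- effect_size("d_s", rnorm(1), se = runif(1, 0.05, 0.5))
    b <- effect_size("d_s", rnorm(1), se = runif(1, 0.05, 0.5))
    ab <- z_compare(a, b); ba <- z_compare(b, a)
    expect_equal(ab$z, -ba$z, tolerance = 1e-12)
    expect_equal(ab$p_one_tailed + ba$p_one_tailed, 1, tolerance = 1e-12)
  }

  expect_error(z_compare(effect_size("d_z", 1, se = 0.2),
                         effect_size("d_s", 1, se = 0.2)), "kinds differ")
  expect_error(z_compare(effect_size("d_z", 1), effect_size("d_z", 1, se = 0.2)),
               "standard errors")
})

test_that("Fisher-z comparison of partial eta squared matches the atanh oracle", {
  eq <- fisherz_compare_peta(0.3, 40, 0.3, 40)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_one_tailed, 0.5)

  cmp <- fisherz_compare_peta(0.5, 20, 0.1, 40)
  z_oracle <- (atanh(sqrt(0.5)) - atanh(sqrt(0.1))) / sqrt(1 / 17 + 1 / 37)
  expect_equal(cmp$z, z_oracle, tolerance = 1e-6)
  expect_equal(cmp$z, 1.890, tolerance = 1e-3)
  expect_equal(cmp$p_one_tailed, 1 - pnorm(z_oracle), tolerance = 1e-6)
  expect_false(cmp$compatible)

  expect_error(fisherz_compare_peta(0.5, 3, 0.1, 40), "exceed 3")
  expect_error(fisherz_compare_peta(1, 30, 0.1, 40), "\\[0, 1\\)")
})

test_that("the four verdicts partition the significance/direction/compatibility space", {
  expected <- list(
    # significant, same direction
    list(TRUE,  TRUE,  TRUE,  "success"),
    list(TRUE,  TRUE,  FALSE, "practical_failure"),
    # significant, opposite direction: direction failure dominates
    list(TRUE,  FALSE, TRUE,  "informative_failure"),
    list(TRUE,  FALSE, FALSE, "informative_failure"),
    # not significant
    list(FALSE, TRUE,  TRUE,  "inconclusive"),
    list(FALSE, TRUE,  FALSE, "informative_failure"),
    list(FALSE, FALSE, TRUE,  "inconclusive"),
    list(FALSE, FALSE, FALSE, "informative_failure"))
  seen <- character(0)
  for (case in expected) {
    v <- classify_outcome(case[[1]], case[[2]], case[[3]])
    expect_s3_class(v, "replication_outcome")
    expect_identical(unclass(v), case[[4]])
    seen <- c(seen, unclass(v))
  }
  # every combination lands in exactly one of the four verdicts
  expect_setequal(unique(seen), c("success", "practical_failure",
                                  "informative_failure", "inconclusive"))

  # the documented archetypes, with real component objects
  sig <- run_test_from_summary(
    study_summary("paired", n1 = 20, mean_diff = 1, sd_diff = 1))
  ns <- run_test_from_summary(
    study_summary("paired", n1 = 20, mean_diff = 0.05, sd_diff = 1))
  compat <- z_compare(effect_size("d_z", 0.5, se = 0.3),
                      effect_size("d_z", 0.45, se = 0.3))
  incompat <- z_compare(effect_size("d_z", 1.2, se = 0.15),
                        effect_size("d_z", 0.2, se = 0.15))
  expect_identical(unclass(classify_outcome(sig, TRUE, compat)), "success")
  expect_identical(unclass(classify_outcome(ns, TRUE, incompat)),
                   "informative_failure")
  expect_identical(unclass(classify_outcome(sig, TRUE, incompat)),
                   "practical_failure")
  expect_identical(unclass(classify_outcome(ns, TRUE, compat)),
                   "inconclusive")
})
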