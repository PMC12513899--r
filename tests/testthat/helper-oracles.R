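# Independent Monte Carlo and closed-form oracles used across test files.
# These deliberately avoid the package's own code paths: raw data are drawn
# directly, and estimators are written out in full.

# d_z estimates from `reps` simulated paired samples (difference scores
# drawn directly), optionally Hedges-corrected.
mc_paired_dz <- function(n, d, reps, hedges = TRUE) {
  m <- matrix(rnorm(n * reps, mean = d), nrow = n)   # unit-SD differences
  est <- colMeans(m) / apply(m, 2, sd)
  if (hedges) est * (1 - 3 / (4 * (n - 1) - 1)) else est
}

# pooled-SD d_s estimates from simulated two-group samples
mc_indep_ds <- function(n1, n2, d, reps, hedges = TRUE) {
  g1 <- matrix(rnorm(n1 * reps), nrow = n1)
  g2 <- matrix(rnorm(n2 * reps, mean = d), nrow = n2)
  sp <- sqrt(((n1 - 1) * apply(g1, 2, var) + (n2 - 1) * apply(g2, 2, var)) /
               (n1 + n2 - 2))
  est <- (colMeans(g2) - colMeans(g1)) / sp
  if (hedges) est * (1 - 3 / (4 * (n1 + n2 - 2) - 1)) else est
}

# one-way between-subjects ANOVA observed partial eta squared, computed
# from raw sums of squares (no package code)
oracle_eta_from_raw <- function(y, g) {
  gm <- tapply(y, g, mean)
  npg <- tapply(y, g, length)
  ssb <- sum(npg * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.character(g)])^2)
  ssb / (ssb + ssw)
}

# observed F for the same layout
oracle_F_from_raw <- function(y, g) {
  k <- length(unique(g)); N <- length(y)
  gm <- tapply(y, g, mean)
  npg <- tapply(y, g, length)
  ssb <- sum(npg * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.character(g)])^2)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# exact two-sided power of a paired t-test, written independently of the
# package's power function
oracle_power_paired <- function(d, n, alpha = 0.05) {
  crit <- qt(1 - alpha / 2, n - 1)
  ncp <- abs(d) * sqrt(n)
  pt(crit, n - 1, ncp, lower.tail = FALSE) + pt(-crit, n - 1, ncp)
}
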