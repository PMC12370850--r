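test_that("t-based quantities reproduce their closed forms", {
  expect_equal(round(t_p_value(2.06, 30), 3), 0.048)
  expect_equal(t_p_value(0, 17), 1)
  expect_equal(round(t_p_value(2.042, 30), 2), 0.05)
  expect_equal(round(cohens_d_from_t(2.06, 31), 2), 0.37)
  expect_equal(cohens_d_from_t(0, 12), 0)
  expect_error(t_p_value(1, 0))

  # d from (t, n) equals d from raw differences to machine precision
  set.seed(4)
  d <- rnorm(20, 0.3)
  t_stat <- mean(d) / (sd(d) / sqrt(20))
  expect_equal(cohens_d_from_t(t_stat, 20), mean(d) / sd(d),
               tolerance = 1e-12)
})

test_that("Wilcoxon p and rank-biserial r reproduce printed conventions", {
  expect_equal(round(wilcoxon_p(358.5, 31), 3), 0.031)
  expect_equal(round(rank_biserial(358.5, 31), 2), 0.45)
  expect_equal(wilcoxon_p(31 * 32 / 4, 31), 1) # null center, capped
  expect_equal(rank_biserial(496, 31), 1)
  expect_equal(rank_biserial(496 / 2, 31), 0)
  expect_error(wilcoxon_p(500, 31), "range")
  expect_error(rank_biserial(-1, 31), "range")
})

test_that("exact Wilcoxon mode matches 2^10 brute-force enumeration", {
  for (W in c(0, 5, 13, 27, 28, 40, 55)) {
    expect_equal(wilcoxon_p(W, 10, method = "exact"),
                 oracle_wilcoxon_exact(W, 10), tolerance = 1e-12,
                 label = sprintf("W = %d", W))
  }
  expect_error(wilcoxon_p(10.5, 10, method = "exact"), "integer")
})

test_that("wilcoxon_p is symmetric about the null center", {
  n <- 14
  S <- n * (n + 1) / 2
  for (W in c(0, 10, 33, 50)) {
    expect_equal(wilcoxon_p(W, n), wilcoxon_p(S - W, n), tolerance = 1e-12)
    expect_equal(wilcoxon_p(W, n, "exact"), wilcoxon_p(S - W, n, "exact"),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon_w drops zeros and mid-ranks ties", {
  w <- wilcoxon_w(c(5, 3, 3, 1, 7), c(1, 3, 1, 1, 3))
  # diffs 4, 0, 2, 0, 4 -> nonzero 4, 2, 4; ranks 2.5, 1, 2.5 all positive
  expect_equal(w$n, 3)
  expect_equal(w$W, 6)
  expect_true(w$has_ties)
  expect_error(wilcoxon_w(1:4, 1:4), "zero")
})

test_that("paired_compare routes by normality and signs follow construction", {
  set.seed(10)
  x <- rnorm(20)
  y <- x - 0.8 + rnorm(20, sd = 0.5)
  res <- paired_compare(x, y)
  expect_equal(res$method, "paired_t")
  expect_gt(res$statistic, 0)
  expect_equal(res$effect, mean(x - y) / sd(x - y), tolerance = 1e-12)

  # heavy-tailed differences route to the signed-rank branch
  set.seed(11)
  xs <- exp(rnorm(30, sd = 1.5))
  ys <- rep(0, 30)
  res2 <- paired_compare(xs, ys)
  expect_equal(res2$method, "wilcoxon")
  expect_equal(res2$effect, 1) # all differences positive

  expect_error(paired_compare(1:5, 1:5), "zero")
  expect_error(paired_compare(1:3, 1:4), "equal length")
})

test_that("effect and tier labels apply the conventional thresholds", {
  expect_equal(effect_size_label(0.19, "d"), "none")
  expect_equal(effect_size_label(-0.55, "d"), "medium")
  expect_equal(effect_size_label(0.85, "d"), "large")
  expect_equal(effect_size_label(0.45, "r"), "medium")
  expect_equal(effect_size_label(0.09, "r"), "none")
  expect_equal(tier_label(0.049), "significant")
  expect_equal(tier_label(0.05), "trend")
  expect_equal(tier_label(0.0999), "trend")
  expect_equal(tier_label(0.10), "ns")
})

test_that("Shapiro routing statistic behaves under null and skew", {
  ps <- sapply(1:200, function(s) {
    set.seed(s)
    shapiro_normality(rnorm(31))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  skew_reject <- sapply(1:100, function(s) {
    set.seed(s)
    shapiro_normality(exp(rnorm(31))) < 0.05
  })
  expect_gte(mean(skew_reject), 0.9)
  expect_error(shapiro_normality(rep(1, 10)), "constant")
  expect_error(shapiro_normality(1:2))
})

test_that("BH-FDR matches the hand-applied step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2)
  cm <- bh_fdr(p, q = 0.05)
  expect_equal(cm$table$rejected, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(cm$table$p_corrected, oracle_bh(p), tolerance = 1e-12)

  for (s in 1:5) {
    set.seed(s)
    pr <- runif(12)^2
    expect_equal(bh_fdr(pr)$table$p_corrected, oracle_bh(pr),
                 tolerance = 1e-12)
  }

  all1 <- bh_fdr(rep(1, 4))
  expect_false(any(all1$table$rejected))
  single <- bh_fdr(0.03)
  expect_equal(single$table$p_corrected, 0.03)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.2, 1.4)))
})

test_that("BH adjusted p is monotone and rejections nest across levels", {
  set.seed(6)
  p <- runif(30)
  cm <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(cm$table$p_corrected[o]) >= -1e-12))
  rej_small <- bh_fdr(p, q = 0.02)$table$rejected
  rej_large <- bh_fdr(p, q = 0.10)$table$rejected
  expect_true(all(rej_large[rej_small]))
  expect_true(all(cm$table$p_corrected >= cm$table$p_raw - 1e-12))
})

test_that("paired permutation max-statistic: exact null, floor, reduction", {
  set.seed(3)
  A <- matrix(rnorm(40), 8, 5)
  cm <- perm_maxstat_paired(A, A + 0 * A, n_perm = 200, seed = 1)
  # A - B identically zero: all sites flagged degenerate
  expect_true(all(is.na(cm$table$p_corrected)))

  B <- A + matrix(rnorm(40, sd = 0.1), 8, 5)
  cm2 <- perm_maxstat_paired(A, B, n_perm = 200, seed = 1)
  expect_true(all(cm2$table$p_corrected >= 1 / 201))
  expect_true(all(cm2$table$p_corrected <= 1))

  # single site reduces to an unadjusted sign-flip permutation t-test
  D <- rnorm(10, 0.8)
  one <- perm_maxstat_paired(matrix(D), matrix(rep(0, 10)),
                             n_perm = 999, seed = 7)
  t_obs <- mean(D) / (sd(D) / sqrt(10))
  set.seed(1234)
  ref <- mean(c(TRUE, replicate(999, {
    s <- sample(c(-1, 1), 10, replace = TRUE)
    abs(mean(s * D) / (sd(s * D) / sqrt(10))) >= abs(t_obs)
  })))
  expect_equal(one$table$p_corrected, ref, tolerance = 0.03)
})

test_that("Monte-Carlo permutation p agrees with exhaustive 2^6 enumeration", {
  set.seed(9)
  A <- matrix(rnorm(18, 0.6), 6, 3)
  B <- matrix(rnorm(18), 6, 3)
  ex <- perm_maxstat_paired(A, B, exhaustive = TRUE)
  mc <- perm_maxstat_paired(A, B, n_perm = 5000, seed = 11)
  expect_equal(mc$table$p_corrected, ex$table$p_corrected, tolerance = 0.02)
  expect_true(all(ex$table$p_corrected >= 1 / 64))
})

test_that("correlation permutation map honors construction and symmetry", {
  set.seed(12)
  idx <- rnorm(12)
  maps <- matrix(rnorm(12 * 6), 12, 6)
  maps[, 4] <- idx # noise-free perfect correlation
  cm <- perm_maxstat_corr(idx, maps, n_perm = 999, seed = 3)
  expect_equal(cm$table$p_corrected[4], 1 / 1000)
  expect_equal(cm$table$stat[4], 1, tolerance = 1e-12)

  flipped <- perm_maxstat_corr(-idx, maps, n_perm = 999, seed = 3)
  expect_equal(flipped$table$stat, -cm$table$stat, tolerance = 1e-12)
  expect_equal(flipped$table$p_corrected, cm$table$p_corrected,
               tolerance = 1e-12)

  expect_error(perm_maxstat_corr(rep(1, 12), maps, seed = 1), "constant")
  expect_error(perm_maxstat_corr(idx[1:11], maps, seed = 1), "nrow")
})

test_that("power calculation reproduces the closed form and margins", {
  expect_equal(power_sample_size(0.5), 32L)
  expect_equal(power_sample_size(1.0), 8L) # ceiling(7.849)
  expect_equal(power_sample_size(0.5, margin = 0.05), 34L)
  expect_equal(power_sample_size(0.5, method = "noncentral_t"), 34L)
  expect_error(power_sample_size(0))
})
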