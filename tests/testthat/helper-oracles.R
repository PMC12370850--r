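# Independent oracles used across the suite. Each deliberately avoids the
# implementation path it checks.

# Poincare indices by literally building the 2-D point cloud, rotating it
# by 45 degrees, and taking coordinate SDs.
oracle_lorenz <- function(intervals) {
  x <- intervals[-length(intervals)]
  y <- intervals[-1L]
  theta <- -pi / 4
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  pts <- R %*% rbind(x, y)
  # after -45 deg rotation the identity line maps onto the first axis
  list(sd_along = sd(pts[1, ]), sd_perp = sd(pts[2, ]))
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
oracle_wilcoxon_exact <- function(W, n) {
  ranks <- seq_len(n)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% ranks)
  lo <- mean(Ws <= W)
  hi <- mean(Ws >= W)
  min(1, 2 * min(lo, hi))
}

# Benjamini-Hochberg step-up applied by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# expected relative alpha power from generating band amplitudes (Parseval:
# unit-SD components scaled by amplitude contribute amplitude^2 variance)
oracle_rel_alpha <- function(amps, alpha_factor = 1) {
  a <- amps
  a[["alpha"]] <- a[["alpha"]] * alpha_factor
  a[["alpha"]]^2 / sum(a^2)
}

# 95% binomial band around a nominal rate
binom_band <- function(nominal, n_rep) {
  half <- 1.96 * sqrt(nominal * (1 - nominal) / n_rep)
  c(nominal - half, nominal + half)
}

tiny_cohort <- function(n_subjects = 2, seed = 7, duration_s = 12,
                        fs = 125, ...) {
  gen_paired_cohort(sim_config(n_subjects = n_subjects, seed = seed,
                               fs = fs, duration_s = duration_s,
                               trim_s = 0, ...))
}
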