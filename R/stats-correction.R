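# Multiple-comparison corrections: Benjamini-Hochberg step-up for sensor
# maps, permutation max-statistic (sign-flip / index-shuffle) familywise
# control for source maps, connectivity maps, and index-map correlations.

corrected_map <- function(sites, stat, p_raw, p_corrected, method,
                          n_perm = NA_integer_, seed = NA_integer_,
                          q = NA_real_, flagged = NULL) {
  structure(list(
    table = data.frame(site = sites, stat = stat, p_raw = p_raw,
                       p_corrected = p_corrected,
                       significant = !is.na(p_corrected) & p_corrected < 0.05,
                       stringsAsFactors = FALSE),
    method = method, n_perm = n_perm, seed = seed, q = q,
    flagged = flagged %||% character(0)),
    class = "corrected_map")
}

#' @export
print.corrected_map <- function(x, ...) {
  cat(sprintf("<corrected_map: %s, %d sites, %d significant>\n",
              x$method, nrow(x$table), sum(x$table$significant, na.rm = TRUE)))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values with a rejection mask at level `q`
#' (rejected iff adjusted p <= q).
#'
#' @param p vector of raw p-values
#' @param q FDR level
#' @param sites optional site labels
#' @return a `corrected_map` whose table carries `rejected` at `q`
#' @export
bh_fdr <- function(p, q = 0.05, sites = NULL) {
  p <- as.numeric(p)
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  out <- corrected_map(sites %||% paste0("site", seq_along(p)),
                       stat = NA_real_, p_raw = p, p_corrected = adj,
                       method = "bh_fdr", q = q)
  out$table$rejected <- adj <= q
  out
}

paired_t_stats <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  list(t = m / sqrt(v / n), var = v, n = n)
}

all_sign_patterns <- function(n) {
  if (n > 20) stop("exhaustive enumeration limited to n <= 20", call. = FALSE)
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(m) <- NULL
  m
}

#' Paired permutation max-statistic correction
#'
#' Per-site paired t statistics on `A - B`; the null distribution is built
#' by random per-subject sign flips of the difference maps, and each
#' site's corrected p is the proportion of permutations (plus the observed
#' arrangement) whose maximum |t| over sites reaches that site's observed
#' |t|. Controls the familywise error over the map. Zero-variance sites
#' are flagged and excluded (p = NA).
#'
#' @param A,B subjects x sites matrices, matched dimensions, >= 4 subjects
#' @param n_perm number of random sign-flip permutations
#' @param seed RNG seed (required: corrected p-values must be reproducible)
#' @param exhaustive if TRUE, enumerate all `2^n` sign patterns instead of
#'   sampling (n <= 20); `n_perm` is then ignored
#' @return a `corrected_map` (corrected p >= 1/(n_perm+1), or >= 2^-n
#'   in exhaustive mode)
#' @export
perm_maxstat_paired <- function(A, B, n_perm = 5000, seed, exhaustive = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B))) stop("A and B dimensions differ", call. = FALSE)
  n <- nrow(A)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  if (missing(seed) && !exhaustive) stop("`seed` is required", call. = FALSE)
  D <- A - B
  sites <- colnames(D) %||% paste0("site", seq_len(ncol(D)))
  obs <- paired_t_stats(D)
  ok <- obs$var > 0
  flagged <- sites[!ok]
  t_obs <- obs$t
  if (!any(ok)) {
    return(corrected_map(sites, stat = t_obs,
                         p_raw = rep(NA_real_, length(sites)),
                         p_corrected = rep(NA_real_, length(sites)),
                         method = "perm_maxstat", n_perm = n_perm,
                         seed = if (exhaustive) NA_integer_ else seed,
                         flagged = flagged))
  }
  Dk <- D[, ok, drop = FALSE]
  sumsq <- colSums(Dk^2)
  S <- if (exhaustive) all_sign_patterns(n)
       else with_seed_(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                    nrow = n_perm))
  M <- (S %*% Dk) / n
  V <- sweep(-n * M^2, 2L, sumsq, "+") / (n - 1)
  Tm <- abs(M / sqrt(V / n))
  max_t <- apply(Tm, 1L, max)
  p_corr <- rep(NA_real_, length(sites))
  tol <- 1e-10
  if (exhaustive) {
    p_corr[ok] <- vapply(abs(t_obs[ok]), function(t0)
      mean(max_t >= t0 - tol), numeric(1))
  } else {
    p_corr[ok] <- vapply(abs(t_obs[ok]), function(t0)
      (sum(max_t >= t0 - tol) + 1) / (nrow(S) + 1), numeric(1))
  }
  corrected_map(sites, stat = t_obs, p_raw = t_p_value_vec(t_obs, n - 1),
                p_corrected = p_corr,
                method = if (exhaustive) "perm_maxstat_exhaustive" else "perm_maxstat",
                n_perm = nrow(S), seed = if (exhaustive) NA_integer_ else seed,
                flagged = flagged)
}

t_p_value_vec <- function(t, df) 2 * stats::pt(-abs(t), df)

#' Index-map correlation with permutation max-|r| correction
#'
#' Correlates a per-subject index with every site of a subjects x sites
#' map; the null is built by shuffling the index across subjects, and
#' corrected p-values use the permutation distribution of the maximum |r|
#' over sites.
#'
#' @param index per-subject index values (e.g. FAA score, CSI)
#' @param maps subjects x sites matrix (e.g. ROI band power, LPS edges)
#' @param n_perm number of index shuffles
#' @param seed RNG seed (required)
#' @return a `corrected_map` with per-site Pearson r as the statistic
#' @export
perm_maxstat_corr <- function(index, maps, n_perm = 5000, seed) {
  maps <- as.matrix(maps)
  index <- as.numeric(index)
  if (length(index) != nrow(maps)) stop("length(index) != nrow(maps)", call. = FALSE)
  n <- length(index)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  if (stats::sd(index) == 0) stop("constant index", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  sites <- colnames(maps) %||% paste0("site", seq_len(ncol(maps)))
  sds <- apply(maps, 2L, stats::sd)
  ok <- sds > 0
  flagged <- sites[!ok]
  z_idx <- (index - mean(index)) / stats::sd(index)
  Zm <- scale(maps[, ok, drop = FALSE])
  r_ok <- as.numeric(crossprod(Zm, z_idx)) / (n - 1)
  perms <- with_seed_(seed,
    vapply(seq_len(n_perm), function(i) z_idx[sample.int(n)], numeric(n)))
  R <- abs(crossprod(Zm, perms)) / (n - 1) # sites x n_perm
  max_r <- apply(R, 2L, max)
  tol <- 1e-12
  p_corr <- rep(NA_real_, length(sites))
  p_corr[ok] <- vapply(abs(r_ok), function(r0)
    (sum(max_r >= r0 - tol) + 1) / (n_perm + 1), numeric(1))
  r_all <- rep(NA_real_, length(sites))
  r_all[ok] <- r_ok
  t_r <- r_all * sqrt((n - 2) / pmax(1e-300, 1 - r_all^2))
  corrected_map(sites, stat = r_all, p_raw = t_p_value_vec(t_r, n - 2),
                p_corrected = p_corr, method = "perm_maxstat_corr",
                n_perm = n_perm, seed = seed, flagged = flagged)
}

#' A-priori paired-design sample size
#'
#' Normal-approximation closed form
#' `n = ceiling(((z_{1-alpha/2} + z_{power}) / d)^2)` for a two-sided
#' paired (one-sample-on-differences) design; an exact noncentral-t mode
#' iterating [stats::power.t.test()] is available. An attrition margin can
#' be added on top (`ceiling(n * (1 + margin))`).
#'
#' @param d standardized effect size of the paired differences
#' @param alpha two-sided significance level
#' @param power target power
#' @param method `"normal"` (closed form) or `"noncentral_t"` (exact)
#' @param margin fractional attrition margin applied after `n`
#' @return required number of subjects (integer)
#' @examples
#' power_sample_size(0.5)               # 32
#' power_sample_size(0.5, margin = 0.05) # 34
#' @export
power_sample_size <- function(d, alpha = 0.05, power = 0.80,
                              method = c("normal", "noncentral_t"),
                              margin = 0) {
  method <- match.arg(method)
  stop_if_not_scalar_num(d, "d", lower = .Machine$double.eps)
  stop_if_not_scalar_num(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  stop_if_not_scalar_num(power, "power", lower = 1e-12, upper = 1 - 1e-12)
  n <- if (method == "normal") {
    ceiling(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / d)^2)
  } else {
    ceiling(stats::power.t.test(delta = d, sd = 1, sig.level = alpha,
                                power = power, type = "one.sample")$n)
  }
  as.integer(ceiling(n * (1 + margin)))
}
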