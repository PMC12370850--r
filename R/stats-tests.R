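# Normality-routed paired comparisons with effect sizes and two-tier
# significance reporting.

#' Shapiro-Wilk normality p-value
#'
#' @param x numeric vector, 3 <= n <= 5000, non-constant
#' @return the Shapiro-Wilk p-value
#' @export
shapiro_normality <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant vector has no defined normality test",
                              call. = FALSE)
  stats::shapiro.test(x)$p.value
}

#' Two-sided p-value from a t statistic
#'
#' @param t t statistic
#' @param df degrees of freedom, >= 1
#' @return `2 * P(T >= |t|)` under the central t distribution
#' @examples
#' t_p_value(2.06, 30) # 0.048
#' @export
t_p_value <- function(t, df) {
  stop_if_not_scalar_num(df, "df", lower = 1)
  2 * stats::pt(-abs(t), df)
}

#' Cohen's d from a paired t statistic
#'
#' Paired-design conversion `d = t / sqrt(n)`, identical to
#' `mean(diff) / sd(diff)`.
#'
#' @param t paired t statistic
#' @param n number of subjects (pairs), >= 2
#' @return Cohen's d
#' @examples
#' cohens_d_from_t(2.06, 31) # 0.37
#' @export
cohens_d_from_t <- function(t, n) {
  stop_if_not_scalar_num(n, "n", lower = 2)
  t / sqrt(n)
}

#' Signed-rank W statistic for paired data
#'
#' Zero differences are dropped; tied absolute differences take mid-ranks;
#' `W` is the sum of ranks of positive differences.
#'
#' @param x,y paired measurement vectors (W is computed on `x - y`)
#' @return list with `W`, `n` (non-zero pairs), `has_ties`
#' @export
wilcoxon_w <- function(x, y) {
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  if (!length(d)) stop("all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  list(W = sum(r[d > 0]), n = length(d), has_ties = anyDuplicated(abs(d)) > 0)
}

#' Two-sided Wilcoxon signed-rank p-value from W
#'
#' Default is the continuity-corrected normal approximation
#' `z = (|W - n(n+1)/4| - 0.5) / sqrt(n(n+1)(2n+1)/24)`, the convention of
#' common statistics GUIs (half-integer W from mid-ranked ties is handled
#' naturally). An exact mode (valid without ties, integer W, n <= 25) sums
#' the exact signed-rank distribution.
#'
#' @param W signed-rank statistic, `0 <= W <= n(n+1)/2`
#' @param n number of non-zero pairs
#' @param method `"approx"` (continuity-corrected normal) or `"exact"`
#' @return two-sided p-value (capped at 1)
#' @examples
#' wilcoxon_p(358.5, 31) # 0.031
#' @export
wilcoxon_p <- function(W, n, method = c("approx", "exact")) {
  method <- match.arg(method)
  stop_if_not_scalar_num(n, "n", lower = 1)
  S <- n * (n + 1) / 2
  if (W < 0 || W > S) stop("W out of range [0, n(n+1)/2]", call. = FALSE)
  if (method == "exact") {
    if (W != round(W))
      stop("exact mode requires an integer W (no tied mid-ranks)", call. = FALSE)
    lo <- stats::psignrank(W, n)                  # P(W* <= W)
    hi <- 1 - stats::psignrank(W - 1, n)          # P(W* >= W)
    return(min(1, 2 * min(lo, hi)))
  }
  z <- (abs(W - n * (n + 1) / 4) - 0.5) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  min(1, 2 * stats::pnorm(-z))
}

#' Matched-pairs rank-biserial effect size
#'
#' `r = (W+ - W-) / (W+ + W-) = 2W/S - 1` with `S = n(n+1)/2`; signed for
#' direction, `|r|` is used for effect-size labelling.
#'
#' @param W signed-rank statistic
#' @param n number of non-zero pairs
#' @return rank-biserial r in `[-1, 1]`
#' @examples
#' rank_biserial(358.5, 31) # 0.45
#' @export
rank_biserial <- function(W, n) {
  stop_if_not_scalar_num(n, "n", lower = 1)
  S <- n * (n + 1) / 2
  if (W < 0 || W > S) stop("W out of range [0, n(n+1)/2]", call. = FALSE)
  2 * W / S - 1
}

#' Effect-size label
#'
#' Thresholds: small/medium/large at d = 0.2/0.5/0.8 and r = 0.1/0.3/0.5;
#' below the small threshold the label is `"none"`. Applied to `|effect|`.
#'
#' @param effect effect-size value (d or r)
#' @param type `"d"` or `"r"`
#' @return one of `"none"`, `"small"`, `"medium"`, `"large"`
#' @export
effect_size_label <- function(effect, type = c("d", "r")) {
  type <- match.arg(type)
  cuts <- if (type == "d") c(0.2, 0.5, 0.8) else c(0.1, 0.3, 0.5)
  a <- abs(effect)
  if (a >= cuts[3]) "large" else if (a >= cuts[2]) "medium"
  else if (a >= cuts[1]) "small" else "none"
}

#' Two-tier significance label
#'
#' `"significant"` for p < 0.05, `"trend"` for 0.05 <= p < 0.10 (half-open
#' on both ends: exactly 0.05 is a trend, exactly 0.10 is ns), else `"ns"`.
#'
#' @param p p-value
#' @return tier label
#' @export
tier_label <- function(p) {
  if (p < 0.05) "significant" else if (p < 0.10) "trend" else "ns"
}

#' Normality-routed paired comparison
#'
#' The paired differences are routed by a Shapiro-Wilk test at alpha 0.05:
#' normal-looking differences get a paired t-test with Cohen's
#' `d = mean(diff)/sd(diff)`; otherwise a Wilcoxon signed-rank test (exact
#' when `n <= 25` with no ties or zeros, else continuity-corrected normal
#' approximation) with the matched-pairs rank-biserial r. The difference
#' direction is `x - y` throughout (condition A minus condition B).
#'
#' @param x,y equal-length paired measurement vectors (n >= 3)
#' @param wilcoxon `"auto"`, `"approx"`, or `"exact"` p-value mode for the
#'   non-parametric branch
#' @param normality_alpha routing threshold for the Shapiro-Wilk p
#' @return a `test_result`: method, statistic, df, p, effect, effect_type,
#'   effect_label, tier, n
#' @export
paired_compare <- function(x, y, wilcoxon = c("auto", "approx", "exact"),
                           normality_alpha = 0.05) {
  wilcoxon <- match.arg(wilcoxon)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stop("`x` and `y` must be paired vectors of equal length >= 3", call. = FALSE)
  d <- x - y
  if (all(d == 0)) stop("all differences are zero", call. = FALSE)
  sw_p <- if (stats::sd(d) > 0) shapiro_normality(d) else 0 # constant != 0: route nonparametric
  if (sw_p >= normality_alpha) {
    tt <- stats::t.test(x, y, paired = TRUE)
    eff <- mean(d) / stats::sd(d)
    res <- list(method = "paired_t", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                effect = eff, effect_type = "d",
                effect_label = effect_size_label(eff, "d"),
                tier = tier_label(tt$p.value), n = length(x),
                shapiro_p = sw_p)
  } else {
    w <- wilcoxon_w(x, y)
    mode <- if (wilcoxon == "auto") {
      if (!w$has_ties && w$n <= 25) "exact" else "approx"
    } else wilcoxon
    p <- wilcoxon_p(w$W, w$n, method = mode)
    eff <- rank_biserial(w$W, w$n)
    res <- list(method = "wilcoxon", statistic = w$W, df = NA_integer_,
                p = p, effect = eff, effect_type = "r",
                effect_label = effect_size_label(eff, "r"),
                tier = tier_label(p), n = length(x), shapiro_p = sw_p,
                wilcoxon_mode = mode)
  }
  structure(res, class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  stat_name <- if (x$method == "paired_t") "t" else "W"
  df_txt <- if (!is.na(x$df %||% NA)) sprintf("(%g)", x$df) else ""
  cat(sprintf("<test_result: %s %s%s = %.3f, p = %.4f [%s], %s = %.3f (%s)>\n",
              x$method, stat_name, df_txt, x$statistic, x$p, x$tier,
              x$effect_type, x$effect, x$effect_label))
  invisible(x)
}
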