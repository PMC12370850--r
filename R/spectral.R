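# Welch power spectra, relative band power, frontal alpha asymmetry,
# and cohort-level band power tables.

welch_segments <- function(n, L, overlap) {
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  list(starts = starts, step = step)
}

#' Welch power spectral density
#'
#' Hann-tapered, 50%-overlapping window periodograms averaged per channel.
#' One-sided density scaling: summing `power * df` over the grid recovers
#' the signal variance (Parseval) for stationary zero-mean input.
#'
#' @param rec a [recording()]
#' @param window_s FFT window length in seconds (grid resolution is
#'   `1/window_s` Hz)
#' @param overlap fractional window overlap
#' @return a `power_spectrum`: `freqs` (Hz), `power` (channels x freqs,
#'   amplitude^2/Hz), `window_s`, `n_windows`, `fs`, `labels`
#' @export
psd <- function(rec, window_s = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$data)
  L <- round(window_s * rec$fs)
  if (L > n) stop("recording shorter than one window", call. = FALSE)
  if (L < 4) stop("window too short", call. = FALSE)
  seg <- welch_segments(n, L, overlap)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L) # periodic Hann
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  freqs <- (0:(nf - 1L)) * rec$fs / L
  acc <- matrix(0, nrow(rec$data), nf)
  for (s in seg$starts) {
    seg_data <- rec$data[, s:(s + L - 1L), drop = FALSE] *
      rep(w, each = nrow(rec$data))
    X <- t(stats::mvfft(t(seg_data)))
    acc <- acc + Mod(X[, seq_len(nf), drop = FALSE])^2
  }
  P <- acc / (length(seg$starts) * rec$fs * U)
  # fold negative frequencies into the one-sided density
  dbl <- 2:(if (L %% 2 == 0) nf - 1L else nf)
  P[, dbl] <- 2 * P[, dbl]
  rownames(P) <- rec$labels
  structure(list(freqs = freqs, power = P, window_s = window_s,
                 n_windows = length(seg$starts), fs = rec$fs,
                 labels = rec$labels),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum: %d channels, %d bins (0-%g Hz, df = %g), %d windows>\n",
              nrow(x$power), length(x$freqs), max(x$freqs),
              1 / x$window_s, x$n_windows))
  invisible(x)
}

band_bins <- function(freqs, band) freqs > band[1] & freqs <= band[2]

#' Relative band power
#'
#' Power integrated over `band` divided by power integrated over `total`,
#' per channel. Bin membership is half-open `(low, high]` so adjacent bands
#' tile a range without double counting.
#'
#' @param spec a `power_spectrum` from [psd()]
#' @param band `c(low, high)` Hz
#' @param total reference range, default 1-60 Hz
#' @return named numeric vector of fractions in `[0, 1]`, one per channel
#' @export
relative_band_power <- function(spec, band, total = c(1, 60)) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (band[1] < total[1] || band[2] > total[2])
    stop("`band` must lie within `total`", call. = FALSE)
  sel_b <- band_bins(spec$freqs, band)
  sel_t <- band_bins(spec$freqs, total)
  if (!any(sel_b)) stop("no frequency bins inside `band`", call. = FALSE)
  num <- rowSums(spec$power[, sel_b, drop = FALSE])
  den <- rowSums(spec$power[, sel_t, drop = FALSE])
  if (any(den <= 0)) stop("zero total power in reference range", call. = FALSE)
  out <- num / den
  names(out) <- spec$labels
  out
}

#' Frontal alpha asymmetry score
#'
#' Relative alpha power (alpha band over the 1-60 Hz total) at F4 minus at
#' F3. Because alpha is inversely related to cortical activation, higher
#' scores index relatively greater left-frontal activity. Relative (rather
#' than absolute) power is used for its better test-retest reliability.
#'
#' @param rec a [recording()] containing channels labelled `F3` and `F4`
#' @param alpha alpha band in Hz
#' @param total reference range in Hz
#' @param window_s Welch window length passed to [psd()]
#' @return an `faa_score`: list with `value` (= `f4_rel - f3_rel`),
#'   `f3_rel`, `f4_rel`
#' @export
faa <- function(rec, alpha = c(8, 13), total = c(1, 60), window_s = 2) {
  stopifnot(inherits(rec, "recording"))
  if (!all(c("F3", "F4") %in% rec$labels))
    stop("recording must contain channels F3 and F4", call. = FALSE)
  spec <- psd(rec, window_s = window_s)
  rel <- relative_band_power(spec, alpha, total)
  structure(list(value = unname(rel["F4"] - rel["F3"]),
                 f3_rel = unname(rel["F3"]), f4_rel = unname(rel["F4"])),
            class = "faa_score")
}

#' @export
print.faa_score <- function(x, ...) {
  cat(sprintf("<faa_score: %+.4f (F4 rel alpha %.4f - F3 rel alpha %.4f)>\n",
              x$value, x$f4_rel, x$f3_rel))
  invisible(x)
}

#' Cohort band power table
#'
#' One relative-power row per subject x condition x channel (or ROI) x
#' band. The sensor level reads each bundle's EEG recording; the roi level
#' reads the ROI source series with the source band dialect.
#'
#' @param cohort a [gen_paired_cohort()] result (or compatible list)
#' @param scheme a [band_scheme()]
#' @param level `"sensor"` or `"roi"`
#' @param preprocess_fn optional function `recording -> recording` applied
#'   before spectral analysis (e.g. the pipeline's filter/trim/reject chain)
#' @param total reference range for relative power
#' @param window_s Welch window length
#' @return data.frame with columns subject, condition, site, band, rel_power
#' @export
band_power_table <- function(cohort, scheme, level = c("sensor", "roi"),
                             preprocess_fn = NULL, total = c(1, 60),
                             window_s = 2) {
  level <- match.arg(level)
  stopifnot(inherits(scheme, "band_scheme"))
  field <- if (level == "sensor") "eeg" else "roi"
  rows <- list()
  fs_seen <- NULL
  for (subj in cohort$subjects) {
    for (cond in c("altruistic", "selfish")) {
      rec <- subj[[cond]][[field]]
      if (is.null(rec)) stop("missing ", field, " recording for ", subj$id,
                             "/", cond, call. = FALSE)
      fs_seen <- c(fs_seen, rec$fs)
      if (!is.null(preprocess_fn)) rec <- preprocess_fn(rec)
      spec <- psd(rec, window_s = window_s)
      for (b in names(scheme$bands)) {
        rp <- relative_band_power(spec, scheme$bands[[b]], total)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj$id, condition = cond, site = names(rp),
          band = b, rel_power = unname(rp), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(unique(fs_seen)) > 1L)
    stop("mixed sampling rates within cohort", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
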