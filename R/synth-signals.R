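# Synthetic band-limited EEG, coupled ROI source series, and RRI series.
#
# Band components are white noise band-limited in the FFT domain
# (zero-phase, exact band content) rather than sums of sinusoids, matching
# the broadband character of EEG and making variance bookkeeping
# (Parseval) exact up to component normalization.

fft_bandlimit <- function(x, low, high, fs) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  fm <- pmin(f, fs - f) # two-sided frequency magnitude
  X <- stats::fft(x)
  X[!(fm > low & fm <= high)] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# unit-SD band-limited noise component
band_component <- function(n, fs, band) {
  e <- fft_bandlimit(stats::rnorm(n), band[1], band[2], fs)
  s <- stats::sd(e)
  if (s == 0) stop("degenerate band component (band too narrow?)", call. = FALSE)
  e / s
}

# unit-SD 1/f-shaped background noise, spectral floor at `floor_hz`
pink_noise <- function(n, fs, floor_hz = 1) {
  f <- (0:(n - 1)) * fs / n
  fm <- pmin(f, fs - f)
  g <- 1 / sqrt(pmax(fm, floor_hz))
  g[1] <- 0 # no DC
  X <- stats::fft(stats::rnorm(n)) * g
  e <- Re(stats::fft(X, inverse = TRUE)) / n
  e / stats::sd(e)
}

#' Default sensor-level band amplitudes (arbitrary units, roughly uV)
#' @return named numeric vector over the five bands
#' @export
default_band_amplitudes <- function() {
  c(delta = 22, theta = 14, alpha = 20, beta = 9, gamma = 5)
}

#' Generate a synthetic multichannel EEG recording
#'
#' Each channel is a sum of five band-limited stochastic processes (one
#' per band of `scheme`, SD-normalized then scaled by `band_amplitudes`)
#' plus 1/f-shaped background noise. A positive `faa_shift` multiplies the
#' F4 alpha amplitude by `1 + faa_shift` and the F3 alpha amplitude by
#' `1 - faa_shift`, injecting a frontal alpha asymmetry of known size.
#' Identical seed and arguments give bit-identical samples.
#'
#' @param channels electrode labels, a subset of [electrodes_1020()]
#' @param fs sampling rate, Hz (> 120 so the gamma band is below Nyquist)
#' @param duration_s recording length, seconds (>= 2)
#' @param band_amplitudes named amplitude per band (SD of each component)
#' @param faa_shift dimensionless frontal-alpha asymmetry offset
#' @param noise_sd SD of the 1/f background
#' @param seed integer seed
#' @param scheme a [band_scheme()] naming the component bands
#' @return a [recording()]
#' @export
gen_eeg <- function(channels = electrodes_1020(), fs = 250, duration_s = 240,
                    band_amplitudes = default_band_amplitudes(),
                    faa_shift = 0, noise_sd = 8, seed = 1L,
                    scheme = band_scheme("sensor")) {
  bad <- setdiff(channels, electrodes_1020())
  if (length(bad)) stop("unknown electrode label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (fs <= 120) stop("fs must exceed 120 Hz (gamma top x 2)", call. = FALSE)
  if (duration_s < 2) stop("duration_s must be at least 2 s", call. = FALSE)
  if (abs(faa_shift) >= 1) stop("|faa_shift| must be < 1", call. = FALSE)
  miss <- setdiff(names(scheme$bands), names(band_amplitudes))
  if (length(miss)) stop("band_amplitudes missing: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  n <- round(duration_s * fs)
  data <- with_seed_(seed, {
    out <- matrix(0, length(channels), n)
    for (i in seq_along(channels)) {
      ch <- channels[i]
      sig <- numeric(n)
      for (b in names(scheme$bands)) {
        amp <- band_amplitudes[[b]]
        if (b == "alpha" && faa_shift != 0) {
          if (ch == "F4") amp <- amp * (1 + faa_shift)
          if (ch == "F3") amp <- amp * (1 - faa_shift)
        }
        sig <- sig + amp * band_component(n, fs, scheme$bands[[b]])
      }
      if (noise_sd > 0) sig <- sig + noise_sd * pink_noise(n, fs)
      out[i, ] <- sig
    }
    out
  })
  recording(data, channels, fs)
}

circ_shift <- function(x, lag) {
  n <- length(x)
  x[((seq_len(n) - 1L - lag) %% n) + 1L]
}

#' Generate coupled ROI source time series
#'
#' Uncoupled ROIs are independent sums of band-limited noise. Each entry
#' of `coupling_spec` (`list(roi_a=, roi_b=, band=, lag=, strength=)`)
#' replaces roi_b's component in that band by a `strength`-weighted
#' mixture of roi_a's component delayed by `lag` samples (circular shift,
#' so the spectrum is preserved) and roi_b's own independent component
#' with weight `sqrt(1 - strength^2)`. `lag = 0` produces purely
#' instantaneous (zero-lag) mixing, which lagged phase synchronization
#' must suppress.
#'
#' @param roi_labels unique ROI labels, default [roi_atlas_19()]
#' @param fs sampling rate, Hz
#' @param duration_s length, seconds
#' @param coupling_spec list of coupling entries, see Details
#' @param seed integer seed
#' @param scheme [band_scheme()] for the component bands (source dialect)
#' @param band_amplitudes amplitude per band
#' @return a [recording()] of ROI series
#' @export
gen_roi_series <- function(roi_labels = roi_atlas_19(), fs = 250,
                           duration_s = 240, coupling_spec = list(),
                           seed = 1L, scheme = band_scheme("source"),
                           band_amplitudes = default_band_amplitudes()) {
  if (anyDuplicated(roi_labels)) stop("ROI labels must be unique", call. = FALSE)
  if (fs <= 120) stop("fs must exceed 120 Hz", call. = FALSE)
  n <- round(duration_s * fs)
  for (cp in coupling_spec) {
    if (!all(c(cp$roi_a, cp$roi_b) %in% roi_labels))
      stop("coupling references unknown ROI label", call. = FALSE)
    if (!cp$band %in% names(scheme$bands))
      stop("coupling references unknown band: ", cp$band, call. = FALSE)
    if (cp$lag < 0 || cp$lag >= n)
      stop("coupling lag must be in [0, duration in samples)", call. = FALSE)
    if (cp$strength < 0 || cp$strength > 1)
      stop("coupling strength must be in [0, 1]", call. = FALSE)
  }
  data <- with_seed_(seed, {
    comp <- array(0, dim = c(length(roi_labels), length(scheme$bands), n),
                  dimnames = list(roi_labels, names(scheme$bands), NULL))
    for (i in seq_along(roi_labels))
      for (b in names(scheme$bands))
        comp[i, b, ] <- band_component(n, fs, scheme$bands[[b]])
    for (cp in coupling_spec) {
      src <- comp[cp$roi_a, cp$band, ]
      own <- comp[cp$roi_b, cp$band, ]
      comp[cp$roi_b, cp$band, ] <-
        cp$strength * circ_shift(src, cp$lag) +
        sqrt(1 - cp$strength^2) * own
    }
    out <- matrix(0, length(roi_labels), n)
    for (i in seq_along(roi_labels))
      for (b in names(scheme$bands))
        out[i, ] <- out[i, ] + band_amplitudes[[b]] * comp[i, b, ]
    out
  })
  recording(data, roi_labels, fs)
}

#' Generate a synthetic RR-interval series with controlled Poincare geometry
#'
#' The series is mean + slow component + fast component + linear trend.
#' The slow component is a first-order autoregressive process and the fast
#' component white noise, with variances solved from the target lag-1
#' autocovariance structure: `sd1^2 = gamma0 - gamma1`,
#' `sd2^2 = gamma0 + gamma1`, so `gamma0 = (sd1^2 + sd2^2)/2` and
#' `gamma1 = (sd2^2 - sd1^2)/2 = a * var(slow)` with `|a| = 0.9`.
#' `sd1_trend_ms_per_min` scales the fast component linearly over time
#' (shrinking or growing the perpendicular spread within the task), and
#' `trend_ms_per_min` adds a linear drift to the mean.
#'
#' @param n_beats number of beats
#' @param mean_ms mean RR interval, ms
#' @param sd1_ms,sd2_ms target Poincare SDs, ms
#' @param trend_ms_per_min linear drift of the mean, ms per minute
#' @param sd1_trend_ms_per_min linear drift of SD1, ms per minute
#' @param seed integer seed
#' @return an [rri_series()]
#' @export
gen_rri <- function(n_beats, mean_ms = 790, sd1_ms = 20, sd2_ms = 45,
                    trend_ms_per_min = 0, sd1_trend_ms_per_min = 0,
                    seed = 1L) {
  stop_if_not_scalar_num(n_beats, "n_beats", lower = 3)
  stop_if_not_scalar_num(mean_ms, "mean_ms", lower = .Machine$double.eps)
  stop_if_not_scalar_num(sd1_ms, "sd1_ms", lower = 0)
  stop_if_not_scalar_num(sd2_ms, "sd2_ms", lower = 0)
  gamma0 <- (sd1_ms^2 + sd2_ms^2) / 2
  gamma1 <- (sd2_ms^2 - sd1_ms^2) / 2
  a <- if (gamma1 == 0) 0 else 0.9 * sign(gamma1)
  v_slow <- if (a == 0) 0 else gamma1 / a
  v_fast <- gamma0 - v_slow
  if (v_fast < 0)
    stop("infeasible SD1/SD2 combination for the AR(1)+white decomposition",
         call. = FALSE)
  n <- as.integer(n_beats)
  iv <- with_seed_(seed, {
    slow <- numeric(n)
    if (v_slow > 0) {
      slow[1] <- stats::rnorm(1, 0, sqrt(v_slow))
      innov <- stats::rnorm(n - 1, 0, sqrt(v_slow * (1 - a^2)))
      for (t in 2:n) slow[t] <- a * slow[t - 1] + innov[t - 1]
    }
    fast <- stats::rnorm(n, 0, sqrt(max(v_fast, 0)))
    t_min <- (seq_len(n) - 1) * mean_ms / 60000 # approximate beat time, minutes
    if (sd1_trend_ms_per_min != 0) {
      if (sd1_ms <= 0) stop("sd1 trend requires sd1_ms > 0", call. = FALSE)
      fast <- fast * pmax(0, 1 + sd1_trend_ms_per_min * t_min / sd1_ms)
    }
    mean_ms + slow + fast + trend_ms_per_min * t_min
  })
  if (any(iv <= 0))
    stop("parameter combination produced non-positive intervals", call. = FALSE)
  rri_series(iv)
}
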