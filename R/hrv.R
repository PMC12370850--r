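# Lorenz-plot (Poincare) heart-rate-variability analysis:
# RRI container, R-peak detection, SD1/SD2/CSI/CVI, segment change scores.

#' RR-interval series
#'
#' Ordered RR intervals in milliseconds with cumulative-time addressing
#' (beat n is placed at `t0 + cumsum(intervals)[n] / 1000` seconds).
#'
#' @param intervals numeric vector of RR intervals, ms, all > 0
#' @param t0 time origin in seconds
#' @return an `rri_series`
#' @export
rri_series <- function(intervals, t0 = 0) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1L || !all(is.finite(intervals)) || any(intervals <= 0))
    stop("RR intervals must be finite and positive", call. = FALSE)
  structure(list(intervals = intervals, t0 = t0), class = "rri_series")
}

#' Beat times of an RRI series, seconds
#' @param rri an [rri_series()]
#' @return numeric vector, one time per beat (end of each interval)
#' @export
rri_times <- function(rri) rri$t0 + cumsum(rri$intervals) / 1000

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series: %d intervals, mean %.1f ms, span %.1f s>\n",
              length(x$intervals), mean(x$intervals),
              sum(x$intervals) / 1000))
  invisible(x)
}

#' Range sanity filter for RR intervals
#'
#' Drops physiologically implausible intervals (default outside
#' 300-2000 ms); the number removed is recorded in attribute `n_removed`.
#' No interpolation is attempted.
#'
#' @param rri an [rri_series()]
#' @param min_ms,max_ms acceptance range in ms
#' @return filtered `rri_series` with attribute `n_removed`
#' @export
sanitize_rri <- function(rri, min_ms = 300, max_ms = 2000) {
  keep <- rri$intervals >= min_ms & rri$intervals <= max_ms
  out <- rri_series(rri$intervals[keep], t0 = rri$t0)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' R-peak detection on a single-channel ECG
#'
#' Adaptive robust-threshold peak picking: samples deviating from the
#' channel median by more than `threshold_mads` robust SDs are candidate
#' R-peaks; candidates closer together than the refractory period are
#' merged onto the local maximum. Successive peak-time differences are
#' returned in ms.
#'
#' @param ecg a single-channel [recording()] with `fs >= 250` Hz
#' @param refractory_s minimum peak separation, seconds
#' @param threshold_mads candidate threshold in robust standard deviations
#' @return an [rri_series()]
#' @export
detect_rpeaks <- function(ecg, refractory_s = 0.25, threshold_mads = 4) {
  stopifnot(inherits(ecg, "recording"))
  if (ecg$fs < 250) stop("ECG sampling rate must be >= 250 Hz", call. = FALSE)
  x <- ecg$data[1L, ]
  med <- stats::median(x)
  rsd <- stats::mad(x)
  thr <- med + threshold_mads * rsd
  cand <- which(x > thr)
  if (length(cand) < 3L)
    stop("fewer than 3 detected R-peaks (no QRS-like activity?)", call. = FALSE)
  gap <- round(refractory_s * ecg$fs)
  breaks <- c(0L, which(diff(cand) > gap), length(cand))
  peaks <- integer(length(breaks) - 1L)
  for (i in seq_len(length(breaks) - 1L)) {
    grp <- cand[(breaks[i] + 1L):breaks[i + 1L]]
    peaks[i] <- grp[which.max(x[grp])]
  }
  if (length(peaks) < 3L)
    stop("fewer than 3 detected R-peaks after refractory merging", call. = FALSE)
  rri_series(diff(peaks) / ecg$fs * 1000, t0 = peaks[1L] / ecg$fs)
}

#' Lorenz-plot indices
#'
#' From the Poincare point cloud (RRI_n, RRI_n+1): `sd1` is the sample SD
#' of `(RRI_{n+1} - RRI_n)/sqrt(2)` (spread perpendicular to the identity
#' line, short-term/vagal) and `sd2` the sample SD of
#' `(RRI_{n+1} + RRI_n)/sqrt(2)` (spread along it). The transverse and
#' longitudinal axes are `T = 4*sd1`, `L = 4*sd2`; the cardiac sympathetic
#' index is `CSI = L/T` and the cardiac vagal index `CVI = log10(L*T)`
#' (Toichi convention; natural log available via `log_base`).
#'
#' CSI is undefined (NA, `defined = FALSE`) when `sd1 = 0`; CVI when either
#' SD is zero. No silent infinities.
#'
#' @param rri an [rri_series()] with at least 3 intervals
#' @param log_base `"log10"` or `"ln"` for CVI
#' @return a `lorenz_indices`: sd1, sd2, L, T, csi, cvi, n_points, defined
#' @export
lorenz_indices <- function(rri, log_base = c("log10", "ln")) {
  stopifnot(inherits(rri, "rri_series"))
  log_base <- match.arg(log_base)
  iv <- rri$intervals
  if (length(iv) < 3L) stop("need at least 3 intervals", call. = FALSE)
  x <- iv[-length(iv)]
  y <- iv[-1L]
  sd1 <- stats::sd((y - x) / sqrt(2))
  sd2 <- stats::sd((y + x) / sqrt(2))
  L <- 4 * sd2
  Tt <- 4 * sd1
  csi <- if (sd1 > 0) L / Tt else NA_real_
  cvi <- if (sd1 > 0 && sd2 > 0) {
    if (log_base == "log10") log10(L * Tt) else log(L * Tt)
  } else NA_real_
  structure(list(sd1 = sd1, sd2 = sd2, L = L, T = Tt, csi = csi, cvi = cvi,
                 n_points = length(x), defined = sd1 > 0 && sd2 > 0,
                 log_base = log_base),
            class = "lorenz_indices")
}

#' @export
print.lorenz_indices <- function(x, ...) {
  cat(sprintf("<lorenz_indices: SD1 %.2f ms, SD2 %.2f ms, CSI %s, CVI %s (%s)>\n",
              x$sd1, x$sd2,
              if (is.na(x$csi)) "undefined" else sprintf("%.3f", x$csi),
              if (is.na(x$cvi)) "undefined" else sprintf("%.3f", x$cvi),
              x$log_base))
  invisible(x)
}

subset_rri_by_time <- function(rri, from_s, to_s, closed_left = TRUE) {
  t <- rri_times(rri) - rri$t0
  keep <- if (closed_left) t >= from_s & t <= to_s else t > from_s & t <= to_s
  rri$intervals[keep]
}

#' Whole-task and first/last-minute Lorenz indices with change scores
#'
#' Computes [lorenz_indices()] for the entire series, the first minute of
#' the task, and the last minute; beats are assigned to segments by their
#' R-peak time. Change scores subtract the first-minute value from the
#' last-minute value (CSI, CVI, and mean RRI).
#'
#' @param rri an [rri_series()] spanning at least `2 * segment_s` seconds
#' @param segment_s segment length, seconds
#' @param log_base CVI logarithm base, see [lorenz_indices()]
#' @return a `segmented_indices`: total / first_min / last_min
#'   `lorenz_indices` plus csi_change, cvi_change, rri_change (ms)
#' @export
segment_indices <- function(rri, segment_s = 60, log_base = c("log10", "ln")) {
  stopifnot(inherits(rri, "rri_series"))
  log_base <- match.arg(log_base)
  span <- sum(rri$intervals) / 1000
  if (span < 2 * segment_s)
    stop(sprintf("series spans %.1f s < 2 x %g s segments", span, segment_s),
         call. = FALSE)
  first_iv <- subset_rri_by_time(rri, 0, segment_s)
  last_iv <- subset_rri_by_time(rri, span - segment_s, span, closed_left = FALSE)
  if (length(first_iv) < 3L || length(last_iv) < 3L)
    stop("segment with fewer than 3 beats", call. = FALSE)
  total <- lorenz_indices(rri, log_base)
  first <- lorenz_indices(rri_series(first_iv), log_base)
  last <- lorenz_indices(rri_series(last_iv), log_base)
  structure(list(
    total = total, first_min = first, last_min = last,
    csi_change = last$csi - first$csi,
    cvi_change = last$cvi - first$cvi,
    rri_change = mean(last_iv) - mean(first_iv)),
    class = "segmented_indices")
}

#' @export
print.segmented_indices <- function(x, ...) {
  cat("<segmented_indices>\n")
  cat(sprintf("  total:     CSI %.3f  CVI %.3f  mean RRI n/a\n",
              x$total$csi, x$total$cvi))
  cat(sprintf("  changes:   CSI %+.3f  CVI %+.3f  RRI %+.1f ms\n",
              x$csi_change, x$cvi_change, x$rri_change))
  invisible(x)
}

#' Read an RRI text file (one interval in ms per line, '#' comments)
#' @param path file path
#' @return an [rri_series()]
#' @export
read_rri <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rri_series(as.numeric(lines))
}

#' Write an RRI series as plain text (ms per line)
#' @param rri an [rri_series()]
#' @param path output path
#' @param digits significant digits (17 = exact double round trip)
#' @return `path`, invisibly
#' @export
write_rri <- function(rri, path, digits = 10) {
  writeLines(c("# RR intervals [ms]",
               formatC(rri$intervals, digits = digits, format = "g")), path)
  invisible(path)
}
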