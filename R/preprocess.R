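#' Zero-phase band-pass filter
#'
#' Cascade of a 4th-order Butterworth high-pass and low-pass, each applied
#' forward and backward (zero phase, so the phase structure that lagged
#' phase synchronization relies on downstream is untouched). The channel
#' mean (DC) is removed first. Defaults reproduce the 1.5-60 Hz analysis
#' band.
#'
#' @param rec a [recording()]
#' @param low high-pass cutoff, Hz
#' @param high low-pass cutoff, Hz
#' @param order filter order for each cascade stage
#' @return a filtered `recording` of identical dimensions
#' @export
bandpass <- function(rec, low = 1.5, high = 60, order = 4) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("need 0 < low < high < fs/2 (got low=%g, high=%g, fs/2=%g)",
                 low, high, nyq), call. = FALSE)
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    x <- out[i, ] - mean(out[i, ])
    x <- signal::filtfilt(hp, x)
    out[i, ] <- signal::filtfilt(lp, x)
  }
  recording(out, rec$labels, rec$fs, rec$annotations)
}

#' Trim task edges
#'
#' Drops the first and last `trim_s` seconds (movement-artifact-prone task
#' onset/offset) and returns the central segment. Annotations are shifted
#' and clipped accordingly.
#'
#' @param rec a [recording()]
#' @param trim_s seconds to remove from each end
#' @return the trimmed `recording`
#' @export
trim_edges <- function(rec, trim_s = 30) {
  stopifnot(inherits(rec, "recording"))
  stop_if_not_scalar_num(trim_s, "trim_s", lower = 0)
  if (trim_s == 0) return(rec)
  n <- ncol(rec$data)
  k <- round(trim_s * rec$fs)
  if (n - 2 * k < 1)
    stop(sprintf("recording too short to trim: %.3f s <= 2 x %g s",
                 n / rec$fs, trim_s), call. = FALSE)
  ann <- rec$annotations
  if (!is.null(ann) && nrow(ann)) {
    ann$start_s <- ann$start_s - trim_s
    ann$end_s <- ann$end_s - trim_s
    keep <- ann$end_s > 0 & ann$start_s < (n - 2 * k) / rec$fs
    ann <- ann[keep, , drop = FALSE]
  }
  recording(rec$data[, (k + 1):(n - k), drop = FALSE], rec$labels, rec$fs, ann)
}

#' Windowed amplitude artifact rejection
#'
#' Splits the recording into consecutive `win_s`-second windows and drops
#' any window in which some channel's peak absolute deviation from its
#' median exceeds `z_amp` robust standard deviations (median absolute
#' deviation x 1.4826, so spikes do not inflate their own threshold).
#' Surviving windows are concatenated. A deliberately simple stand-in for
#' subspace-reconstruction artifact chains, which target human artifacts
#' absent from synthetic data.
#'
#' @param rec a [recording()]
#' @param z_amp rejection threshold in robust standard deviations
#' @param win_s window length, seconds
#' @return list with `recording` (kept data) and `mask`, a `rejection_mask`
#'   (data.frame of kept windows plus `rejected_fraction`)
#' @export
reject_artifacts <- function(rec, z_amp = 10, win_s = 1) {
  stopifnot(inherits(rec, "recording"))
  if (win_s < 1 / rec$fs) stop("`win_s` must cover at least one sample", call. = FALSE)
  n <- ncol(rec$data)
  L <- max(1L, round(win_s * rec$fs))
  starts <- seq(1L, n, by = L)
  med <- apply(rec$data, 1L, stats::median)
  rsd <- apply(rec$data, 1L, stats::mad) # mad() already scales by 1.4826
  rsd[rsd == 0] <- Inf                    # flat channel can never reject
  keep <- logical(length(starts))
  for (w in seq_along(starts)) {
    idx <- starts[w]:min(n, starts[w] + L - 1L)
    dev <- abs(rec$data[, idx, drop = FALSE] - med) / rsd
    keep[w] <- max(dev) <= z_amp
  }
  if (!any(keep)) stop("all windows rejected", call. = FALSE)
  kept_idx <- unlist(lapply(which(keep), function(w)
    starts[w]:min(n, starts[w] + L - 1L)))
  mask <- structure(list(
    kept_windows = data.frame(
      start_s = (starts[keep] - 1L) / rec$fs,
      end_s = pmin(n, starts[keep] + L - 1L) / rec$fs),
    rejected_fraction = 1 - length(kept_idx) / n),
    class = "rejection_mask")
  list(recording = recording(rec$data[, kept_idx, drop = FALSE],
                             rec$labels, rec$fs),
       mask = mask)
}

#' @export
print.rejection_mask <- function(x, ...) {
  cat(sprintf("<rejection_mask: %d windows kept, %.1f%% rejected>\n",
              nrow(x$kept_windows), 100 * x$rejected_fraction))
  invisible(x)
}
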