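# Lagged phase synchronization (LPS) between ROI time series.
#
# LPS keeps only the non-instantaneous component of phase synchronization,
# Im(rho)^2 / (1 - Re(rho)^2) of the complex coherency rho of unit-modulus
# normalized spectra, which makes it robust to zero-lag mixing such as
# volume conduction.

# normalized Fourier coefficients per window: array [channel, bin, window]
normalized_window_ffts <- function(rec, band, window_s, overlap) {
  n <- ncol(rec$data)
  L <- round(window_s * rec$fs)
  if (L > n) stop("recording shorter than one window", call. = FALSE)
  seg <- welch_segments(n, L, overlap)
  if (length(seg$starts) < 2L) stop("need at least 2 windows", call. = FALSE)
  freqs <- (0:(L - 1)) * rec$fs / L
  half <- freqs <= rec$fs / 2
  sel <- which(band_bins(freqs, band) & half)
  if (!length(sel)) stop("band contains no frequency bins at this resolution",
                         call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
  nch <- nrow(rec$data)
  Z <- array(0i, dim = c(nch, length(sel), length(seg$starts)))
  for (k in seq_along(seg$starts)) {
    s <- seg$starts[k]
    seg_data <- rec$data[, s:(s + L - 1L), drop = FALSE] * rep(w, each = nch)
    X <- t(stats::mvfft(t(seg_data)))[, sel, drop = FALSE]
    m <- Mod(X)
    m[m == 0] <- 1 # zero coefficient carries no phase; contributes 0
    Z[, , k] <- ifelse(Mod(X) == 0, 0i, X / m)
  }
  list(Z = Z, freqs = freqs[sel], n_windows = length(seg$starts))
}

# window-averaged complex coherency per bin: array [ch, ch, bin]
coherency_bins <- function(rec, band, window_s, overlap) {
  nf <- normalized_window_ffts(rec, band, window_s, overlap)
  nch <- dim(nf$Z)[1L]
  nb <- dim(nf$Z)[2L]
  rho <- array(0i, dim = c(nch, nch, nb))
  for (b in seq_len(nb)) {
    M <- nf$Z[, b, , drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, nrow = nch)
    rho[, , b] <- (M %*% Conj(t(M))) / dim(M)[2L]
  }
  list(rho = rho, freqs = nf$freqs, n_windows = nf$n_windows)
}

#' Complex phase coherency between channels in a band
#'
#' Per window and in-band frequency bin, each channel's Fourier coefficient
#' is normalized to unit modulus (phase only); the coherency of a pair is
#' the average over windows and bins of one channel's normalized
#' coefficient times the conjugate of the other's. `|rho| <= 1`.
#'
#' @param x a [recording()] (e.g. an ROI source series set)
#' @param band `c(low, high)` Hz
#' @param window_s window length, seconds
#' @param overlap fractional overlap
#' @return complex channels x channels matrix with attributes `n_windows`
#'   and `n_bins`
#' @export
phase_coherency <- function(x, band, window_s = 2, overlap = 0.5) {
  stopifnot(inherits(x, "recording"))
  cb <- coherency_bins(x, band, window_s, overlap)
  rho <- apply(cb$rho, c(1, 2), mean)
  dimnames(rho) <- list(x$labels, x$labels)
  attr(rho, "n_windows") <- cb$n_windows
  attr(rho, "n_bins") <- length(cb$freqs)
  rho
}

#' Lagged phase synchronization of a complex coherency
#'
#' `LPS = Im(rho)^2 / (1 - Re(rho)^2)`, in `[0, 1]`. A purely real rho
#' (perfect zero-lag synchronization, denominator below `eps`) has no
#' lagged component and maps to 0. Vectorized over matrices/arrays.
#'
#' @param rho complex coherency value(s) with `|rho| <= 1`
#' @param eps degenerate-denominator guard
#' @return numeric value(s) in `[0, 1]`
#' @export
lps <- function(rho, eps = 1e-12) {
  if (any(Mod(rho) > 1 + 1e-9, na.rm = TRUE))
    stop("|rho| must be <= 1", call. = FALSE)
  re <- Re(rho)
  im <- Im(rho)
  den <- 1 - re^2
  out <- ifelse(den < eps, 0, im^2 / den)
  pmin(pmax(out, 0), 1)
}

#' Band-level LPS connectivity matrix
#'
#' The coherency is computed per in-band bin (averaged over windows), each
#' bin's lagged phase synchronization is taken, and bins are averaged. A
#' pure-delay coupled pair scores 1 at every bin with a nonzero phase;
#' instantaneous mixing scores only the small-sample bias level.
#'
#' @param x a [recording()] of ROI series
#' @param band `c(low, high)` Hz
#' @param window_s,overlap windowing, matched to [psd()] defaults
#' @param band_name optional label stored on the result
#' @return a `connectivity_matrix`: symmetric ROI x ROI matrix in `[0,1]`,
#'   diagonal `NA`, attributes `band`, `n_windows`, `n_bins`
#' @export
lps_matrix <- function(x, band, window_s = 2, overlap = 0.5, band_name = NULL) {
  stopifnot(inherits(x, "recording"))
  cb <- coherency_bins(x, band, window_s, overlap)
  vals <- apply(cb$rho, 3L, lps)
  v <- matrix(rowMeans(matrix(vals, nrow = length(x$labels)^2)),
              nrow = length(x$labels))
  v <- (v + t(v)) / 2 # symmetrize exactly (Im sign flips across the diagonal)
  diag(v) <- NA_real_
  dimnames(v) <- list(x$labels, x$labels)
  structure(v, class = c("connectivity_matrix", class(v)),
            band = band_name %||% sprintf("%g-%g Hz", band[1], band[2]),
            n_windows = cb$n_windows, n_bins = length(cb$freqs))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix: %d x %d, band %s, %d windows, %d bins>\n",
              nrow(x), ncol(x), attr(x, "band"), attr(x, "n_windows"),
              attr(x, "n_bins")))
  v <- x[upper.tri(x)]
  cat(sprintf("  LPS range %.4f - %.4f (median %.4f)\n",
              min(v), max(v), stats::median(v)))
  invisible(x)
}

#' Cohort functional-connectivity table
#'
#' Band-by-band LPS matrices for every subject and condition, returned in
#' long format.
#'
#' @param cohort a [gen_paired_cohort()] result
#' @param scheme a [band_scheme()], by default the source dialect
#' @param preprocess_fn optional function applied to each ROI recording
#' @param window_s,overlap windowing
#' @return data.frame: subject, condition, band, roi_a, roi_b, lps
#'   (upper-triangle pairs only)
#' @export
fc_table <- function(cohort, scheme = band_scheme("source"),
                     preprocess_fn = NULL, window_s = 2, overlap = 0.5) {
  stopifnot(inherits(scheme, "band_scheme"))
  labels_ref <- NULL
  rows <- list()
  for (subj in cohort$subjects) {
    for (cond in c("altruistic", "selfish")) {
      rec <- subj[[cond]]$roi
      if (is.null(rec)) stop("missing ROI series for ", subj$id, "/", cond,
                             call. = FALSE)
      if (is.null(labels_ref)) labels_ref <- rec$labels
      if (!identical(rec$labels, labels_ref))
        stop("mismatched ROI labels across subjects", call. = FALSE)
      if (!is.null(preprocess_fn)) rec <- preprocess_fn(rec)
      for (b in names(scheme$bands)) {
        m <- lps_matrix(rec, scheme$bands[[b]], window_s, overlap, band_name = b)
        ut <- which(upper.tri(m), arr.ind = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj$id, condition = cond, band = b,
          roi_a = labels_ref[ut[, 1L]], roi_b = labels_ref[ut[, 2L]],
          lps = m[ut], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
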