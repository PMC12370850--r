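#' Multichannel recording container
#'
#' A labelled channels-by-samples matrix with a sampling rate, the unit of
#' preprocessing, spectral, and connectivity analysis. Used for both scalp
#' EEG (10-20 labels) and ROI source series.
#'
#' @param data numeric matrix, channels x samples
#' @param labels character vector, one label per row of `data`
#' @param fs sampling rate in Hz
#' @param annotations optional data.frame with columns `start_s`, `end_s`, `tag`
#' @return a `recording` object
#' @export
recording <- function(data, labels, fs, annotations = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("`data` must be a finite numeric matrix", call. = FALSE)
  if (length(labels) != nrow(data))
    stop("label count (", length(labels), ") must equal channel count (",
         nrow(data), ")", call. = FALSE)
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  stop_if_not_scalar_num(fs, "fs", lower = .Machine$double.eps)
  rownames(data) <- labels
  structure(list(data = data, labels = as.character(labels), fs = fs,
                 annotations = annotations),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %d channels x %d samples, fs = %g Hz, %.3f s>\n",
              nrow(x$data), ncol(x$data), x$fs, rec_duration(x)))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `recording`
#' @return duration in seconds
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Write a recording as a delimited text matrix
#'
#' Format: a one-line header `#fs=<Hz>`, a CSV header row of channel labels,
#' then one CSV row per sample (samples x channels).
#'
#' @param rec a `recording`
#' @param path output file path
#' @param digits significant digits to write; 17 gives an exact double
#'   round trip, the default 7 keeps files small
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path, digits = 7) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#fs=%.10g", rec$fs), con)
  writeLines(paste(rec$labels, collapse = ","), con)
  m <- t(rec$data)
  lines <- apply(m, 1L, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#' @param path file path
#' @return a `recording`
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^#fs=", header))
    stop("not a recording file (missing #fs= header): ", path, call. = FALSE)
  fs <- as.numeric(sub("^#fs=", "", header))
  tab <- utils::read.csv(path, skip = 1L, header = TRUE, check.names = FALSE)
  recording(t(as.matrix(tab)), labels = colnames(tab), fs = fs)
}
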