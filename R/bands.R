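#' Frequency band schemes
#'
#' Two band dialects are used side by side: the \emph{sensor} scheme
#' (delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-60 Hz) for
#' scalp-electrode analyses, and the \emph{source} scheme
#' (delta 1-3.5, theta 4-8, alpha 8.5-13, beta 13.5-30, gamma 30.5-60 Hz)
#' for ROI-level analyses. Every caller selects a scheme explicitly.
#'
#' @param name `"sensor"` or `"source"`
#' @return a `band_scheme` object: list with `name` and a named list `bands`
#'   of `c(low, high)` Hz pairs
#' @examples
#' band_scheme("sensor")$bands$alpha
#' @export
band_scheme <- function(name = c("sensor", "source")) {
  name <- match.arg(name)
  bands <- switch(name,
    sensor = list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 60)),
    source = list(delta = c(1, 3.5), theta = c(4, 8), alpha = c(8.5, 13),
                  beta = c(13.5, 30), gamma = c(30.5, 60)))
  structure(list(name = name, bands = bands), class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("<band_scheme:", x$name, ">\n")
  for (b in names(x$bands))
    cat(sprintf("  %-6s %5.1f - %5.1f Hz\n", b, x$bands[[b]][1], x$bands[[b]][2]))
  invisible(x)
}

#' Standard 10-20 electrode montage (19 channels)
#'
#' @return character vector of the 19 electrode labels
#' @export
electrodes_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Default 19-region cortical ROI set
#'
#' Thirteen regions central to social-cognition networks (medial prefrontal
#' cortex, anterior cingulate, bilateral dorsolateral prefrontal cortex,
#' bilateral lateral temporal cortex, bilateral medial temporal lobe,
#' posterior cingulate, precuneus, medial frontal gyrus, bilateral fusiform)
#' plus six configurable additional regions completing the 19-ROI set.
#'
#' @return character vector of 19 ROI labels
#' @export
roi_atlas_19 <- function() {
  c("mPFC", "ACC", "DLPFC_L", "DLPFC_R",
    "LTC_L", "LTC_R", "MTL_L", "MTL_R",
    "PCC", "Precuneus", "MFG", "Fusiform_L", "Fusiform_R",
    "IPL_L", "IPL_R", "FEF_L", "FEF_R", "SMA", "V1")
}
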