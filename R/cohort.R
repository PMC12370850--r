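# Paired two-condition cohort simulation: per subject, an altruistic and a
# selfish bundle (EEG + ROI source series + RRI + task time), with
# condition effects additive on generator parameters and Gaussian subject
# random intercepts -- the simplest structure under which paired tests are
# exactly the right analysis.

#' Simulation configuration for a paired cohort
#'
#' Defaults mirror the target study conditions: 31 subjects, 19-channel
#' EEG, ~4-minute tasks trimmed by 30 s at each edge, RR intervals around
#' 790 ms with SD1/SD2 near 20/45 ms (total CSI ~ 2.25). Condition
#' contrasts are injected through `faa_shift` (frontal alpha asymmetry,
#' altruistic condition) and `csi_trend` (ms/min drift of the fast RRI
#' spread within the altruistic task; positive values grow SD1 over the
#' task, driving the CSI change score negative).
#'
#' @param n_subjects number of subjects (>= 2)
#' @param seed root seed; per-subject/condition/stream child seeds are
#'   derived deterministically
#' @param fs sampling rate, Hz (> 120)
#' @param duration_s task length, seconds (> `2 * trim_s + 4`)
#' @param trim_s edge trim applied by the analysis pipeline, seconds
#' @param band_amplitudes sensor band amplitudes for [gen_eeg()]
#' @param noise_sd 1/f background SD for [gen_eeg()]
#' @param faa_shift asymmetry offset added in the altruistic condition
#' @param csi_trend SD1 drift (ms/min) in the altruistic condition
#' @param time_shift_s task-time shift (s) in the altruistic condition
#' @param coupling_spec ROI coupling list for [gen_roi_series()]
#' @param rri_mean_ms,rri_sd1_ms,rri_sd2_ms RRI generator targets
#' @param time_mean_s mean task completion time, seconds
#' @param subject_sd named list of Gaussian random-intercept SDs:
#'   `asym` (FAA shift), `rri_mean` (ms), `time` (s), `sd1_frac`,
#'   `sd2_frac` (lognormal-ish fractional jitter of SD1/SD2)
#' @param within_sd named list of per-recording condition-level jitter SDs:
#'   `asym`, `time`
#' @return a `sim_config`
#' @export
sim_config <- function(n_subjects = 31, seed = 1L, fs = 250, duration_s = 240,
                       trim_s = 30,
                       band_amplitudes = default_band_amplitudes(),
                       noise_sd = 8, faa_shift = 0, csi_trend = 0,
                       time_shift_s = 0, coupling_spec = list(),
                       rri_mean_ms = 790, rri_sd1_ms = 20, rri_sd2_ms = 45,
                       time_mean_s = 215,
                       subject_sd = list(asym = 0.03, rri_mean = 60,
                                         time = 45, sd1_frac = 0.15,
                                         sd2_frac = 0.15),
                       within_sd = list(asym = 0.04, time = 25)) {
  stop_if_not_scalar_num(n_subjects, "n_subjects", lower = 2)
  stop_if_not_scalar_num(fs, "fs", lower = 120 + 1e-9)
  stop_if_not_scalar_num(trim_s, "trim_s", lower = 0)
  stop_if_not_scalar_num(duration_s, "duration_s",
                         lower = 2 * trim_s + 4 + 1e-9)
  if (abs(faa_shift) >= 1) stop("|faa_shift| must be < 1", call. = FALSE)
  for (cp in coupling_spec) {
    if (cp$strength < 0 || cp$strength > 1)
      stop("coupling strength must be in [0, 1]", call. = FALSE)
    if (cp$lag < 0) stop("coupling lag must be >= 0", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed), fs = fs,
    duration_s = duration_s, trim_s = trim_s,
    band_amplitudes = band_amplitudes, noise_sd = noise_sd,
    faa_shift = faa_shift, csi_trend = csi_trend,
    time_shift_s = time_shift_s, coupling_spec = coupling_spec,
    rri_mean_ms = rri_mean_ms, rri_sd1_ms = rri_sd1_ms,
    rri_sd2_ms = rri_sd2_ms, time_mean_s = time_mean_s,
    subject_sd = subject_sd, within_sd = within_sd),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config: n = %d, fs = %g Hz, %g s tasks ",
                     "(trim %g s), faa_shift = %g, csi_trend = %g, seed = %d>\n"),
              x$n_subjects, x$fs, x$duration_s, x$trim_s, x$faa_shift,
              x$csi_trend, x$seed))
  invisible(x)
}

#' Generate a paired two-condition cohort
#'
#' Every subject gets an altruistic and a selfish bundle (EEG recording,
#' ROI source series, RRI series, task time). Condition effects are
#' additive on the generator parameters; subjects carry Gaussian random
#' intercepts on asymmetry, RRI mean, SD1/SD2, and task time, so paired
#' tests are the appropriate downstream analysis. Condition order is
#' counterbalanced (recorded per subject). The configuration actually
#' used is stored as `$config` for parameter-recovery tests.
#'
#' @param config a [sim_config()]
#' @return a `paired_cohort`: list with `subjects` (each with `id`,
#'   `order`, `altruistic`, `selfish` bundles) and `config`
#' @export
gen_paired_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  subjects <- vector("list", cfg$n_subjects)
  n_beats <- ceiling(cfg$duration_s * 1000 / cfg$rri_mean_ms * 1.1) + 5
  for (i in seq_len(cfg$n_subjects)) {
    sseed <- child_seed(cfg$seed, i * 101L)
    intercepts <- with_seed_(sseed, list(
      asym = stats::rnorm(1, 0, cfg$subject_sd$asym),
      rri_mean = stats::rnorm(1, 0, cfg$subject_sd$rri_mean),
      time = stats::rnorm(1, 0, cfg$subject_sd$time),
      sd1_frac = exp(stats::rnorm(1, 0, cfg$subject_sd$sd1_frac)),
      sd2_frac = exp(stats::rnorm(1, 0, cfg$subject_sd$sd2_frac))))
    bundles <- list()
    for (ci in 1:2) {
      cond <- c("altruistic", "selfish")[ci]
      alt <- cond == "altruistic"
      cseed <- child_seed(sseed, ci)
      jit <- with_seed_(child_seed(cseed, 9L), list(
        asym = stats::rnorm(1, 0, cfg$within_sd$asym),
        time = stats::rnorm(1, 0, cfg$within_sd$time)))
      shift <- intercepts$asym + jit$asym + if (alt) cfg$faa_shift else 0
      shift <- max(min(shift, 0.95), -0.95)
      eeg <- gen_eeg(electrodes_1020(), cfg$fs, cfg$duration_s,
                     cfg$band_amplitudes, faa_shift = shift,
                     noise_sd = cfg$noise_sd, seed = child_seed(cseed, 1L))
      roi <- gen_roi_series(roi_atlas_19(), cfg$fs, cfg$duration_s,
                            cfg$coupling_spec, seed = child_seed(cseed, 2L))
      rri <- gen_rri(n_beats,
                     mean_ms = cfg$rri_mean_ms + intercepts$rri_mean,
                     sd1_ms = cfg$rri_sd1_ms * intercepts$sd1_frac,
                     sd2_ms = cfg$rri_sd2_ms * intercepts$sd2_frac,
                     sd1_trend_ms_per_min = if (alt) cfg$csi_trend else 0,
                     seed = child_seed(cseed, 3L))
      time_s <- cfg$time_mean_s + intercepts$time + jit$time +
        if (alt) cfg$time_shift_s else 0
      bundles[[cond]] <- list(eeg = eeg, roi = roi, rri = rri,
                              time_s = max(time_s, 30))
    }
    subjects[[i]] <- list(
      id = sprintf("S%02d", i),
      order = if (i %% 2 == 1L) c("altruistic", "selfish")
              else c("selfish", "altruistic"),
      altruistic = bundles$altruistic,
      selfish = bundles$selfish)
  }
  structure(list(subjects = subjects, config = cfg), class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort: %d subjects x 2 conditions, fs = %g Hz, %g s>\n",
              length(x$subjects), x$config$fs, x$config$duration_s))
  invisible(x)
}

config_to_list <- function(cfg) unclass(cfg)

#' Write a cohort to a directory layout
#'
#' Per subject and condition: `eeg.csv` and `roi.csv` (delimited matrices
#' with `#fs=` header), `rri.txt` (ms per line), `meta.json` (task time).
#' A top-level `manifest.json` records the full simulation configuration
#' and subject order, sufficient to regenerate the cohort bit-identically.
#'
#' @param cohort a `paired_cohort`
#' @param dir output directory (created if missing)
#' @param digits significant digits for signal files (17 = exact round trip)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir, digits = 7) {
  stopifnot(inherits(cohort, "paired_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort$subjects) {
    for (cond in c("altruistic", "selfish")) {
      d <- file.path(dir, subj$id, cond)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      b <- subj[[cond]]
      write_recording(b$eeg, file.path(d, "eeg.csv"), digits = digits)
      write_recording(b$roi, file.path(d, "roi.csv"), digits = digits)
      write_rri(b$rri, file.path(d, "rri.txt"), digits = max(digits, 10))
      # %.17g so the task time survives the text round trip bit-exactly
      writeLines(sprintf("{\"time_s\": %.17g}", b$time_s),
                 file.path(d, "meta.json"))
    }
  }
  manifest <- list(
    format = "physiopair-cohort-v1",
    subjects = lapply(cohort$subjects, function(s)
      list(id = s$id, order = s$order)),
    config = config_to_list(cohort$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory containing `manifest.json`
#' @return a `paired_cohort`
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  cfg_raw <- mf$config
  cfg_raw$band_amplitudes <- unlist(cfg_raw$band_amplitudes)
  cfg <- do.call(sim_config, cfg_raw[intersect(names(cfg_raw),
                                               names(formals(sim_config)))])
  subjects <- lapply(mf$subjects, function(s) {
    out <- list(id = s$id, order = unlist(s$order))
    for (cond in c("altruistic", "selfish")) {
      d <- file.path(dir, s$id, cond)
      meta <- jsonlite::read_json(file.path(d, "meta.json"),
                                  simplifyVector = TRUE)
      out[[cond]] <- list(
        eeg = read_recording(file.path(d, "eeg.csv")),
        roi = read_recording(file.path(d, "roi.csv")),
        rri = read_rri(file.path(d, "rri.txt")),
        time_s = meta$time_s)
    }
    out
  })
  structure(list(subjects = subjects, config = cfg), class = "paired_cohort")
}
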