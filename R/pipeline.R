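# End-to-end orchestration: simulate/load -> preprocess -> spectral + HRV
# + connectivity -> statistics -> report files.

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a cohort from `sim`) or `"files"`
#'   (load a cohort directory written by [write_cohort()])
#' @param sim a [sim_config()] (simulate mode)
#' @param input_dir cohort directory (files mode)
#' @param out_dir optional output directory; when given, the report is
#'   written as CSV/JSON
#' @param n_perm permutations for the max-statistic corrections
#' @param seed statistics seed (permutation reproducibility); defaults to
#'   the simulation seed in simulate mode
#' @param wilcoxon Wilcoxon p-value mode for [paired_compare()]
#' @param cvi_log_base CVI logarithm base, `"log10"` or `"ln"`
#' @param bp_low,bp_high analysis band-pass cutoffs, Hz
#' @param z_amp,artifact_win_s artifact-rejection parameters
#' @param window_s Welch/connectivity window, seconds
#' @param correlation_indices which Table-1 indices to correlate against
#'   ROI-power and connectivity maps
#' @return a `run_config`
#' @export
run_config <- function(mode = c("simulate", "files"), sim = NULL,
                       input_dir = NULL, out_dir = NULL, n_perm = 5000,
                       seed = NULL, wilcoxon = "auto",
                       cvi_log_base = c("log10", "ln"),
                       bp_low = 1.5, bp_high = 60, z_amp = 10,
                       artifact_win_s = 1, window_s = 2,
                       correlation_indices = c("faa", "csi_total",
                                               "cvi_total", "cvi_change",
                                               "rri_change")) {
  mode <- match.arg(mode)
  cvi_log_base <- match.arg(cvi_log_base)
  if (mode == "simulate") {
    if (!inherits(sim, "sim_config"))
      stop("simulate mode requires `sim = sim_config(...)`", call. = FALSE)
    seed <- seed %||% sim$seed
  } else {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("files mode requires an existing `input_dir`", call. = FALSE)
    if (is.null(seed)) stop("files mode requires `seed`", call. = FALSE)
  }
  structure(list(mode = mode, sim = sim, input_dir = input_dir,
                 out_dir = out_dir, n_perm = n_perm, seed = as.integer(seed),
                 wilcoxon = wilcoxon, cvi_log_base = cvi_log_base,
                 bp_low = bp_low, bp_high = bp_high, z_amp = z_amp,
                 artifact_win_s = artifact_win_s, window_s = window_s,
                 correlation_indices = correlation_indices),
            class = "run_config")
}

table1_row <- function(measure, x, y, res) {
  param <- res$method == "paired_t"
  center <- function(v) if (param) mean(v) else stats::median(v)
  spread <- function(v) if (param) stats::sd(v) else stats::IQR(v)
  data.frame(measure = measure,
             alt_center = center(x), alt_spread = spread(x),
             sel_center = center(y), sel_spread = spread(y),
             method = res$method, statistic = res$statistic,
             df = if (is.na(res$df %||% NA)) NA_real_ else res$df,
             p = res$p, effect = res$effect, effect_type = res$effect_type,
             effect_label = res$effect_label, tier = res$tier,
             stringsAsFactors = FALSE)
}

map_to_long <- function(cm, extra) {
  cbind(extra, cm$table, row.names = NULL)
}

wide_map <- function(tab, value_col) {
  # subjects x sites matrix from a long table with columns subject, site
  sites <- unique(tab$site)
  subs <- unique(tab$subject)
  m <- matrix(NA_real_, length(subs), length(sites),
              dimnames = list(subs, sites))
  m[cbind(match(tab$subject, subs), match(tab$site, sites))] <- tab[[value_col]]
  m
}

#' Run the end-to-end paired analysis
#'
#' Simulates or loads a paired cohort, preprocesses every EEG recording
#' (band-pass, edge trim, windowed artifact rejection; ROI series are
#' trimmed only), then computes frontal alpha asymmetry, sensor and ROI
#' relative band power, band-wise LPS connectivity, and Lorenz-plot HRV
#' indices, and finally the statistics layer: a Table-1-style paired
#' comparison table, FDR-corrected sensor topographies, permutation
#' max-statistic ROI power and connectivity contrasts, and index-vs-map
#' correlation maps. Deterministic given the seeds in the configuration.
#'
#' @param config a [run_config()]
#' @return a `report_bundle`: `table1`, `topography`, `roi_power`, `fc`,
#'   `correlations`, `hrv`, `rejections`, `provenance`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- switch(config$mode,
    simulate = gen_paired_cohort(config$sim),
    files = read_cohort(config$input_dir))
  cfg <- cohort$config
  scheme_sensor <- band_scheme("sensor")
  scheme_source <- band_scheme("source")

  prep_eeg <- function(rec) {
    r <- bandpass(rec, config$bp_low, config$bp_high)
    r <- trim_edges(r, cfg$trim_s)
    reject_artifacts(r, z_amp = config$z_amp, win_s = config$artifact_win_s)
  }
  prep_roi <- function(rec) trim_edges(rec, cfg$trim_s)

  subs <- vapply(cohort$subjects, `[[`, "", "id")
  conds <- c("altruistic", "selfish")
  faa_tab <- NULL
  hrv_tab <- NULL
  rej_tab <- NULL
  sensor_rows <- list()
  roi_rows <- list()
  fc_rows <- list()
  have_segments <- TRUE

  for (subj in cohort$subjects) {
    for (cond in conds) {
      b <- subj[[cond]]
      pe <- prep_eeg(b$eeg)
      rec <- pe$recording
      rej_tab <- rbind(rej_tab, data.frame(
        subject = subj$id, condition = cond,
        rejected_fraction = pe$mask$rejected_fraction))
      fa <- faa(rec, window_s = config$window_s)
      span <- sum(b$rri$intervals) / 1000
      seg <- if (span >= 120) {
        segment_indices(b$rri, log_base = config$cvi_log_base)
      } else {
        have_segments <- FALSE
        NULL
      }
      tot <- if (is.null(seg)) lorenz_indices(sanitize_rri(b$rri),
                                              log_base = config$cvi_log_base)
             else seg$total
      hrv_tab <- rbind(hrv_tab, data.frame(
        subject = subj$id, condition = cond,
        time_s = b$time_s, faa = fa$value,
        sd1 = tot$sd1, sd2 = tot$sd2,
        csi_total = tot$csi, cvi_total = tot$cvi,
        rri_total = mean(b$rri$intervals),
        csi_change = if (is.null(seg)) NA_real_ else seg$csi_change,
        cvi_change = if (is.null(seg)) NA_real_ else seg$cvi_change,
        rri_change = if (is.null(seg)) NA_real_ else seg$rri_change,
        stringsAsFactors = FALSE))

      spec <- psd(rec, window_s = config$window_s)
      for (bn in names(scheme_sensor$bands)) {
        rp <- relative_band_power(spec, scheme_sensor$bands[[bn]])
        sensor_rows[[length(sensor_rows) + 1L]] <- data.frame(
          subject = subj$id, condition = cond, site = names(rp), band = bn,
          rel_power = unname(rp), stringsAsFactors = FALSE)
      }
      roi_rec <- prep_roi(b$roi)
      spec_roi <- psd(roi_rec, window_s = config$window_s)
      for (bn in names(scheme_source$bands)) {
        rp <- relative_band_power(spec_roi, scheme_source$bands[[bn]])
        roi_rows[[length(roi_rows) + 1L]] <- data.frame(
          subject = subj$id, condition = cond, site = names(rp), band = bn,
          rel_power = unname(rp), stringsAsFactors = FALSE)
      }
      for (bn in names(scheme_source$bands)) {
        m <- lps_matrix(roi_rec, scheme_source$bands[[bn]],
                        window_s = config$window_s, band_name = bn)
        ut <- which(upper.tri(m), arr.ind = TRUE)
        fc_rows[[length(fc_rows) + 1L]] <- data.frame(
          subject = subj$id, condition = cond, band = bn,
          site = paste(roi_rec$labels[ut[, 1L]], roi_rec$labels[ut[, 2L]],
                       sep = "--"),
          lps = m[ut], stringsAsFactors = FALSE)
      }
    }
  }
  sensor_tab <- do.call(rbind, sensor_rows)
  roi_tab <- do.call(rbind, roi_rows)
  fc_tab <- do.call(rbind, fc_rows)

  # ---- Table-1 analogue: paired comparisons of scalar endpoints ----
  measures <- c("time_s", "faa", "csi_total", "cvi_total", "rri_total",
                "csi_change", "cvi_change", "rri_change")
  pretty <- c(time_s = "time", faa = "faa", csi_total = "csi_total",
              cvi_total = "cvi_total", rri_total = "rri_total",
              csi_change = "csi_change", cvi_change = "cvi_change",
              rri_change = "rri_change")
  table1 <- NULL
  for (m in measures) {
    xa <- hrv_tab[hrv_tab$condition == "altruistic", m][match(subs,
            hrv_tab$subject[hrv_tab$condition == "altruistic"])]
    xs <- hrv_tab[hrv_tab$condition == "selfish", m][match(subs,
            hrv_tab$subject[hrv_tab$condition == "selfish"])]
    if (any(!is.finite(xa)) || any(!is.finite(xs))) next
    if (all(xa == xs)) next
    res <- paired_compare(xa, xs, wilcoxon = config$wilcoxon)
    table1 <- rbind(table1, table1_row(pretty[[m]], xa, xs, res))
  }

  # ---- sensor topographies: per-band BH-FDR over electrodes ----
  topo <- NULL
  for (bn in names(scheme_sensor$bands)) {
    tb <- sensor_tab[sensor_tab$band == bn, ]
    Aw <- wide_map(tb[tb$condition == "altruistic", ], "rel_power")
    Bw <- wide_map(tb[tb$condition == "selfish", ], "rel_power")
    Bw <- Bw[rownames(Aw), colnames(Aw), drop = FALSE]
    ts <- paired_t_stats(Aw - Bw)
    praw <- t_p_value_vec(ts$t, ts$n - 1)
    cm <- bh_fdr(praw, sites = colnames(Aw))
    cm$table$stat <- ts$t
    topo <- rbind(topo, map_to_long(cm, data.frame(band = bn)))
  }

  # ---- ROI power and FC contrasts: permutation max-statistic ----
  roi_power <- NULL
  fc_maps <- NULL
  k <- 0L
  for (bn in names(scheme_source$bands)) {
    k <- k + 1L
    tb <- roi_tab[roi_tab$band == bn, ]
    Aw <- wide_map(tb[tb$condition == "altruistic", ], "rel_power")
    Bw <- wide_map(tb[tb$condition == "selfish", ], "rel_power")
    cm <- perm_maxstat_paired(Aw, Bw[rownames(Aw), colnames(Aw)],
                              n_perm = config$n_perm,
                              seed = child_seed(config$seed, 1000L + k))
    roi_power <- rbind(roi_power, map_to_long(cm, data.frame(band = bn)))

    tf <- fc_tab[fc_tab$band == bn, ]
    Af <- wide_map(tf[tf$condition == "altruistic", ], "lps")
    Bf <- wide_map(tf[tf$condition == "selfish", ], "lps")
    cmf <- perm_maxstat_paired(Af, Bf[rownames(Af), colnames(Af)],
                               n_perm = config$n_perm,
                               seed = child_seed(config$seed, 2000L + k))
    fc_maps <- rbind(fc_maps, map_to_long(cmf, data.frame(band = bn)))
  }

  # ---- index-vs-map correlations, per condition ----
  correlations <- NULL
  k <- 0L
  for (idx_name in config$correlation_indices) {
    if (!idx_name %in% names(hrv_tab)) next
    for (cond in conds) {
      idx <- hrv_tab[hrv_tab$condition == cond, idx_name][
        match(subs, hrv_tab$subject[hrv_tab$condition == cond])]
      if (any(!is.finite(idx)) || stats::sd(idx) == 0) next
      for (bn in names(scheme_source$bands)) {
        for (map_type in c("roi_power", "fc")) {
          k <- k + 1L
          tb <- if (map_type == "roi_power") {
            roi_tab[roi_tab$band == bn & roi_tab$condition == cond, ]
          } else {
            fc_tab[fc_tab$band == bn & fc_tab$condition == cond, ]
          }
          value_col <- if (map_type == "roi_power") "rel_power" else "lps"
          Mw <- wide_map(tb, value_col)[subs, , drop = FALSE]
          cm <- perm_maxstat_corr(idx, Mw, n_perm = config$n_perm,
                                  seed = child_seed(config$seed, 3000L + k))
          correlations <- rbind(correlations, map_to_long(cm,
            data.frame(index = idx_name, condition = cond, band = bn,
                       map_type = map_type)))
        }
      }
    }
  }

  provenance <- list(
    package = "physiopair",
    version = as.character(utils::packageVersion("physiopair")),
    mode = config$mode,
    stats_seed = config$seed,
    n_perm = config$n_perm,
    wilcoxon = config$wilcoxon,
    cvi_log_base = config$cvi_log_base,
    bandpass = c(config$bp_low, config$bp_high),
    window_s = config$window_s,
    sim = config_to_list(cfg),
    have_segment_scores = have_segments)

  bundle <- structure(list(
    table1 = table1, topography = topo, roi_power = roi_power, fc = fc_maps,
    correlations = correlations, hrv = hrv_tab, band_power_sensor = sensor_tab,
    band_power_roi = roi_tab, fc_values = fc_tab, rejections = rej_tab,
    provenance = provenance),
    class = "report_bundle")

  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk as CSV/JSON
#'
#' Output is plain text with no timestamps, so identical configurations
#' (including seeds) produce byte-identical files.
#'
#' @param bundle a `report_bundle` from [run_pipeline()]
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(bundle$table1, "table1.csv")
  wr(bundle$topography, "topography.csv")
  wr(bundle$roi_power, "roi_power.csv")
  wr(bundle$fc, "fc_comparison.csv")
  wr(bundle$correlations, "correlations.csv")
  wr(bundle$hrv, "hrv_indices.csv")
  wr(bundle$rejections, "rejections.csv")
  jsonlite::write_json(bundle$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  if (!is.null(x$table1)) {
    cat("  paired endpoints:\n")
    for (i in seq_len(nrow(x$table1)))
      cat(sprintf("    %-11s %s p = %.4f [%s], %s = %+.3f (%s)\n",
                  x$table1$measure[i], x$table1$method[i], x$table1$p[i],
                  x$table1$tier[i], x$table1$effect_type[i],
                  x$table1$effect[i], x$table1$effect_label[i]))
  }
  nsig <- function(df) if (is.null(df)) 0L else sum(df$significant, na.rm = TRUE)
  cat(sprintf("  topography: %d significant electrode-band cells (FDR)\n",
              if (is.null(x$topography)) 0L else sum(x$topography$rejected)))
  cat(sprintf("  roi_power: %d | fc: %d | correlations: %d significant (perm)\n",
              nsig(x$roi_power), nsig(x$fc), nsig(x$correlations)))
  invisible(x)
}

#' Write a miniature fixture cohort for tests and examples
#'
#' Six subjects, 125-Hz, 30-second tasks with trimming disabled, a known
#' injected frontal alpha asymmetry, and one pure-delay alpha coupling
#' (LTC_L -> LTC_R, 3-sample lag) that analysis must recover as the
#' connectivity-matrix maximum.
#'
#' @param outdir target directory
#' @param seed integer seed
#' @return the cohort directory path, invisibly
#' @export
make_fixtures <- function(outdir, seed = 42L) {
  cfg <- sim_config(
    n_subjects = 6, seed = seed, fs = 125, duration_s = 30, trim_s = 0,
    faa_shift = 0.15, noise_sd = 4,
    coupling_spec = list(list(roi_a = "LTC_L", roi_b = "LTC_R",
                              band = "alpha", lag = 3, strength = 1)))
  write_cohort(gen_paired_cohort(cfg), outdir, digits = 7)
  invisible(outdir)
}
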