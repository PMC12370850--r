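test_that("generators are bit-identical under identical seeds", {
  a <- gen_eeg(c("F3", "F4", "Cz"), fs = 250, duration_s = 10, seed = 99)
  b <- gen_eeg(c("F3", "F4", "Cz"), fs = 250, duration_s = 10, seed = 99)
  expect_identical(a$data, b$data)
  expect_false(identical(
    gen_eeg(c("Cz"), fs = 250, duration_s = 10, seed = 1)$data,
    gen_eeg(c("Cz"), fs = 250, duration_s = 10, seed = 2)$data))

  r1 <- gen_roi_series(c("mPFC", "ACC"), fs = 250, duration_s = 10, seed = 5)
  r2 <- gen_roi_series(c("mPFC", "ACC"), fs = 250, duration_s = 10, seed = 5)
  expect_identical(r1$data, r2$data)

  expect_identical(gen_rri(100, seed = 3)$intervals,
                   gen_rri(100, seed = 3)$intervals)

  cfg <- sim_config(n_subjects = 2, seed = 17, fs = 125, duration_s = 10,
                    trim_s = 0)
  c1 <- gen_paired_cohort(cfg)
  c2 <- gen_paired_cohort(cfg)
  expect_identical(c1$subjects[[2]]$selfish$eeg$data,
                   c2$subjects[[2]]$selfish$eeg$data)
  expect_identical(c1$subjects[[1]]$altruistic$rri$intervals,
                   c2$subjects[[1]]$altruistic$rri$intervals)
})

test_that("gen_eeg validates inputs and respects the montage", {
  expect_error(gen_eeg(c("F3", "XX"), seed = 1), "unknown electrode")
  expect_error(gen_eeg("Cz", fs = 100, seed = 1), "120")
  expect_error(gen_eeg("Cz", fs = 250, duration_s = 1, seed = 1), "duration")
  e <- gen_eeg(duration_s = 4, fs = 250, seed = 1)
  expect_equal(e$labels, electrodes_1020())
  expect_equal(ncol(e$data), 1000)
})

test_that("zero asymmetry gives FAA near zero, injected asymmetry recovers sign", {
  null_faas <- sapply(1:15, function(s)
    faa(gen_eeg(c("F3", "F4"), fs = 125, duration_s = 60, faa_shift = 0,
                seed = s))$value)
  expect_lt(abs(mean(null_faas)), 0.02)

  # symmetric +/- alpha amplitude offset must produce positive FAA nearly
  # always (Monte-Carlo sign recovery at the Parseval-predicted effect size)
  signs <- sapply(1:100, function(s)
    faa(gen_eeg(c("F3", "F4"), fs = 125, duration_s = 180, faa_shift = 0.2,
                seed = 1000 + s))$value > 0)
  expect_gte(sum(signs), 95)

  amps <- default_band_amplitudes()
  predicted <- oracle_rel_alpha(amps, 1.2) - oracle_rel_alpha(amps, 0.8)
  measured <- mean(sapply(1:10, function(s)
    faa(gen_eeg(c("F3", "F4"), fs = 125, duration_s = 180, faa_shift = 0.2,
                noise_sd = 0, seed = s))$value))
  expect_equal(measured, predicted, tolerance = 0.1)
})

test_that("gen_roi_series validates coupling specs", {
  expect_error(gen_roi_series(c("mPFC", "mPFC"), seed = 1), "unique")
  expect_error(gen_roi_series(c("mPFC", "ACC"), duration_s = 10, seed = 1,
                              coupling_spec = list(list(roi_a = "mPFC",
                                                        roi_b = "nope",
                                                        band = "alpha",
                                                        lag = 1,
                                                        strength = 1))),
               "unknown ROI")
  expect_error(gen_roi_series(c("mPFC", "ACC"), fs = 125, duration_s = 10,
                              seed = 1,
                              coupling_spec = list(list(roi_a = "mPFC",
                                                        roi_b = "ACC",
                                                        band = "alpha",
                                                        lag = 1e6,
                                                        strength = 1))),
               "lag")
  expect_error(gen_roi_series(c("mPFC", "ACC"), fs = 125, duration_s = 10,
                              seed = 1,
                              coupling_spec = list(list(roi_a = "mPFC",
                                                        roi_b = "ACC",
                                                        band = "alpha",
                                                        lag = 1,
                                                        strength = 2))),
               "strength")
})

test_that("paired cohort carries both bundles, order flags, and truth", {
  cfg <- sim_config(n_subjects = 3, seed = 5, fs = 125, duration_s = 10,
                    trim_s = 0, faa_shift = 0.1)
  coh <- gen_paired_cohort(cfg)
  expect_length(coh$subjects, 3)
  for (s in coh$subjects) {
    expect_true(all(c("altruistic", "selfish") %in% names(s)))
    expect_setequal(s$order, c("altruistic", "selfish"))
    for (cond in c("altruistic", "selfish")) {
      expect_s3_class(s[[cond]]$eeg, "recording")
      expect_s3_class(s[[cond]]$roi, "recording")
      expect_s3_class(s[[cond]]$rri, "rri_series")
      expect_true(s[[cond]]$time_s > 0)
    }
  }
  # counterbalancing alternates starting condition
  expect_false(identical(coh$subjects[[1]]$order, coh$subjects[[2]]$order))
  expect_identical(coh$config, cfg) # truth stored for recovery tests
  expect_equal(formals(sim_config)$n_subjects, 31)
})

test_that("cohort directory round trip preserves data and config", {
  cfg <- sim_config(n_subjects = 2, seed = 23, fs = 125, duration_s = 8,
                    trim_s = 0, faa_shift = 0.1)
  coh <- gen_paired_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir, digits = 17)
  back <- read_cohort(dir)
  expect_equal(back$subjects[[1]]$altruistic$eeg$data,
               coh$subjects[[1]]$altruistic$eeg$data)
  expect_equal(back$subjects[[2]]$selfish$rri$intervals,
               coh$subjects[[2]]$selfish$rri$intervals)
  expect_equal(back$config$faa_shift, cfg$faa_shift)
  expect_equal(back$config$n_subjects, cfg$n_subjects)
  expect_identical(back$subjects[[1]]$id, "S01")
})
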