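test_that("lps closed forms hold", {
  expect_equal(lps(0.7 + 0i), 0)          # pure zero-lag coupling
  expect_equal(lps(0.6i), 0.36)           # Re = 0: value is c^2
  phis <- c(0.3, 1.2, 2.5)
  expect_equal(lps(exp(1i * phis)), rep(1, 3)) # pure-delay limit
  expect_equal(lps(1 + 0i), 0)            # degenerate denominator clamp
  expect_error(lps(1.5 + 0.2i), "<= 1")
  expect_true(all(lps(0.5 * exp(1i * seq(0, 2 * pi, 0.1))) >= 0))
})

test_that("self-coherency is exactly one and duplicated channels are coherent", {
  set.seed(1)
  x <- rnorm(2500)
  rec <- recording(rbind(x, x, rnorm(2500)), c("A", "B", "C"), 250)
  rho <- phase_coherency(rec, c(8, 13))
  expect_equal(unname(Re(diag(rho))), rep(1, 3))
  expect_equal(Mod(rho["A", "B"]), 1)
  expect_lt(Mod(rho["A", "C"]), 0.5)
})

test_that("independent noise coherency follows the K^(-1/2) bias law", {
  mods <- sapply(1:12, function(s) {
    set.seed(s)
    rec <- recording(matrix(rnorm(2 * 30 * 250), 2), c("A", "B"), 250)
    rho <- phase_coherency(rec, c(8, 13))
    K <- attr(rho, "n_windows") * attr(rho, "n_bins")
    c(Mod(rho["A", "B"]), 1 / sqrt(K))
  })
  ratio <- mean(mods[1, ]) / mean(mods[2, ])
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 3)
})

test_that("pure-delay coupling saturates LPS; zero-lag mixing is suppressed", {
  band <- band_scheme("source")$bands$alpha
  delayed <- gen_roi_series(c("LTC_L", "LTC_R", "PCC"), fs = 1000,
                            duration_s = 20,
                            coupling_spec = list(list(roi_a = "LTC_L",
                                                      roi_b = "LTC_R",
                                                      band = "alpha",
                                                      lag = 25, strength = 1)),
                            seed = 5)
  m <- lps_matrix(delayed, band)
  expect_gt(m["LTC_L", "LTC_R"], 0.9)
  expect_equal(m["LTC_L", "LTC_R"], max(m, na.rm = TRUE))

  instant <- gen_roi_series(c("LTC_L", "LTC_R", "PCC"), fs = 1000,
                            duration_s = 20,
                            coupling_spec = list(list(roi_a = "LTC_L",
                                                      roi_b = "LTC_R",
                                                      band = "alpha",
                                                      lag = 0, strength = 0.9)),
                            seed = 5)
  m0 <- lps_matrix(instant, band)
  bias <- m0["LTC_L", "PCC"] # an uncoupled pair at the same problem size
  expect_lt(m0["LTC_L", "LTC_R"], max(0.15, 3 * bias))

  # empty coupling: everything sits at the small-sample bias level
  null_set <- gen_roi_series(c("mPFC", "ACC", "PCC", "V1"),
                             fs = 250, duration_s = 30, seed = 2)
  mn <- lps_matrix(null_set, band)
  expect_lt(max(mn, na.rm = TRUE), 0.25)
})

test_that("LPS is symmetric, amplitude-invariant, and bounded", {
  x <- gen_roi_series(c("mPFC", "ACC", "PCC"), fs = 250, duration_s = 20,
                      coupling_spec = list(list(roi_a = "mPFC", roi_b = "ACC",
                                                band = "theta", lag = 7,
                                                strength = 0.6)),
                      seed = 3)
  band <- band_scheme("source")$bands$theta
  m <- lps_matrix(x, band)
  expect_identical(m["mPFC", "ACC"], m["ACC", "mPFC"])
  expect_true(all(is.na(diag(m))))
  v <- m[upper.tri(m)]
  expect_true(all(v >= 0 & v <= 1))

  scaled_data <- x$data
  scaled_data[2, ] <- 40 * scaled_data[2, ]
  ms <- lps_matrix(recording(scaled_data, x$labels, x$fs), band)
  expect_equal(ms, m, tolerance = 1e-10)
})

test_that("coherency phase tracks the imposed delay (phase-ramp oracle)", {
  fs <- 250
  lag <- 10
  x <- gen_roi_series(c("mPFC", "ACC"), fs = fs, duration_s = 30,
                      coupling_spec = list(list(roi_a = "mPFC", roi_b = "ACC",
                                                band = "alpha", lag = lag,
                                                strength = 1)),
                      seed = 6)
  rho <- phase_coherency(x, band_scheme("source")$bands$alpha)
  expected_phase <- 2 * pi * mean(c(8.5, 13)) * lag / fs
  measured <- Arg(rho["mPFC", "ACC"]) # ACC lags mPFC by `lag` samples
  expect_equal(measured %% (2 * pi), expected_phase %% (2 * pi),
               tolerance = 0.15)
})

test_that("fc_table reproduces construction and validates labels", {
  coh <- tiny_cohort(n_subjects = 2, seed = 13, duration_s = 16,
                     coupling_spec = list(list(roi_a = "LTC_L",
                                               roi_b = "LTC_R",
                                               band = "alpha", lag = 3,
                                               strength = 1)))
  tab <- fc_table(coh)
  expect_true(all(tab$lps >= 0 & tab$lps <= 1))
  alpha_rows <- tab[tab$band == "alpha" & tab$subject == "S01" &
                      tab$condition == "altruistic", ]
  top <- alpha_rows[which.max(alpha_rows$lps), ]
  expect_setequal(c(top$roi_a, top$roi_b), c("LTC_L", "LTC_R"))

  coh$subjects[[2]]$selfish$roi$labels[1] <- "bogus"
  expect_error(fc_table(coh), "mismatched ROI labels")
})
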