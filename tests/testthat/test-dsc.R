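test_that("peak detection finds Lorentzian candidates and ignores baselines", {
  grid <- seq(7, 40, by = 0.05)
  one <- simulate_dsc(dsc_model(data.frame(center = 24.6, hwhm = 0.4,
                                           amplitude = 1),
                                baseline = c(0.1, 0.002)), grid)
  cand <- detect_peaks(one)
  expect_length(cand, 1)
  expect_equal(cand, 24.6, tolerance = 0.051)
  # two peaks 3 degC apart, HWHM 0.3 (brute-force local-maxima oracle
  # agrees: the noise-free trace has exactly two interior maxima)
  two <- simulate_dsc(dsc_model(data.frame(center = c(21.5, 24.5),
                                           hwhm = c(0.3, 0.3),
                                           amplitude = c(0.6, 1))), grid)
  y <- two$heat_flow
  oracle <- sum(diff(sign(diff(y))) == -2)
  expect_equal(oracle, 2)
  expect_length(detect_peaks(two), 2)
  # pure baseline: no candidates
  flat <- simulate_dsc(dsc_model(data.frame(center = numeric(0),
                                            hwhm = numeric(0),
                                            amplitude = numeric(0)),
                                 baseline = c(0.3, 0.01)), grid)
  expect_length(detect_peaks(flat), 0)
})

test_that("a noise-free Lorentzian is recovered to high precision", {
  grid <- seq(7, 40, by = 0.05)
  tg <- simulate_dsc(dsc_model(data.frame(center = 24.0, hwhm = 0.5,
                                          amplitude = 1.0)), grid)
  fit <- fit_tm(tg, n_peaks = 1)
  expect_equal(fit$centers, 24.0, tolerance = 1e-6)
  expect_equal(fit$hwhms, 0.5, tolerance = 1e-5)
  expect_equal(fit$amplitudes, 1.0, tolerance = 1e-5)
  expect_true(fit$converged)
})

test_that("preset thermograms return their transition temperatures", {
  f1 <- fit_tm(preset_dsc_curve(preset("dmpc_pure")), n_peaks = 1)
  expect_equal(f1$centers[1], 24.64, tolerance = 1e-4)
  f2 <- fit_tm(preset_dsc_curve(preset("nap10_aescin10")), n_peaks = 2)
  expect_equal(f2$centers[1], 24.00, tolerance = 1e-4)  # main (highest T)
  expect_lt(f2$centers[2], f2$centers[1])               # aescin-rich domain
})

test_that("automatic model selection accepts a second peak only when real", {
  grid <- seq(7, 40, by = 0.05)
  f_two <- fit_tm(preset_dsc_curve(preset("nap10_aescin08"),
                                   noise_sd = 0.01, seed = 11),
                  n_peaks = "auto")
  expect_equal(f_two$n_peaks, 2)
  f_one <- fit_tm(preset_dsc_curve(preset("dmpc_pure"),
                                   noise_sd = 0.01, seed = 11),
                  n_peaks = "auto")
  expect_equal(f_one$n_peaks, 1)
})

test_that("fitted Tm is unbiased and tight over noisy replicates", {
  grid <- seq(7, 40, by = 0.05)
  model <- function(sd) dsc_model(data.frame(center = 24.64, hwhm = 0.45,
                                             amplitude = 1),
                                  baseline = c(0.02, 0.001), noise_sd = sd)
  tms <- vapply(1:100, function(s) {
    fit_tm(simulate_dsc(model(0.02), grid, seed = s), n_peaks = 1)$centers
  }, numeric(1))
  expect_lt(abs(mean(tms) - 24.64), 0.02)
  expect_lt(sd(tms), 0.05)
})

test_that("translating the temperature axis translates the fitted centers", {
  grid <- seq(7, 40, by = 0.05)
  tg <- simulate_dsc(dsc_model(data.frame(center = 24.3, hwhm = 0.5,
                                          amplitude = 1),
                               noise_sd = 0.01), grid, seed = 2)
  shift <- 3.25
  tg2 <- thermogram(tg$temperature + shift, tg$heat_flow)
  f1 <- fit_tm(tg, n_peaks = 1)
  f2 <- fit_tm(tg2, n_peaks = 1)
  expect_equal(f2$centers, f1$centers + shift, tolerance = 1e-8)
})

test_that("degenerate inputs raise informative fitting errors", {
  grid <- seq(7, 40, by = 0.05)
  flat <- simulate_dsc(dsc_model(data.frame(center = numeric(0),
                                            hwhm = numeric(0),
                                            amplitude = numeric(0)),
                                 baseline = c(0.3, 0)), grid)
  expect_error(fit_tm(flat, n_peaks = 1), "candidate")
  one <- simulate_dsc(dsc_model(data.frame(center = 24, hwhm = 0.4,
                                           amplitude = 1)), grid)
  expect_error(fit_tm(one, n_peaks = 3), "n_peaks")
  expect_error(fit_tm(one, n_peaks = 1, window = c(38, 40)), "few points|candidate")
})
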