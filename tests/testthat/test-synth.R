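test_that("unmodulated limit produces perfectly regular 1000 ms beats", {
  cfg <- synth_config(duration_s = 60, hr_bpm = 60, rsa_amp_ms = 0,
                      mayer_amp_mmHg = 0, resp_abp_amp_mmHg = 0,
                      brs_slope_ms_per_mmHg = 0, noise_sd = 0, seed = 1)
  bp <- generate_beat_pair(cfg)
  expect_equal(bp$rr$values, rep(1000, length(bp$rr$values)))
  expect_equal(diff(bp$rr$times), rep(1, length(bp$rr$times) - 1), tolerance = 1e-9)
})

test_that("identical configuration and seed give bit-identical output", {
  cfg <- synth_config(duration_s = 30, seed = 42)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  for (ch in names(a$recording$channels))
    expect_identical(a$recording$channels[[ch]]$values,
                     b$recording$channels[[ch]]$values)
  expect_identical(a$truth, b$truth)
  # a different seed must change the noisy channels
  c2 <- generate_recording(synth_config(duration_s = 30, seed = 43))
  expect_false(identical(a$recording$channels$abp$values,
                         c2$recording$channels$abp$values))
})

test_that("ground truth beat times and RR intervals are consistent", {
  gr <- generate_recording(synth_config(duration_s = 120, seed = 3))
  tr <- gr$truth
  expect_true(all(diff(tr$beat_times) > 0))
  expect_equal(diff(tr$beat_times) * 1000,
               tr$rr_ms[-length(tr$rr_ms)], tolerance = 1e-6)
})

test_that("respiratory sinus arrhythmia puts the RR spectral peak at the breathing frequency", {
  cfg <- synth_config(duration_s = 300, hr_bpm = 60, resp_bpm = 6,
                      rsa_amp_ms = 20, mayer_amp_mmHg = 0,
                      resp_abp_amp_mmHg = 0, brs_slope_ms_per_mmHg = 0,
                      noise_sd = 0, seed = 5)
  bp <- generate_beat_pair(cfg)
  # oracle: direct DFT of the uniformly resampled RR series
  grid <- seq(bp$rr$times[1], bp$rr$times[length(bp$rr$times)], by = 0.25)
  v <- approx(bp$rr$times, bp$rr$values, xout = grid)$y
  v <- v - mean(v)
  amp <- Mod(fft(v))[seq_len(floor(length(v) / 2))]
  f <- (seq_along(amp) - 1) * 4 / length(v)
  keep <- f > 0.01                         # exclude the DC region
  peak_f <- f[keep][which.max(amp[keep])]
  expect_lt(abs(peak_f - 0.1), 0.01)
})

test_that("beat pair realizes the imposed baroreflex slope exactly at zero delay", {
  cfg <- synth_config(duration_s = 120, hr_bpm = 60, rsa_amp_ms = 0,
                      brs_slope_ms_per_mmHg = 10, brs_delay_s = 0,
                      noise_sd = 0, seed = 1)
  bp <- generate_beat_pair(cfg)
  fit <- lm(bp$rr$values ~ bp$sap$values)
  expect_equal(unname(coef(fit)[2]), 10, tolerance = 1e-6)
})

test_that("a lag scan locates the configured baroreflex delay in beats", {
  cfg <- synth_config(duration_s = 300, hr_bpm = 60, rsa_amp_ms = 0,
                      brs_slope_ms_per_mmHg = 10, brs_delay_s = 2,
                      noise_sd = 0, seed = 2)
  bp <- generate_beat_pair(cfg)
  rr <- bp$rr$values; sap <- bp$sap$values; n <- length(rr)
  slope_at_lag <- function(k)
    unname(coef(lm(rr[(k + 1):n] ~ sap[1:(n - k)]))[2])
  expect_equal(slope_at_lag(2), 10, tolerance = 1e-6)
  expect_lt(abs(slope_at_lag(0)), 0.9 * 10)
})

test_that("uncoupled pairs rarely show significant RR-SAP correlation", {
  sig <- vapply(1:100, function(s) {
    bp <- generate_beat_pair(null_pair_config(s))
    cor.test(bp$rr$values, bp$sap$values)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.90)
})

test_that("apply_transfer honours identity, scalar gain, and phase lead", {
  t <- seq(0, 200 - 0.25, by = 0.25)
  x <- uniform_signal(sin(2 * pi * 0.1 * t) + 0.3 * sin(2 * pi * 0.05 * t),
                      fs = 4)
  one <- function(f) rep(1, length(f)); zero <- function(f) rep(0, length(f))
  y_id <- apply_transfer(x, one, zero)
  expect_lt(max(abs(y_id$values - x$values)), 1e-9)
  y_g2 <- apply_transfer(x, function(f) rep(2, length(f)), zero)
  expect_lt(max(abs(y_g2$values - 2 * x$values)), 1e-9)
  # 36 deg at 0.1 Hz on a pure 0.1 Hz tone = 1.0 s lead
  # oracle: cross-correlation peak lag
  xs <- uniform_signal(sin(2 * pi * 0.1 * t), fs = 4)
  y <- apply_transfer(xs, one, function(f) rep(36, length(f)))
  lags <- 0:12
  cors <- vapply(lags, function(k) {
    n <- length(t)
    cor(xs$values[(k + 1):n], y$values[1:(n - k)])
  }, numeric(1))
  best_lag_s <- lags[which.max(cors)] / 4
  expect_equal(best_lag_s, 1.0, tolerance = 0.25)
})

test_that("noise-free identity transfer reproduces the pressure pulse in velocity", {
  cfg <- synth_config(duration_s = 60, noise_sd = 0, seed = 1,
                      ca_gain = function(f) rep(1, length(f)),
                      ca_phase_deg = function(f) rep(0, length(f)))
  gr <- generate_recording(cfg)
  abp <- gr$recording$channels$abp$values
  cbv <- gr$recording$channels$cbv$values
  expect_lt(max(abs((cbv - mean(cbv)) - (abp - mean(abp)))), 1e-6)
})

test_that("end-tidal CO2 falls as breathing rate rises", {
  lev <- vapply(c(6, 10, 15), function(rb) {
    gr <- generate_recording(synth_config(duration_s = 90, resp_bpm = rb,
                                          noise_sd = 0, seed = 1))
    gr$truth$etco2_epoch_mean_mmHg
  }, numeric(1))
  expect_true(all(diff(lev) < 0))
  expect_equal(lev[1] - lev[3], 0.43 * 9, tolerance = 1e-9)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(synth_config(hr_bpm = 200), "hr_bpm")
  expect_error(synth_config(duration_s = -1), "duration_s")
  expect_error(synth_config(rsa_amp_ms = -5), "rsa_amp_ms")
  expect_error(synth_config(noise_sd = c(abp = -1)), "noise_sd")
  expect_error(synth_config(noise_sd = c(bogus = 1)), "bogus")
  expect_error(generate_beat_pair(synth_config(duration_s = 3)),
               class = "breathca_insufficient_beats")
})
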