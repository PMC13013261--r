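test_that("identity and scalar-gain systems give unit coherence and exact gain", {
  x <- broadband_4hz(2048, seed = 1)
  sp <- cross_spectra(x, x)
  pow <- sp$msc[!is.na(sp$msc)]
  expect_true(all(abs(pow - 1) < 1e-9))
  expect_true(all(abs(sp$phase_deg[-1]) < 1e-6))
  expect_true(all(abs(sp$gain[-1] - 1) < 1e-9))
  y2 <- uniform_signal(2 * x$values, 4)
  sp2 <- cross_spectra(x, y2)
  expect_true(all(abs(sp2$gain[-1] - 2) < 1e-9))
  expect_true(all(abs(sp2$msc[-1] - 1) < 1e-9))
})

test_that("an imposed 36 degree lead at 0.1 Hz is recovered from broadband input", {
  x <- broadband_4hz(4096, seed = 2)
  y <- apply_transfer(x, function(f) rep(1, length(f)),
                      function(f) rep(36, length(f)))
  sp <- cross_spectra(x, y)
  k <- which.min(abs(sp$freqs - 0.1))
  expect_lt(abs(sp$phase_deg[k] - 36), 3)
})

test_that("input validation rejects wrong rates and short signals", {
  expect_error(cross_spectra(uniform_signal(rnorm(500), 5),
                             uniform_signal(rnorm(500), 5)),
               class = "breathca_bad_fs")
  expect_error(cross_spectra(uniform_signal(rnorm(100), 4),
                             uniform_signal(rnorm(100), 4)),
               class = "breathca_insufficient_data")
})

test_that("coherence threshold follows the window-count confidence formula", {
  expect_equal(coherence_critical(2), 0.95)
  expect_equal(coherence_critical(5), 0.5271, tolerance = 1e-4)
  expect_lt(abs(coherence_critical(100) - 0.0298), 1e-4)
  Ls <- 2:40
  expect_true(all(diff(vapply(Ls, coherence_critical, numeric(1))) < 0))
  expect_error(coherence_critical(1))
})

test_that("band averaging gates on coherence and applies the anti-wrap rule", {
  x <- broadband_4hz(4096, seed = 3)
  sp <- cross_spectra(x, x)
  bm <- band_metrics(sp, vlf_band())
  expect_true(bm$defined)
  expect_equal(bm$coherence, 1, tolerance = 1e-9)
  expect_equal(bm$ps_deg, 0, tolerance = 1e-6)
  expect_equal(bm$gain, 1, tolerance = 1e-9)
  expect_identical(bm$n_bins_used,
                   sum(sp$freqs >= 0.02 & sp$freqs <= 0.07))

  # all-gated band is flagged undefined, not zero
  fake <- structure(list(freqs = sp$freqs, msc = rep(0.01, length(sp$freqs)),
                         phase_deg = sp$phase_deg, gain = sp$gain,
                         n_windows = 4L), class = "spectral_estimate")
  und <- band_metrics(fake, vlf_band())
  expect_false(und$defined)
  expect_identical(und$n_bins_used, 0L)
  expect_true(is.na(und$ps_deg))

  # anti-wrap: negative phase below 0.1 Hz is excluded from the average
  neg <- structure(list(freqs = sp$freqs, msc = rep(1, length(sp$freqs)),
                        phase_deg = ifelse(seq_along(sp$freqs) %% 2 == 0, -20, 40),
                        gain = rep(1, length(sp$freqs)),
                        n_windows = 4L), class = "spectral_estimate")
  bm2 <- band_metrics(neg, vlf_band())
  expect_equal(bm2$ps_deg, 40)

  # a sliver between two bin centres holds no bins at all
  expect_error(band_metrics(sp, frequency_band(1.992, 1.998)),
               class = "breathca_empty_band")
})

test_that("a first-order high-pass system is recovered within 5 degrees in the VLF", {
  fc <- 0.07
  gain_fn <- function(f) f / sqrt(f^2 + fc^2)
  phase_fn <- function(f) { p <- atan2(fc, f) * 180 / pi; p[f <= 0] <- 0; p }
  x <- broadband_4hz(8192, seed = 4)
  y <- apply_transfer(x, gain_fn, phase_fn)
  sp <- cross_spectra(x, y)
  bm <- band_metrics(sp, vlf_band())
  keep <- sp$freqs >= 0.02 & sp$freqs <= 0.07
  expect_lt(abs(bm$ps_deg - mean(phase_fn(sp$freqs[keep]))), 5)
  expect_lt(abs(bm$gain - mean(gain_fn(sp$freqs[keep]))) /
              mean(gain_fn(sp$freqs[keep])), 0.1)
})

test_that("breathing-frequency bands map paced rates and floor degenerate spread", {
  b6 <- bf_band(6)
  expect_equal(c(b6$f_lo, b6$f_hi), c(0.08, 0.12))
  b10 <- bf_band(10)
  expect_equal(c(b10$f_lo, b10$f_hi), c(0.15, 0.19))
  b15 <- bf_band(15)
  expect_equal(c(b15$f_lo, b15$f_hi), c(0.23, 0.27))
  expect_error(bf_band(8), "6, 10 or 15")
  sp0 <- bf_band(15, sd_bpm = 0, mode = "spontaneous")
  expect_equal(c(sp0$f_lo, sp0$f_hi), c(0.23, 0.27))
  spw <- bf_band(15, sd_bpm = 6, mode = "spontaneous")
  expect_equal(c(spw$f_lo, spw$f_hi), c(9 / 60, 21 / 60))
})

test_that("coherence is scale invariant and phase antisymmetric under input swap", {
  x <- broadband_4hz(2048, seed = 5)
  set.seed(6)
  y <- uniform_signal(0.5 * x$values + rnorm(2048, 0, 0.5), 4)
  sp <- cross_spectra(x, y)
  sp_scaled <- cross_spectra(uniform_signal(7 * x$values, 4),
                             uniform_signal(0.2 * y$values, 4))
  expect_equal(sp_scaled$msc, sp$msc, tolerance = 1e-9)
  sp_swap <- cross_spectra(y, x)
  expect_equal(sp_swap$phase_deg[-1], -sp$phase_deg[-1], tolerance = 1e-9)
  # gain scales linearly with output scaling
  sp_g <- cross_spectra(x, uniform_signal(3 * y$values, 4))
  expect_equal(sp_g$gain[-1], 3 * sp$gain[-1], tolerance = 1e-9)
})
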