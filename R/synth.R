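#' Configuration for the synthetic cardio-cerebral signal generator
#'
#' Collects every tunable of the generator with physiologically realistic
#' defaults. The generator produces five synchronized 200 Hz channels (ABP,
#' CBv, ECG, EtCO2, respiration) plus beat-domain ground truth, so that each
#' analysis stage can be validated by parameter recovery:
#'
#' * RR intervals are coupled to systolic pressure through an imposed
#'   baroreflex slope (`brs_slope_ms_per_mmHg`) acting with a latency
#'   (`brs_delay_s`, discretized to the nearest whole beat),
#' * cerebral blood velocity is the pressure signal passed through a
#'   configurable linear transfer function (`ca_gain`, `ca_phase_deg`),
#' * systolic pressure carries a Mayer wave (0.1 Hz) and a
#'   breathing-frequency oscillation, RR additionally carries respiratory
#'   sinus arrhythmia,
#' * the capnogram is a breath-synchronous plateau wave whose end-tidal level
#'   falls linearly with respiratory rate.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling frequency in Hz (default 200).
#' @param hr_bpm mean heart rate, beats/min, must lie in \[40, 140\].
#' @param resp_bpm respiratory rate, breaths/min.
#' @param rsa_amp_ms amplitude of respiratory sinus arrhythmia in the RR
#'   series, ms.
#' @param mayer_amp_mmHg amplitude of the 0.1 Hz Mayer-wave oscillation of
#'   systolic pressure, mmHg.
#' @param resp_abp_amp_mmHg amplitude of the breathing-frequency oscillation
#'   of systolic pressure, mmHg.
#' @param brs_slope_ms_per_mmHg imposed baroreflex gain, ms of RR change per
#'   mmHg of systolic pressure deviation.
#' @param brs_delay_s baroreflex latency in seconds; realized as a discrete
#'   beat lag `round(brs_delay_s * hr_bpm / 60)`.
#' @param ca_gain function of frequency (Hz) returning the ABP to CBv
#'   amplitude ratio (cm s^-1 mmHg^-1). Default: first-order high-pass
#'   magnitude with corner 0.07 Hz and high-frequency gain 1.1, mimicking the
#'   high-pass character of cerebral autoregulation.
#' @param ca_phase_deg function of frequency (Hz) returning the phase lead of
#'   CBv over ABP in degrees. Default: first-order high-pass phase
#'   `atan(0.07 / f)` in degrees.
#' @param etco2_base_mmHg end-tidal CO2 plateau level at the reference
#'   breathing rate, mmHg.
#' @param etco2_slope_mmHg_per_bpm decline of the end-tidal level per
#'   breath/min above the reference rate.
#' @param etco2_ref_bpm reference breathing rate for the end-tidal level.
#' @param sap_base_mmHg mean systolic pressure, mmHg.
#' @param dbp_base_mmHg diastolic (baseline) pressure of the pulse wave, mmHg.
#' @param cbv_base_cm_s mean cerebral blood velocity, cm/s.
#' @param noise_sd named numeric vector of additive Gaussian noise standard
#'   deviations; recognized names: `abp`, `cbv`, `ecg`, `etco2` (waveform
#'   noise in channel units), `rr` (ms) and `sap` (mmHg) for beat-to-beat
#'   variability. Missing names default to 0.
#' @param seed integer seed; identical configurations (including the seed)
#'   produce bit-identical output.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 300, fs = 200, hr_bpm = 70, resp_bpm = 6,
                         rsa_amp_ms = 25, mayer_amp_mmHg = 3,
                         resp_abp_amp_mmHg = 4,
                         brs_slope_ms_per_mmHg = 10, brs_delay_s = 2,
                         ca_gain = NULL, ca_phase_deg = NULL,
                         etco2_base_mmHg = 36.5,
                         etco2_slope_mmHg_per_bpm = 0.43,
                         etco2_ref_bpm = 6,
                         sap_base_mmHg = 120, dbp_base_mmHg = 70,
                         cbv_base_cm_s = 60,
                         noise_sd = c(abp = 0.5, cbv = 0.5, ecg = 0.01,
                                      etco2 = 0.2, rr = 4, sap = 1),
                         seed = 1L) {
  if (is.null(ca_gain)) ca_gain <- function(f) 1.1 * f / sqrt(f^2 + 0.07^2)
  if (is.null(ca_phase_deg)) ca_phase_deg <- function(f) {
    p <- atan2(0.07, f) * 180 / pi
    p[f <= 0] <- 0
    p
  }
  ns <- c(abp = 0, cbv = 0, ecg = 0, etco2 = 0, rr = 0, sap = 0)
  if (length(noise_sd)) {
    if (is.null(names(noise_sd)) && length(noise_sd) == 1L) {
      ns[] <- noise_sd
    } else {
      bad <- setdiff(names(noise_sd), names(ns))
      if (length(bad)) stop("unknown noise_sd name(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
      ns[names(noise_sd)] <- noise_sd
    }
  }
  cfg <- structure(
    list(duration_s = duration_s, fs = fs, hr_bpm = hr_bpm, resp_bpm = resp_bpm,
         rsa_amp_ms = rsa_amp_ms, mayer_amp_mmHg = mayer_amp_mmHg,
         resp_abp_amp_mmHg = resp_abp_amp_mmHg,
         brs_slope_ms_per_mmHg = brs_slope_ms_per_mmHg,
         brs_delay_s = brs_delay_s,
         ca_gain = ca_gain, ca_phase_deg = ca_phase_deg,
         etco2_base_mmHg = etco2_base_mmHg,
         etco2_slope_mmHg_per_bpm = etco2_slope_mmHg_per_bpm,
         etco2_ref_bpm = etco2_ref_bpm,
         sap_base_mmHg = sap_base_mmHg, dbp_base_mmHg = dbp_base_mmHg,
         cbv_base_cm_s = cbv_base_cm_s,
         noise_sd = ns, seed = as.integer(seed)),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  chk <- function(val, name, lo = -Inf, hi = Inf) {
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) ||
        val < lo || val > hi)
      .err(sprintf("invalid configuration field `%s`: must be a finite number in [%s, %s]",
                   name, format(lo), format(hi)), "breathca_config_error")
  }
  chk(cfg$fs, "fs", lo = 1e-9)
  chk(cfg$duration_s, "duration_s", lo = 0)
  chk(cfg$hr_bpm, "hr_bpm", lo = 40, hi = 140)
  chk(cfg$resp_bpm, "resp_bpm", lo = 1e-9)
  chk(cfg$rsa_amp_ms, "rsa_amp_ms", lo = 0)
  chk(cfg$mayer_amp_mmHg, "mayer_amp_mmHg", lo = 0)
  chk(cfg$resp_abp_amp_mmHg, "resp_abp_amp_mmHg", lo = 0)
  chk(cfg$brs_slope_ms_per_mmHg, "brs_slope_ms_per_mmHg")
  chk(cfg$brs_delay_s, "brs_delay_s", lo = 0)
  chk(cfg$etco2_base_mmHg, "etco2_base_mmHg", lo = 0)
  chk(cfg$etco2_slope_mmHg_per_bpm, "etco2_slope_mmHg_per_bpm")
  chk(cfg$etco2_ref_bpm, "etco2_ref_bpm", lo = 0)
  if (any(!is.finite(cfg$noise_sd)) || any(cfg$noise_sd < 0))
    .err("invalid configuration field `noise_sd`: all entries must be finite and >= 0",
         "breathca_config_error")
  invisible(cfg)
}

# run code with the config's seed without disturbing the caller's RNG stream
with_config_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# beat-domain core: systolic pressures, RR intervals and beat times.
# RR_n (interval started by beat n) = RR0 + slope * (SAP_{n-k} - SAP_base)
#                                   + RSA(t_n) + noise.
generate_beats <- function(cfg, n_beats = NULL) {
  rr0 <- 60000 / cfg$hr_bpm
  if (is.null(n_beats))
    n_beats <- ceiling(cfg$duration_s / (rr0 / 1000)) + 5L
  k <- round(cfg$brs_delay_s * cfg$hr_bpm / 60)
  fr <- cfg$resp_bpm / 60
  sap_noise <- rnorm(n_beats, 0, cfg$noise_sd[["sap"]])
  rr_noise <- rnorm(n_beats, 0, cfg$noise_sd[["rr"]])
  t <- numeric(n_beats)
  sap <- numeric(n_beats)
  rr <- numeric(n_beats)
  for (n in seq_len(n_beats)) {
    sap[n] <- cfg$sap_base_mmHg +
      cfg$mayer_amp_mmHg * sin(2 * pi * 0.1 * t[n]) +
      cfg$resp_abp_amp_mmHg * sin(2 * pi * fr * t[n]) +
      sap_noise[n]
    drive <- if (n > k) sap[n - k] - cfg$sap_base_mmHg else 0
    rr[n] <- rr0 + cfg$brs_slope_ms_per_mmHg * drive +
      cfg$rsa_amp_ms * sin(2 * pi * fr * t[n]) + rr_noise[n]
    rr[n] <- min(max(rr[n], 300), 2000)  # physiologic guard
    if (n < n_beats) t[n + 1] <- t[n] + rr[n] / 1000
  }
  list(onset_times = t, rr_ms = rr, sap_mmHg = sap, lag_beats = k)
}

#' Generate a coupled beat-to-beat RR / SAP pair with known ground truth
#'
#' Produces the beat-domain series that feed the baroreflex (xBRS) and joint
#' symbolic dynamics analyses. The RR interval started by beat n responds to
#' the systolic pressure of beat n-k, where k is the configured baroreflex
#' delay in beats; both series are anchored at beat onset times so that with
#' zero delay a lag-0 regression of RR on SAP recovers the configured slope
#' exactly.
#'
#' @param config a [synth_config()].
#' @return a list with elements `rr` (`beat_series`, ms), `sap`
#'   (`beat_series`, mmHg) and `truth` (ground-truth list: `beat_times`,
#'   `rr_ms`, `sap_mmHg`, `brs_slope_ms_per_mmHg`, `brs_delay_s`,
#'   `lag_beats`).
#' @export
generate_beat_pair <- function(config) {
  validate_synth_config(config)
  with_config_seed(config$seed, {
    b <- generate_beats(config)
    keep <- b$onset_times <= config$duration_s
    if (sum(keep) < 10L)
      .err("duration too short: fewer than 10 beats generated", "breathca_insufficient_beats")
    t <- b$onset_times[keep]; rr <- b$rr_ms[keep]; sap <- b$sap_mmHg[keep]
    list(
      rr = beat_series(t, rr, label = "rr", units = "ms"),
      sap = beat_series(t, sap, label = "sap", units = "mmHg"),
      truth = list(beat_times = t, rr_ms = rr, sap_mmHg = sap,
                   brs_slope_ms_per_mmHg = config$brs_slope_ms_per_mmHg,
                   brs_delay_s = config$brs_delay_s, lag_beats = b$lag_beats))
  })
}

# arterial pulse shape: raised-cosine systolic upstroke over a fixed 0.12 s,
# then exponential decay; tau in seconds since beat onset, rr_s beat length.
pulse_shape <- function(tau, rise_s = 0.12, decay_s = 0.30) {
  p <- numeric(length(tau))
  up <- tau < rise_s & tau >= 0
  p[up] <- 0.5 * (1 - cos(pi * tau[up] / rise_s))
  dn <- tau >= rise_s
  p[dn] <- exp(-(tau[dn] - rise_s) / decay_s)
  p
}

#' Apply a linear frequency-domain transfer function to a uniform signal
#'
#' Multiplies the signal spectrum by `gain(f) * exp(i * phase(f))`, where a
#' positive phase means the *output leads the input* at that frequency. Used
#' by the generator to derive cerebral blood velocity from arterial pressure,
#' and usable on its own to synthesize systems with a known frequency
#' response.
#'
#' @param x a `uniform_signal`.
#' @param gain function of frequency (Hz) returning the amplitude ratio;
#'   must be finite on `[0, fs/2]`.
#' @param phase_deg function of frequency (Hz) returning the output lead in
#'   degrees.
#' @return a `uniform_signal` of the same length and sampling frequency.
#' @examples
#' x <- uniform_signal(sin(2 * pi * 0.1 * seq(0, 100, by = 0.25)), fs = 4)
#' y <- apply_transfer(x, gain = function(f) rep(1, length(f)),
#'                     phase_deg = function(f) rep(36, length(f)))
#' @export
apply_transfer <- function(x, gain, phase_deg) {
  stopifnot(inherits(x, "uniform_signal"), is.function(gain), is.function(phase_deg))
  n <- length(x$values)
  f <- seq(0, floor(n / 2)) * x$fs / n
  g <- gain(f)
  ph <- phase_deg(f) * pi / 180
  if (any(!is.finite(g)) || any(!is.finite(ph)))
    .err("gain/phase not finite over [0, fs/2]", "breathca_config_error")
  H <- rep(0+0i, n)
  # positive-frequency half (including DC); output lead = multiply by e^{+i phi}
  half <- g * exp(1i * ph)
  half[1] <- g[1]                       # DC must stay real
  if (n %% 2 == 0) half[length(half)] <- g[length(g)] * cos(ph[length(ph)])
  H[seq_along(half)] <- half
  if (n > 2) {
    idx <- seq(2, ceiling(n / 2))
    H[n + 2 - idx] <- Conj(H[idx])
  }
  y <- Re(stats::fft(stats::fft(x$values) * H, inverse = TRUE)) / n
  uniform_signal(y, x$fs, t0 = x$t0, label = x$label, units = x$units)
}

# breath-synchronous capnogram: expiratory rise to a plateau whose maximum is
# the end-tidal value, inspiration back to a small baseline.
capnogram <- function(t, resp_bpm, et_level, baseline = 2) {
  period <- 60 / resp_bpm
  phase <- (t %% period) / period
  v <- numeric(length(t))
  rise <- phase < 0.15
  v[rise] <- baseline + (et_level - baseline) * 0.5 * (1 - cos(pi * phase[rise] / 0.15))
  plat <- phase >= 0.15 & phase < 0.70
  v[plat] <- et_level
  fall <- phase >= 0.70 & phase < 0.85
  v[fall] <- baseline + (et_level - baseline) *
    0.5 * (1 + cos(pi * (phase[fall] - 0.70) / 0.15))
  v[phase >= 0.85] <- baseline
  v
}

#' Generate a full synthetic multichannel recording with ground truth
#'
#' Builds the beat-domain series first (see [generate_beat_pair()]), then
#' renders five synchronized channels on one uniform grid:
#'
#' * `abp`: diastolic baseline plus slow Mayer/respiratory modulation plus a
#'   raised-cosine/exponential pulse per beat whose maximum equals the
#'   beat's systolic pressure,
#' * `cbv`: the mean-removed ABP passed through the configured transfer
#'   function ([apply_transfer()]), offset to the configured mean velocity,
#' * `ecg`: narrow Gaussian R waves at beat onsets (plus a small T wave),
#' * `etco2`: breath-synchronous plateau capnogram with end-tidal level
#'   `etco2_base - etco2_slope * (resp_bpm - etco2_ref_bpm)`,
#' * `resp`: sinusoidal respiration trace at the configured rate.
#'
#' @param config a [synth_config()].
#' @return a list with elements `recording` (a [recording()]) and `truth`.
#'   The ground truth records systolic peak times (`beat_times`, beat onset +
#'   0.12 s so that their differences equal the RR intervals), R wave times
#'   (`r_times` = beat onsets), per-beat `rr_ms` and `sap_mmHg`, the imposed
#'   baroreflex slope and delay, the transfer function sampled at probe
#'   frequencies, and the expected end-tidal CO2 level.
#' @export
generate_recording <- function(config) {
  validate_synth_config(config)
  if (config$duration_s < 2 * 60 / config$hr_bpm)
    .err("duration too short for at least two beats", "breathca_insufficient_beats")
  with_config_seed(config$seed, {
    fs <- config$fs
    nsamp <- floor(config$duration_s * fs)
    t <- (seq_len(nsamp) - 1) / fs
    b <- generate_beats(config)
    onset <- b$onset_times
    # slow additive modulation shared by the whole pressure wave
    fr <- config$resp_bpm / 60
    slow <- config$mayer_amp_mmHg * sin(2 * pi * 0.1 * t) +
      config$resp_abp_amp_mmHg * sin(2 * pi * fr * t)
    beat_idx <- findInterval(t, onset)
    beat_idx[beat_idx < 1L] <- 1L
    tau <- t - onset[beat_idx]
    slow_at_onset <- config$mayer_amp_mmHg * sin(2 * pi * 0.1 * onset[beat_idx]) +
      config$resp_abp_amp_mmHg * sin(2 * pi * fr * onset[beat_idx])
    pulse_amp <- b$sap_mmHg[beat_idx] - config$dbp_base_mmHg - slow_at_onset
    abp_clean <- config$dbp_base_mmHg + slow +
      pulse_amp * pulse_shape(tau)
    # cerebral velocity: mean-removed pressure through the transfer function
    cbv_drive <- apply_transfer(
      uniform_signal(abp_clean - mean(abp_clean), fs, label = "abp", units = "mmHg"),
      config$ca_gain, config$ca_phase_deg)
    cbv_clean <- config$cbv_base_cm_s + cbv_drive$values
    # ECG: R wave at beat onset, small T wave at onset + 0.3 s
    ecg_clean <- numeric(nsamp)
    sigma_r <- 0.012
    for (bi in seq_along(onset)) {
      lo <- max(1L, floor((onset[bi] - 0.08) * fs) + 1L)
      hi <- min(nsamp, ceiling((onset[bi] + 0.45) * fs) + 1L)
      if (lo > nsamp) break
      tt <- t[lo:hi]
      ecg_clean[lo:hi] <- ecg_clean[lo:hi] +
        1.0 * exp(-((tt - onset[bi])^2) / (2 * sigma_r^2)) +
        0.15 * exp(-((tt - onset[bi] - 0.30)^2) / (2 * 0.06^2))
    }
    et_level <- config$etco2_base_mmHg -
      config$etco2_slope_mmHg_per_bpm * (config$resp_bpm - config$etco2_ref_bpm)
    etco2_clean <- capnogram(t, config$resp_bpm, et_level)
    resp_trace <- sin(2 * pi * fr * t)
    ns <- config$noise_sd
    channels <- list(
      abp = uniform_signal(abp_clean + rnorm(nsamp, 0, ns[["abp"]]), fs,
                           label = "abp", units = "mmHg"),
      cbv = uniform_signal(cbv_clean + rnorm(nsamp, 0, ns[["cbv"]]), fs,
                           label = "cbv", units = "cm/s"),
      ecg = uniform_signal(ecg_clean + rnorm(nsamp, 0, ns[["ecg"]]), fs,
                           label = "ecg", units = "mV"),
      etco2 = uniform_signal(etco2_clean + rnorm(nsamp, 0, ns[["etco2"]]), fs,
                             label = "etco2", units = "mmHg"),
      resp = uniform_signal(resp_trace, fs, label = "resp", units = "a.u."))
    keep <- onset + 0.12 <= config$duration_s
    probe_f <- c(0.02, 0.05, 0.07, 0.10, 0.17, 0.25)
    truth <- list(
      beat_times = onset[keep] + 0.12,
      r_times = onset[keep],
      rr_ms = b$rr_ms[keep],
      sap_mmHg = b$sap_mmHg[keep],
      ca_probe_freqs_hz = probe_f,
      ca_gain = config$ca_gain(probe_f),
      ca_phase_deg = config$ca_phase_deg(probe_f),
      brs_slope_ms_per_mmHg = config$brs_slope_ms_per_mmHg,
      brs_delay_s = config$brs_delay_s,
      etco2_epoch_mean_mmHg = et_level)
    list(recording = recording(channels, fs), truth = truth)
  })
}
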