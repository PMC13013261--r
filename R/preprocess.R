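#' Repair spike artifacts by derivative thresholding
#'
#' Computes the first difference of the signal and flags samples where the
#' absolute difference exceeds twice its standard deviation, estimated in a
#' sliding window (default 10 s). Flagged samples are replaced by linear
#' interpolation between the nearest clean neighbours. A constant signal
#' (zero-variance derivative) is returned unchanged.
#'
#' Intended for isolated measurement spikes. Note that on a raw pulsatile
#' pressure waveform the physiological systolic upstroke itself can exceed
#' the threshold; for pulsatile channels apply the same rule to beat-to-beat
#' series instead (see [repair_beat_values()]), which is what [run_epoch()]
#' does.
#'
#' @param x a `uniform_signal`.
#' @param window_s evaluation window for the local standard deviation of the
#'   derivative, seconds.
#' @return a list with `signal` (repaired `uniform_signal`) and
#'   `artifact_count` (number of replaced samples).
#' @export
remove_artifacts <- function(x, window_s = 10) {
  stopifnot(inherits(x, "uniform_signal"))
  v <- x$values
  d <- diff(v)
  if (length(d) == 0L || stats::sd(d) == 0)
    return(list(signal = x, artifact_count = 0L))
  w <- max(3L, round(window_s * x$fs))
  sd_loc <- rolling_sd(d, w)
  bad_d <- abs(d) > 2 * sd_loc & sd_loc > 0
  if (!any(bad_d)) return(list(signal = x, artifact_count = 0L))
  # both endpoints of a flagged difference are suspect
  bad <- unique(sort(c(which(bad_d), which(bad_d) + 1L)))
  good <- setdiff(seq_along(v), bad)
  if (length(good) < 2L) return(list(signal = x, artifact_count = 0L))
  v[bad] <- stats::approx(good, v[good], xout = bad, rule = 2)$y
  list(signal = uniform_signal(v, x$fs, t0 = x$t0, label = x$label, units = x$units),
       artifact_count = length(bad))
}

# centered rolling standard deviation via cumulative sums
rolling_sd <- function(d, w) {
  n <- length(d)
  if (n <= w) return(rep(stats::sd(d), n))
  half <- floor(w / 2)
  cs <- c(0, cumsum(d))
  cs2 <- c(0, cumsum(d^2))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  cnt <- hi - lo + 1
  m <- (cs[hi + 1] - cs[lo]) / cnt
  v <- (cs2[hi + 1] - cs2[lo]) / cnt - m^2
  sqrt(pmax(v * cnt / pmax(cnt - 1, 1), 0))
}

#' Apply the spike-repair rule to a beat-to-beat series
#'
#' Same derivative-thresholding rule as [remove_artifacts()], operating on the
#' beat-domain values of a `beat_series` (where spikes correspond to
#' mis-detected or ectopic beats).
#'
#' @param x a `beat_series`.
#' @return a list with `series` (repaired `beat_series`) and
#'   `artifact_count`.
#' @export
repair_beat_values <- function(x) {
  stopifnot(inherits(x, "beat_series"))
  v <- x$values
  d <- diff(v)
  if (length(d) < 2L || stats::sd(d) == 0)
    return(list(series = x, artifact_count = 0L))
  bad_d <- abs(d) > 2 * stats::sd(d)
  if (!any(bad_d)) return(list(series = x, artifact_count = 0L))
  bad <- unique(sort(c(which(bad_d), which(bad_d) + 1L)))
  good <- setdiff(seq_along(v), bad)
  if (length(good) < 2L) return(list(series = x, artifact_count = 0L))
  v[bad] <- stats::approx(x$times[good], v[good], xout = x$times[bad], rule = 2)$y
  list(series = beat_series(x$times, v, label = x$label, units = x$units),
       artifact_count = length(bad))
}

# generic peak picker: local maxima above a rolling threshold, with a
# refractory period resolved greedily from the highest candidate down.
pick_peaks <- function(v, fs, refractory_s = 0.25, thr = NULL) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!is.null(thr)) cand <- cand[v[cand] >= thr[cand]]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(v[cand], decreasing = TRUE)]
  min_gap <- refractory_s * fs
  keep <- logical(n)
  for (i in ord) {
    lo <- max(1L, ceiling(i - min_gap)); hi <- min(n, floor(i + min_gap))
    if (!any(keep[lo:hi])) keep[i] <- TRUE
  }
  which(keep)
}

# rolling window statistic threshold: local mean + c * local sd
rolling_threshold <- function(v, fs, window_s = 10, c_sd = 0.5) {
  w <- max(3L, round(window_s * fs))
  m <- rolling_mean(v, w)
  s <- rolling_sd(v, w)
  m + c_sd * s
}

rolling_mean <- function(v, w) {
  n <- length(v)
  half <- floor(w / 2)
  cs <- c(0, cumsum(v))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect systolic peaks in an arterial pressure waveform
#'
#' Systolic peaks are local maxima of the pressure wave exceeding an adaptive
#' threshold (10 s rolling mean + 0.5 SD), with one peak per cardiac cycle
#' enforced by a 0.25 s refractory period (headroom above the 140 beats/min
#' heart-rate ceiling). The systolic value is the waveform maximum of the
#' cycle.
#'
#' @param abp a cleaned `uniform_signal` (mmHg).
#' @param refractory_s minimum distance between accepted peaks, seconds.
#' @return a `beat_series` of systolic arterial pressure (times = peak times,
#'   values = mmHg).
#' @export
detect_systolic_peaks <- function(abp, refractory_s = 0.25) {
  stopifnot(inherits(abp, "uniform_signal"))
  v <- abp$values
  thr <- rolling_threshold(v, abp$fs, c_sd = 1)
  idx <- pick_peaks(v, abp$fs, refractory_s, thr)
  if (length(idx) < 2L)
    .err("no systolic peaks found", "breathca_no_beats")
  # second pass: widen the refractory period to a fraction of the median
  # cycle so secondary maxima on the diastolic decay are rejected
  if (length(idx) >= 4L) {
    med_cycle <- stats::median(diff(idx)) / abp$fs
    refr2 <- max(refractory_s, 0.6 * med_cycle)
    idx <- pick_peaks(v, abp$fs, refr2, thr)
  }
  t <- signal_times(abp)[idx]
  beat_series(t, v[idx], label = "sap", units = "mmHg")
}

#' Pulse intervals from detected beats
#'
#' Successive differences of beat times in ms, anchored at the later beat.
#'
#' @param beats a `beat_series` of beat events (e.g. systolic peaks or R
#'   waves).
#' @return a `beat_series` of intervals in ms.
#' @export
pulse_intervals <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$times) < 2L)
    .err("need at least two beats to form intervals", "breathca_no_beats")
  beat_series(beats$times[-1], diff(beats$times) * 1000, label = "rr", units = "ms")
}

#' Detect R peaks in an ECG and derive RR intervals
#'
#' The ECG is band-passed at 8--20 Hz with a second-order Butterworth filter
#' applied forward and backward (zero phase, so R-peak latency is unbiased;
#' the effective order doubles). R candidates are local maxima of the
#' filtered signal above an adaptive threshold, with a 0.25 s refractory
#' period. RR values are successive R--R differences in ms anchored at the
#' later R time.
#'
#' @param ecg a cleaned `uniform_signal` (mV).
#' @param refractory_s refractory period, seconds.
#' @return a `beat_series` of RR intervals (ms), with the detected R times
#'   available as attribute `"r_times"`.
#' @export
detect_r_peaks <- function(ecg, refractory_s = 0.25) {
  stopifnot(inherits(ecg, "uniform_signal"))
  v <- ecg$values
  if (stats::sd(v) == 0)
    .err("flat ECG trace: no R peaks", "breathca_no_beats")
  bf <- signal::butter(2, c(8, 20) / (ecg$fs / 2), type = "pass")
  vf <- signal::filtfilt(bf, v)
  thr <- rolling_threshold(vf, ecg$fs, window_s = 5, c_sd = 2)
  idx <- pick_peaks(vf, ecg$fs, refractory_s, thr)
  if (length(idx) < 2L)
    .err("no R peaks found", "breathca_no_beats")
  t <- signal_times(ecg)[idx]
  rr <- pulse_intervals(beat_series(t, v[idx], label = "r", units = "mV"))
  attr(rr, "r_times") <- t
  rr
}

#' Beat-average a waveform and resample it on a uniform grid
#'
#' The waveform is averaged over half-open inter-beat intervals
#' `[beat_i, beat_{i+1})`, each mean anchored at the interval start; the
#' resulting irregular series is cubic-spline interpolated onto a uniform
#' grid (default 4 Hz) spanning the beat-anchored range. This is the
#' standard reduction of pulsatile pressure/velocity waveforms to the
#' beat-to-beat scale used by transfer function analysis.
#'
#' @param x a `uniform_signal`.
#' @param beats a `beat_series` of beat anchors within the span of `x`.
#' @param target_fs output sampling frequency, Hz (default 4).
#' @return a `uniform_signal` at `target_fs`.
#' @export
beat_average_resample <- function(x, beats, target_fs = 4) {
  stopifnot(inherits(x, "uniform_signal"), inherits(beats, "beat_series"))
  bt <- beats$times
  if (length(bt) < 4L)
    .err("fewer than 4 beats: cannot beat-average", "breathca_insufficient_beats")
  t <- signal_times(x)
  idx <- findInterval(t, bt)
  inb <- idx >= 1L & idx < length(bt)
  means <- tapply(x$values[inb], idx[inb], mean)
  anchor <- bt[as.integer(names(means))]
  grid <- seq(anchor[1], anchor[length(anchor)], by = 1 / target_fs)
  out <- stats::spline(anchor, as.numeric(means), xout = grid, method = "fmm")$y
  uniform_signal(out, target_fs, t0 = grid[1], label = x$label, units = x$units)
}

#' Heart rate from the first spectral harmonic of the pressure wave
#'
#' Returns 60 times the frequency of the amplitude-spectrum maximum within
#' 0.67--2.33 Hz (40--140 beats/min). If the maximum falls on a band edge the
#' result carries attribute `"band_edge" = TRUE`.
#'
#' @param abp a `uniform_signal` of at least 60 s.
#' @return heart rate in beats/min (numeric, with attribute `band_edge`).
#' @export
estimate_hr_fft <- function(abp) {
  stopifnot(inherits(abp, "uniform_signal"))
  n <- length(abp$values)
  if (n / abp$fs < 60)
    .err("need at least 60 s of signal for spectral heart rate", "breathca_insufficient_data")
  v <- abp$values - mean(abp$values)
  nfft <- 2^ceiling(log2(n))
  amp <- Mod(stats::fft(c(v, numeric(nfft - n))))[seq_len(nfft / 2 + 1)]
  f <- (seq_len(nfft / 2 + 1) - 1) * abp$fs / nfft
  band <- which(f >= 40 / 60 & f <= 140 / 60)
  if (!length(band)) .err("frequency axis does not cover the cardiac band",
                          "breathca_insufficient_data")
  k <- band[which.max(amp[band])]
  hr <- 60 * f[k]
  structure(hr, band_edge = (k == band[1] || k == band[length(band)]))
}

# breath onsets as hysteretic midrange up-crossings of the (lightly
# smoothed) capnogram: the trace must fall below mid - h before the next
# crossing of mid + h counts, which debounces measurement noise
breath_onsets <- function(etco2) {
  v <- etco2$values
  w <- max(1L, round(0.25 * etco2$fs))
  if (w > 1L) v <- rolling_mean(v, w)
  lo <- min(v); hi <- max(v)
  mid <- (lo + hi) / 2
  h <- 0.05 * (hi - lo)
  armed <- v < mid - h
  trig <- v > mid + h
  up <- integer(0)
  state <- FALSE  # TRUE once the signal has dropped below the lower band
  for (i in seq_along(v)) {
    if (armed[i]) state <- TRUE
    else if (state && trig[i]) { up <- c(up, i); state <- FALSE }
  }
  up
}

#' Respiratory rate and protocol compliance from a capnogram
#'
#' Breaths are detected as upward crossings of the capnogram midrange; the
#' rate is `60 * (n_breaths - 1) / span` between the first and last crossing.
#' With a target rate given, compliance follows the paced-breathing tolerance
#' of +/- 1 breath/min.
#'
#' @param etco2 a `uniform_signal` capnogram of at least 60 s.
#' @param target_bpm optional paced target rate, breaths/min.
#' @return a list with `rate_bpm`, `sd_bpm` (SD of instantaneous
#'   breath-to-breath rates), `n_breaths`, and `compliant` (logical, `NA`
#'   without a target).
#' @export
estimate_resp_rate <- function(etco2, target_bpm = NULL) {
  stopifnot(inherits(etco2, "uniform_signal"))
  if (length(etco2$values) / etco2$fs < 60)
    .err("need at least 60 s of capnogram", "breathca_insufficient_data")
  up <- breath_onsets(etco2)
  if (length(up) < 2L)
    .err("no breaths detected in capnogram", "breathca_no_breaths")
  t <- signal_times(etco2)[up]
  rate <- 60 * (length(up) - 1) / (t[length(t)] - t[1])
  inst <- 60 / diff(t)
  list(rate_bpm = rate,
       sd_bpm = if (length(inst) > 1) stats::sd(inst) else 0,
       n_breaths = length(up),
       compliant = if (is.null(target_bpm)) NA else abs(rate - target_bpm) <= 1)
}
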