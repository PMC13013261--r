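#' Frequency band definition
#'
#' @param f_lo,f_hi band limits in Hz, `0 < f_lo < f_hi <= 2` (the Nyquist of
#'   the 4 Hz beat-averaged series).
#' @param label band label, conventionally `"VLF"` or `"BF"`.
#' @return an object of class `frequency_band`.
#' @export
frequency_band <- function(f_lo, f_hi, label = "") {
  if (!(f_lo > 0 && f_lo < f_hi && f_hi <= 2))
    stop("band limits must satisfy 0 < f_lo < f_hi <= 2 Hz", call. = FALSE)
  structure(list(f_lo = f_lo, f_hi = f_hi, label = label),
            class = "frequency_band")
}

#' Very-low-frequency band (0.02--0.07 Hz)
#'
#' The band where cerebral autoregulation is most active.
#' @return a `frequency_band`.
#' @export
vlf_band <- function() frequency_band(0.02, 0.07, "VLF")

#' Breathing-frequency band for paced or spontaneous breathing
#'
#' For the paced protocol rates the band is centred at 0.10, 0.17 or 0.25 Hz
#' (+/- 0.02 Hz) for 6, 10 and 15 breaths/min respectively. For spontaneous
#' breathing the band is individually `(mean - sd, mean + sd) / 60`, widened
#' symmetrically to a minimum width of 0.04 Hz (matching the paced +/- 0.02
#' Hz) when the respiratory-rate SD is small.
#'
#' @param resp_bpm paced rate; must be 6, 10 or 15 for `mode = "controlled"`.
#' @param sd_bpm respiratory-rate standard deviation (spontaneous mode).
#' @param mode `"controlled"` or `"spontaneous"`.
#' @return a `frequency_band` labelled `"BF"`.
#' @export
bf_band <- function(resp_bpm, sd_bpm = NULL, mode = c("controlled", "spontaneous")) {
  mode <- match.arg(mode)
  if (mode == "controlled") {
    centers <- c(`6` = 0.10, `10` = 0.17, `15` = 0.25)
    key <- as.character(resp_bpm)
    if (!key %in% names(centers))
      stop("controlled breathing rate must be 6, 10 or 15 breaths/min", call. = FALSE)
    ctr <- centers[[key]]
    frequency_band(ctr - 0.02, ctr + 0.02, "BF")
  } else {
    if (is.null(sd_bpm) || sd_bpm < 0)
      stop("spontaneous mode needs a nonnegative sd_bpm", call. = FALSE)
    lo <- (resp_bpm - sd_bpm) / 60
    hi <- (resp_bpm + sd_bpm) / 60
    if (hi - lo < 0.04) {            # degenerate-sd floor
      ctr <- resp_bpm / 60
      lo <- ctr - 0.02; hi <- ctr + 0.02
    }
    frequency_band(max(lo, 1e-6), min(hi, 2), "BF")
  }
}

#' Welch cross-spectral estimate between two 4 Hz beat-averaged signals
#'
#' Implements the transfer-function analysis front end: the global mean is
#' subtracted from each signal (no detrending), the signals are segmented
#' into 102.4 s Hanning-windowed segments with 50% overlap (410 samples at 4
#' Hz; 102.4 s is not an integer sample count, so the segment is rounded to
#' 410 samples = 102.5 s), and auto- and cross-spectra are averaged across
#' segments. The estimate reports magnitude-squared coherence
#' `|Sxy|^2 / (Sxx Syy)`, phase in degrees with the convention *positive =
#' output (CBv) leads input (ABP)*, and gain `|Sxy| / Sxx`.
#'
#' @param abp4 input `uniform_signal` at 4 Hz (arterial pressure).
#' @param cbv4 output `uniform_signal` at 4 Hz (cerebral velocity), equal
#'   length.
#' @param segment_samples Welch segment length in samples (default 410).
#' @param overlap fractional segment overlap (default 0.5).
#' @return an object of class `spectral_estimate` with fields `freqs`, `msc`,
#'   `phase_deg`, `gain`, `n_windows`.
#' @export
cross_spectra <- function(abp4, cbv4, segment_samples = 410L, overlap = 0.5) {
  stopifnot(inherits(abp4, "uniform_signal"), inherits(cbv4, "uniform_signal"))
  if (abs(abp4$fs - 4) > 1e-9 || abs(cbv4$fs - 4) > 1e-9)
    .err("cross_spectra expects 4 Hz beat-averaged inputs", "breathca_bad_fs")
  x <- abp4$values; y <- cbv4$values
  if (length(x) != length(y))
    .err("input signals must have equal length", "breathca_insufficient_data")
  nseg <- as.integer(segment_samples)
  if (length(x) < nseg)
    .err("signal shorter than one Welch segment", "breathca_insufficient_data")
  x <- x - mean(x)
  y <- y - mean(y)
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))   # Hanning
  nf <- floor(nseg / 2) + 1L
  sxx <- syy <- numeric(nf)
  sxy <- rep(0+0i, nf)
  for (s in starts) {
    xs <- x[s:(s + nseg - 1L)] * w
    ys <- y[s:(s + nseg - 1L)] * w
    X <- stats::fft(xs)[seq_len(nf)]
    Y <- stats::fft(ys)[seq_len(nf)]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + Conj(X) * Y
  }
  L <- length(starts)
  sxx <- sxx / L; syy <- syy / L; sxy <- sxy / L
  denom <- sxx * syy
  msc <- ifelse(denom > 0, Mod(sxy)^2 / denom, NA_real_)
  msc <- pmin(pmax(msc, 0), 1)
  phase <- Arg(sxy) * 180 / pi           # + means y leads x
  gain <- ifelse(sxx > 0, Mod(sxy) / sxx, NA_real_)
  structure(list(freqs = (seq_len(nf) - 1) * 4 / nseg,
                 msc = msc, phase_deg = phase, gain = gain,
                 n_windows = L),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d bins, df = %.4f Hz, %d Welch windows\n",
              length(x$freqs), x$freqs[2] - x$freqs[1], x$n_windows))
  invisible(x)
}

#' Coherence threshold from 95% confidence limits on window count
#'
#' For `L` averaged (nominally independent) Welch windows, the
#' `(1 - alpha)` critical value of magnitude-squared coherence between
#' independent signals is `1 - alpha^(1 / (L - 1))`. Bins below this value
#' carry no reliable phase/gain information and are excluded from band
#' averages. Overlap-induced dependence between windows is ignored (nominal
#' segment count).
#'
#' @param n_windows number of Welch windows (>= 2).
#' @param alpha significance level (default 0.05).
#' @return the coherence threshold in `[0, 1]`.
#' @export
coherence_critical <- function(n_windows, alpha = 0.05) {
  if (n_windows < 2) stop("need at least 2 Welch windows", call. = FALSE)
  1 - alpha^(1 / (n_windows - 1))
}

#' Band-averaged coherence, phase shift and gain with coherence gating
#'
#' Keeps the spectral bins whose centres lie inside the closed band, excludes
#' bins with coherence below [coherence_critical()] for the estimate's window
#' count, and excludes bins with negative phase below 0.1 Hz (anti-wrap rule:
#' such bins are removed, not rectified). The remaining bins are averaged
#' arithmetically without weighting. If every bin is excluded the metrics
#' are flagged undefined rather than reported as numbers.
#'
#' @param spec a `spectral_estimate` from [cross_spectra()].
#' @param band a `frequency_band`.
#' @param alpha significance level for the coherence gate.
#' @return an object of class `band_metrics`: `coherence`, `ps_deg`, `gain`,
#'   `n_bins_used`, `defined`, `band`.
#' @export
band_metrics <- function(spec, band, alpha = 0.05) {
  stopifnot(inherits(spec, "spectral_estimate"), inherits(band, "frequency_band"))
  inband <- which(spec$freqs >= band$f_lo - 1e-12 & spec$freqs <= band$f_hi + 1e-12)
  if (!length(inband))
    .err("no spectral bins inside the requested band", "breathca_empty_band")
  thr <- coherence_critical(spec$n_windows, alpha)
  keep <- inband[!is.na(spec$msc[inband]) & spec$msc[inband] >= thr]
  # anti-wrap: drop negative-phase bins below 0.1 Hz
  keep <- keep[!(spec$freqs[keep] < 0.1 & spec$phase_deg[keep] < 0)]
  if (!length(keep)) {
    out <- list(coherence = NA_real_, ps_deg = NA_real_, gain = NA_real_,
                n_bins_used = 0L, defined = FALSE, band = band)
  } else {
    out <- list(coherence = mean(spec$msc[keep]),
                ps_deg = mean(spec$phase_deg[keep]),
                gain = mean(spec$gain[keep]),
                n_bins_used = length(keep), defined = TRUE, band = band)
  }
  structure(out, class = "band_metrics")
}

#' @export
print.band_metrics <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<band_metrics> %s [%.3f, %.3f] Hz: coherence %.3f, PS %.1f deg, gain %.3f (%d bins)\n",
                x$band$label, x$band$f_lo, x$band$f_hi,
                x$coherence, x$ps_deg, x$gain, x$n_bins_used))
  else
    cat(sprintf("<band_metrics> %s [%.3f, %.3f] Hz: undefined (all bins gated out)\n",
                x$band$label, x$band$f_lo, x$band$f_hi))
  invisible(x)
}
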