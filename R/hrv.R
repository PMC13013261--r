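#' Time-domain heart rate variability metrics
#'
#' Computes SDNN (sample SD of RR intervals), RMSSD (root mean square of
#' successive differences), meanNN, and pNN20/pNN50 (percentage of adjacent
#' intervals differing by more than 20/50 ms).
#'
#' @param rr a `beat_series` of RR intervals in ms with at least 10
#'   intervals.
#' @return a list: `sdnn_ms`, `rmssd_ms`, `meannn_ms`, `pnn20_pct`,
#'   `pnn50_pct`.
#' @export
hrv_time <- function(rr) {
  v <- rr_values(rr)
  if (length(v) < 10L)
    .err("need at least 10 RR intervals", "breathca_insufficient_beats")
  d <- diff(v)
  list(sdnn_ms = stats::sd(v),
       rmssd_ms = sqrt(mean(d^2)),
       meannn_ms = mean(v),
       pnn20_pct = 100 * mean(abs(d) > 20),
       pnn50_pct = 100 * mean(abs(d) > 50))
}

rr_values <- function(rr) {
  if (inherits(rr, "beat_series")) rr$values
  else if (is.numeric(rr)) as.numeric(rr)
  else stop("`rr` must be a beat_series or numeric vector", call. = FALSE)
}

# Welch PSD of a demeaned uniform series; one-sided, units^2 per Hz
welch_psd <- function(v, fs, segment_samples, overlap = 0.5) {
  nseg <- min(as.integer(segment_samples), length(v))
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, length(v) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))
  U <- sum(w^2)
  nf <- floor(nseg / 2) + 1L
  p <- numeric(nf)
  for (s in starts) {
    seg <- v[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- p + Mod(stats::fft(seg)[seq_len(nf)])^2
  }
  p <- p / (length(starts) * fs * U)
  p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]     # one-sided
  list(freqs = (seq_len(nf) - 1) * fs / nseg, psd = p)
}

#' Frequency-domain heart rate variability metrics
#'
#' The RR series is cubic-spline resampled to a uniform 4 Hz grid, and a
#' Welch periodogram (Hanning, 120 s segments, 50% overlap) integrated over
#' the low-frequency (0.04--0.15 Hz) and high-frequency (0.15--0.40 Hz)
#' bands. Normalized powers divide by the total power over 0.04--0.40 Hz, so
#' `lfn + hfn = 1`.
#'
#' @param rr a `beat_series` of RR intervals (ms) spanning at least 120 s.
#' @param resample_fs resampling frequency, Hz.
#' @param segment_s Welch segment length, seconds.
#' @return a list: `lf_ms2`, `hf_ms2`, `lfn`, `hfn`, `lf_hf` (`NA` with
#'   attribute when HF power is zero).
#' @export
hrv_freq <- function(rr, resample_fs = 4, segment_s = 120) {
  stopifnot(inherits(rr, "beat_series"))
  span <- diff(range(rr$times))
  if (span < 120)
    .err("need at least 120 s of RR data for spectral metrics", "breathca_insufficient_data")
  grid <- seq(rr$times[1], rr$times[length(rr$times)], by = 1 / resample_fs)
  v <- stats::spline(rr$times, rr$values, xout = grid, method = "fmm")$y
  v <- v - mean(v)
  ps <- welch_psd(v, resample_fs, segment_samples = round(segment_s * resample_fs))
  df <- ps$freqs[2] - ps$freqs[1]
  lf <- sum(ps$psd[ps$freqs >= 0.04 & ps$freqs < 0.15]) * df
  hf <- sum(ps$psd[ps$freqs >= 0.15 & ps$freqs <= 0.40]) * df
  tp <- lf + hf
  list(lf_ms2 = lf, hf_ms2 = hf,
       lfn = if (tp > 0) lf / tp else NA_real_,
       hfn = if (tp > 0) hf / tp else NA_real_,
       lf_hf = if (hf > 0) lf / hf else NA_real_)
}

# Chebyshev-distance template matching machinery -------------------------

# counts of template pairs (i < j) within tolerance r for embedding m,
# comparing only the first n - m templates so that every counted m-template
# has an (m+1)-extension (Richman & Moorman convention)
.template_match_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m                      # templates with an extension
  if (nt < 2) return(c(B = 0, A = 0))
  B <- 0; A <- 0
  for (i in seq_len(nt - 1L)) {
    js <- (i + 1L):nt
    dmax <- abs(x[i] - x[js])
    for (k in seq_len(m - 1L))
      dmax <- pmax(dmax, abs(x[i + k] - x[js + k]))
    hitB <- dmax <= r
    B <- B + sum(hitB)
    dmax1 <- pmax(dmax, abs(x[i + m] - x[js + m]))
    A <- A + sum(dmax1 <= r)
  }
  c(B = B, A = A)
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` and `A` count template pairs (self
#' matches excluded) within Chebyshev tolerance `r` at lengths `m` and
#' `m + 1`. When no length-(m+1) matches exist the result is `NA` (flagged
#' undefined) rather than a substituted infinity.
#'
#' @param x numeric series (RR intervals, ms) or `beat_series`.
#' @param m embedding dimension (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return sample entropy (nats), or `NA` if undefined.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(rr_values(x))) {
  x <- rr_values(x)
  cnt <- .template_match_counts(x, m, r)
  if (cnt[["B"]] == 0 || cnt[["A"]] == 0) return(NA_real_)
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Approximate entropy
#'
#' `ApEn(m, r) = Phi^m(r) - Phi^(m+1)(r)` with
#' `Phi^m = mean_i log(C_i^m(r))`, where `C_i^m` is the fraction of
#' templates (self match included) within Chebyshev tolerance `r` of
#' template i.
#'
#' @inheritParams sample_entropy
#' @return approximate entropy (nats).
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2 * stats::sd(rr_values(x))) {
  x <- rr_values(x)
  phi <- function(mm) {
    n <- length(x)
    nt <- n - mm + 1L
    if (nt < 1) return(NA_real_)
    cnt <- numeric(nt)
    for (i in seq_len(nt)) {
      dmax <- abs(x[i] - x[seq_len(nt)])
      for (k in seq_len(mm - 1L))
        dmax <- pmax(dmax, abs(x[i + k] - x[seq_len(nt) + k]))
      cnt[i] <- sum(dmax <= r)
    }
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1L)
}

#' Fuzzy entropy
#'
#' Templates are locally mean-removed; pair similarity uses the exponential
#' membership `exp(-(d / r)^2)` of order 2 on the Chebyshev distance `d`.
#' `FuzzyEn = ln(phi^m) - ln(phi^(m+1))` with `phi` the mean pairwise
#' membership over distinct template pairs.
#'
#' @inheritParams sample_entropy
#' @return fuzzy entropy (nats).
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2 * stats::sd(rr_values(x))) {
  x <- rr_values(x)
  phi <- function(mm) {
    n <- length(x)
    nt <- n - mm                 # align template counts across m and m+1
    if (nt < 2) return(NA_real_)
    tmpl <- matrix(NA_real_, nt, mm)
    for (k in seq_len(mm)) tmpl[, k] <- x[(seq_len(nt)) + k - 1L]
    tmpl <- tmpl - rowMeans(tmpl)
    tot <- 0
    for (i in seq_len(nt - 1L)) {
      js <- (i + 1L):nt
      d <- abs(tmpl[i, 1] - tmpl[js, 1, drop = TRUE])
      if (mm > 1) for (k in 2:mm)
        d <- pmax(d, abs(tmpl[i, k] - tmpl[js, k, drop = TRUE]))
      tot <- tot + sum(exp(-(d / r)^2))
    }
    tot / (nt * (nt - 1) / 2)
  }
  log(phi(m)) - log(phi(m + 1L))
}

#' Multiscale (sample) entropy
#'
#' Coarse-grains the series at scales 1..max(scale) (non-overlapping block
#' means) and averages the sample entropy across scales, keeping the
#' tolerance fixed at `r` computed from the original series. Short epochs
#' (about 350--500 beats for 5 minutes) only support small scales, hence the
#' default `scales = 1:3`. Requires at least `100 * max(scales)` intervals,
#' otherwise `NA` is returned (flagged).
#'
#' @inheritParams sample_entropy
#' @param scales integer vector of coarse-graining scales.
#' @return mean sample entropy over the scales, or `NA`.
#' @export
multiscale_entropy <- function(x, m = 2, r = 0.2 * stats::sd(rr_values(x)),
                               scales = 1:3) {
  x <- rr_values(x)
  if (length(x) < 100 * max(scales)) return(NA_real_)
  se <- vapply(scales, function(tau) {
    if (tau == 1L) cg <- x
    else {
      nb <- floor(length(x) / tau)
      cg <- colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
    }
    sample_entropy(cg, m = m, r = r)
  }, numeric(1))
  if (all(is.na(se))) NA_real_ else mean(se, na.rm = TRUE)
}

#' Entropy-domain heart rate variability metrics
#'
#' Convenience wrapper returning approximate, sample, fuzzy and multiscale
#' entropy with the conventional parameters m = 2, r = 0.2 SD.
#'
#' @param rr a `beat_series` of RR intervals (ms) or numeric vector with at
#'   least 100 intervals.
#' @param m embedding dimension.
#' @param r_frac tolerance as a fraction of the series SD.
#' @param scales coarse-graining scales for multiscale entropy.
#' @return a list: `apen`, `sampen`, `fuzzyen`, `msen`.
#' @export
hrv_entropy <- function(rr, m = 2, r_frac = 0.2, scales = 1:3) {
  v <- rr_values(rr)
  if (length(v) < 100L)
    .err("need at least 100 RR intervals for entropy metrics", "breathca_insufficient_beats")
  r <- r_frac * stats::sd(v)
  list(apen = approximate_entropy(v, m, r),
       sampen = sample_entropy(v, m, r),
       fuzzyen = fuzzy_entropy(v, m, r),
       msen = multiscale_entropy(v, m, r, scales))
}
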