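# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementations.

# Monte-Carlo distribution of Welch magnitude-squared coherence between
# independent Gaussian white-noise pairs with L averaged windows, evaluated
# at one interior frequency bin; batched over replicates via mvfft.
mc_coherence <- function(L, nrep, nseg = 64L, bin = 11L, chunk = 2000L) {
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))
  out <- numeric(nrep)
  done <- 0L
  while (done < nrep) {
    k <- min(chunk, nrep - done)
    X <- stats::mvfft(matrix(rnorm(nseg * L * k), nseg) * w)[bin, ]
    Y <- stats::mvfft(matrix(rnorm(nseg * L * k), nseg) * w)[bin, ]
    Xg <- matrix(X, L); Yg <- matrix(Y, L)
    out[(done + 1):(done + k)] <- Mod(colMeans(Conj(Xg) * Yg))^2 /
      (colMeans(Mod(Xg)^2) * colMeans(Mod(Yg)^2))
    done <- done + k
  }
  out
}

# Brute-force sample entropy by full distance-matrix template counting
# (O(n^2) memory/time; independent of the package's per-template loop).
sampen_oracle <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  nt <- n - m
  D <- abs(outer(x[1:nt], x[1:nt], "-"))
  for (k in seq_len(m - 1))
    D <- pmax(D, abs(outer(x[(1 + k):(nt + k)], x[(1 + k):(nt + k)], "-")))
  B <- (sum(D <= r) - nt) / 2
  D1 <- pmax(D, abs(outer(x[(1 + m):(nt + m)], x[(1 + m):(nt + m)], "-")))
  A <- (sum(D1 <= r) - nt) / 2
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Spearman rho by explicit average-rank Pearson correlation
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# a quiet generator configuration: pure baroreflex coupling, no RSA
quiet_pair_config <- function(seed, duration_s = 300, slope = 10, delay = 2,
                              hr = 60, rr_noise = 2, sap_noise = 0.5) {
  synth_config(duration_s = duration_s, hr_bpm = hr,
               brs_slope_ms_per_mmHg = slope, brs_delay_s = delay,
               rsa_amp_ms = 0,
               noise_sd = c(rr = rr_noise, sap = sap_noise), seed = seed)
}

# uncoupled null: no baroreflex, no shared respiratory drive into RR
null_pair_config <- function(seed, duration_s = 120) {
  synth_config(duration_s = duration_s, brs_slope_ms_per_mmHg = 0,
               rsa_amp_ms = 0, noise_sd = c(rr = 5, sap = 1), seed = seed)
}

# broadband 4 Hz signal for direct spectral tests
broadband_4hz <- function(n = 2048, seed = 1) {
  set.seed(seed)
  uniform_signal(rnorm(n), fs = 4, label = "abp", units = "mmHg")
}
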