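---
title: "Methods: cerebral autoregulation and autonomic coupling under controlled breathing"
author: "breathca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cerebral autoregulation and autonomic coupling under controlled breathing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathca)
```

## The physiological problem

Cerebral autoregulation buffers cerebral blood flow against fluctuations in
arterial pressure. Because cerebral arterioles respond slowly, the system
behaves like a high-pass filter: slow pressure oscillations (below roughly
0.07 Hz) are damped and phase-advanced in the cerebral blood velocity (CBv)
signal, fast oscillations pass through. Transfer function analysis (TFA) of
the arterial blood pressure (ABP) to CBv relationship quantifies this with
three metrics per frequency band: **coherence** (how reliably linear the
coupling is), **phase shift** (degrees by which CBv leads ABP; higher is
better buffering), and **gain** (cm s^-1^ mmHg^-1^ of velocity change per
pressure change; lower is better damping).

Paced breathing at 6, 10 and 15 breaths/min concentrates respiratory-driven
pressure oscillations at 0.10, 0.17 and 0.25 Hz, which raises coherence in
those bands and simultaneously modulates autonomic activity — baroreflex
sensitivity, heart rate variability (HRV), and beat-to-beat cardiovascular
coupling. This package implements the full analysis chain for such
protocols, plus a synthetic generator so that every stage can be validated
by recovering known parameters.

## The analysis chain

### Beat detection and beat-domain reduction

Systolic peaks are local maxima of the ABP wave above an adaptive threshold
(10 s rolling mean + 0.5 SD in waveform units; 1 SD for the peak gate), with
a two-pass refractory rule: an initial 0.25 s refractory period (headroom
above the 140 beats/min ceiling of the heart-rate band) is widened to 60% of
the median detected cycle, which rejects secondary maxima on the diastolic
decay. R peaks are detected on the 8–20 Hz band-passed ECG (second-order
Butterworth applied forward and backward; zero-phase, so R latency is
unbiased while the effective order doubles).

Two interval series coexist deliberately: HRV uses ECG-derived R–R
intervals; baroreflex and symbolic-coupling analyses use ABP-derived pulse
intervals, so recordings without ECG still support them. Pulse intervals are
anchored at the later beat; per-beat waveform means are computed on
half-open intervals `[beat_i, beat_{i+1})` and anchored at the interval
start. The start-anchor convention shifts a beat-averaged series by about
half a beat relative to the underlying signal; both TFA channels share the
same anchors, so the shift cancels exactly in cross-spectral phase.

### Artifact handling

The repair rule computes the first difference of a signal and replaces
samples whose absolute difference exceeds twice its standard deviation
(estimated in a 10 s sliding window) by linear interpolation between clean
neighbours. On a *pulsatile waveform* the physiological systolic upstroke
itself exceeds this threshold — twice the SD of the derivative sits below
the upstroke slope of every normal pulse — so the pipeline applies the rule
in the beat domain (to systolic values, pulse intervals and beat-averaged
series), where spikes correspond to mis-detected or ectopic beats.
`remove_artifacts()` remains available for raw channels with isolated
measurement spikes. The rule is exactly idempotent on smooth signals with
isolated spikes; on noise-dominated derivatives a repeat pass may touch a
few percent of samples (the Gaussian tail beyond 2 SD), with negligible
amplitude effect.

### Transfer function analysis

Both channels are beat-averaged, cubic-spline resampled to 4 Hz, and mean-
subtracted (no detrending). Welch cross-spectra use Hanning-windowed
segments with 50% overlap. The nominal 102.4 s segment is not an integer
sample count at 4 Hz (409.6 samples); we round to **410 samples (102.5 s)**
and document the one-sample discrepancy, giving a frequency resolution of
about 0.00976 Hz. Phase is reported in degrees on the principal value with
the convention *positive = CBv leads ABP*; gain is `|Sxy| / Sxx`.

Band averages (arithmetic, unweighted — whether to weight bins by coherence
is an open choice; we do not) are taken over bins whose centres lie inside
the closed band:

* **VLF** 0.02–0.07 Hz, where autoregulation is most active;
* **BF** centred at 0.10 / 0.17 / 0.25 Hz (± 0.02 Hz) for paced breathing,
  or individually at the mean spontaneous rate ± SD, floored at a 0.04 Hz
  width so a near-zero rate SD cannot produce an empty band.

Two exclusion rules gate the average: bins whose magnitude-squared
coherence falls below the 95% confidence limit for `L` Welch windows,
`1 - 0.05^(1/(L-1))` (the nominal segment count is used; overlap-induced
dependence is ignored, and the formula is cross-checked against Monte-Carlo
white-noise coherence in the tests), and — the anti-wrap rule — bins with
negative phase below 0.1 Hz, which are *removed*, not rectified. A band
whose bins are all excluded is flagged undefined rather than reported as a
number.

### Heart rate variability

Time domain: SDNN, RMSSD, meanNN, pNN20, pNN50. Frequency domain: the RR
series is spline-resampled to 4 Hz and a Welch periodogram (120 s segments,
50% overlap — a documented package choice) integrated over LF 0.04–0.15 Hz
and HF 0.15–0.40 Hz; normalized powers divide by total power over
0.04–0.40 Hz, so LFn + HFn = 1.

Entropies use the conventional m = 2 and r = 0.2 SD. SampEn excludes self
matches and counts only templates that have an (m+1)-extension, so strictly
periodic series give exactly zero; an undefined SampEn (no matches) is
flagged `NA`, never a substituted infinity. FuzzyEn removes the local mean
per template and uses the order-2 exponential membership `exp(-(d/r)^2)`.
Multiscale entropy averages SampEn over coarse-graining **scales 1–3 only**,
with r fixed from the original series: a 5-minute epoch holds roughly
350–500 beats, which cannot support longer scales; series shorter than
100 × max(scale) are flagged.

### Cross-correlation baroreflex sensitivity (xBRS)

Systolic pressure and pulse-interval series are placed on a common 1 Hz
grid by **nearest-beat staircase sampling**: each second carries the value
of the closest beat. Two alternatives were rejected after analysis: linear
interpolation smooths the series and inflates the significance of window
correlations under the null (accepted-window rates above the expected
level), while previous-beat sampling has up to a full beat of timing error,
which mispairs delayed beats and attenuates the recovered slope by ~10%.
Nearest-beat sampling bounds the timing error at half a beat and does
neither.

In every 10 s window (sliding by 1 s) the interval series is correlated
with pressure at delays of 0–3 s; the delay with the largest positive
correlation is selected (positive, because the baroreflex sign is fixed),
and the window is accepted if p < 0.05 and no ectopic beat is flagged
inside it. The ectopic rule — an interval deviating more than 25% from the
median of its 10 nearest neighbours — is the package's own parameterization
of a criterion whose published form names no constants. The per-epoch xBRS
is the **median** accepted slope (the aggregator is unstated in the source
method family; the median is robust to the skewed window-slope
distribution), with the modal selected delay reported alongside.

A caveat established with the generator: respiratory sinus arrhythmia is an
RR input that does not pass through pressure, so when RSA shares a
frequency with pressure oscillations, any SAP-to-RR regression absorbs it
(upward or downward bias depending on the phase relation to the baroreflex
delay). Parameter-recovery checks therefore impose pure baroreflex coupling
(RSA amplitude zero); runs with RSA active characterize the bias, they do
not define recovery.

### Joint symbolic dynamics

Each beat-to-beat change becomes a binary symbol: 1 when the series
strictly increases, 0 on a decrease *or a tie* (the strict inequality of
the symbolization rule decides ties). Overlapping 3-symbol words —
most-significant-bit earliest in time — from the RR and SAP sequences give
64 joint word types, tabulated as relative frequencies in the 8×8 matrix
`W`. `JSD_sym` is the main-diagonal sum (concordant, baroreflex-like
patterns), `JSD_diam` the antidiagonal sum (opposed patterns); the two
cell sets are disjoint. Word alignment uses lag 0 on the symbol grid: with
pulse intervals anchored at the beat that ends them, a pressure change is
paired with the interval it precedes, which realizes the convention that a
pressure change affects the *subsequent* interval. The lag is nevertheless
a parameter (`lag =`) so sensitivity to the alignment ambiguity can be
checked directly.

### Cohort statistics

The repeated-measures layer is rank-based: Friedman tests across the three
paced conditions (average-rank ties with the classical tie correction;
all-tied tables return statistic 0 and p 1 rather than 0/0; participants
missing any condition are dropped listwise, and the n actually used is
reported), Kendall's `W = chi2 / (n (k-1))` as effect size, and Wilcoxon
signed-rank post-hocs at the Bonferroni threshold `alpha / m` (0.05/3 ≈
0.0167). Zero differences are dropped; the exact distribution is used up to
25 untied non-zero pairs, the continuity-corrected normal approximation
above. Spearman matrices use pairwise-complete observations and flag
constant columns undefined.

The mixed-effects interface fits `CA metric ~ ANS metric + respiratory rate
+ EtCO2 + (1 | participant)` by REML — one autonomic metric per fit — and
reports marginal (type-III) F with Satterthwaite degrees of freedom.
Singular fits are flagged but still reported; in the zero-variance limit
the F statistics coincide with ordinary least squares, which the tests
verify.

## The synthetic generator

The generator builds the beat domain first: systolic pressure carries a
0.1 Hz Mayer wave and a breathing-frequency oscillation; the RR interval
started by beat n is
`RR0 + slope · (SAP[n-k] - SAP0) + RSA(t) + noise`, with `k` the
baroreflex delay rounded to whole beats (baroreflex and symbolic analyses
operate beat-to-beat, so the coupling is imposed where it is measured). The
waveforms are then rendered on a 200 Hz grid:

* ABP: raised-cosine systolic upstroke over a fixed 0.12 s, then
  exponential decay — simple, peak-detectable, and the fixed upstroke makes
  systolic-peak spacing equal the RR series exactly;
* CBv: the mean-removed ABP passed through a configurable linear transfer
  function (default: first-order high-pass, corner 0.07 Hz, high-frequency
  gain 1.1 cm s^-1^ mmHg^-1^ — VLF phase ≈ 46–67°, 0.1 Hz phase ≈ 35°,
  consistent with healthy-adult values);
* ECG: narrow Gaussian R waves at beat onsets plus a small T wave;
* EtCO2: a breath-synchronous plateau wave whose end-tidal (per-breath
  maximum) level is `36.5 - 0.43 · (rate - 6)` mmHg, the linear decline
  implied by paced-breathing capnography medians (36.5 mmHg at 6/min to
  32.6 mmHg at 15/min);
* a sinusoidal respiration trace.

One seeded generator serves all channels, so an identical configuration is
bit-reproducible. Tidal volume is deliberately not a parameter: the
end-tidal level is driven by rate alone, since volume is typically not
measured in these protocols.

**What the generator does not emulate:** nonlinear autoregulation dynamics,
CO2-reactivity feedback onto CBv, arrhythmia and ectopy (beyond outliers
injected explicitly in tests), pulse-wave morphology beyond a single
systolic maximum, and measurement dropouts. Passing parameter-recovery
tests therefore demonstrates correctness of the estimators under the
linear, stationary conditions they assume — not robustness to every
pathology of clinical recordings.

## Numerical choices and degenerate inputs

* Welch segment 410 samples at 4 Hz; bins on closed band edges included.
* Spline interpolation (`method = "fmm"`) for beat-to-grid resampling.
* Peak pickers break flat-top ties toward the earlier sample.
* Constant signals: artifact repair returns them unchanged; peak detection
  raises a no-beats error; spectral heart rate requires 60 s.
* `SampEn` with zero SD and r = 0 still returns 0 for constant series
  (distances tie at zero and `d <= r` counts them).
* Uncoupled-null conditions set both the baroreflex slope *and* RSA to
  zero: with RSA active, RR and SAP share the respiratory drive and are
  correlated even without baroreflex coupling.

## Problem sizes used by the test suite

The suite validates on 120–300 s synthetic recordings (one to four Welch
windows), 100-seed Monte-Carlo runs for null acceptance rates, 30 000
replicates for the coherence-threshold law, and 500–1000 replicates for
type-I calibration of the Friedman, Wilcoxon and mixed-model tests; the
cohort-level test uses six participants × three conditions at 180 s per
epoch. These sizes were chosen so each check is statistically decisive at
its stated tolerance.

## A worked recovery

```{r recovery}
cfg <- synth_config(duration_s = 300, seed = 42,
                    ca_gain = function(f) rep(0.9, length(f)),
                    ca_phase_deg = function(f) rep(36, length(f)))
gr <- generate_recording(cfg)
sap <- detect_systolic_peaks(gr$recording$channels$abp)
abp4 <- beat_average_resample(gr$recording$channels$abp, sap)
cbv4 <- beat_average_resample(gr$recording$channels$cbv, sap)
n <- min(length(abp4$values), length(cbv4$values))
abp4$values <- abp4$values[seq_len(n)]; cbv4$values <- cbv4$values[seq_len(n)]
band_metrics(cross_spectra(abp4, cbv4), bf_band(6))
```

The configured 36° lead and 0.9 gain at the breathing frequency come back
within the tolerances the test suite enforces (±5° and ±10%).

## Known limitations

* EDF input is not supported; recordings are exchanged through the CSV
  dialect (`time_s,abp_mmHg,cbv_cm_s,ecg_mV,etco2_mmHg`).
* The 4 Hz beat series limits TFA to 2 Hz; bands are validated against
  that Nyquist.
* The Friedman layer assumes one value per participant × condition;
  replicated epochs must be reduced upstream.
* MSEn over scales 1–3 is not comparable with implementations that report
  a single long scale or a different aggregation; comparisons across
  software should match parameters explicitly.
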