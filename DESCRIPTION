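Package: breathca
Title: Cerebral Autoregulation and Autonomic Coupling Analysis During Controlled Breathing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the interaction between cerebral autoregulation
    and autonomic nervous system activity under paced-breathing protocols.
    Implements transfer function analysis of the arterial pressure to cerebral
    blood velocity relationship (Welch cross-spectra, coherence gating with
    window-count confidence limits, anti-wrap phase handling, band-averaged
    phase shift and gain in very-low-frequency and breathing-frequency bands),
    heart rate variability metrics in the time, frequency and entropy domains
    (SDNN, RMSSD, pNNx, normalized LF/HF, approximate, sample, fuzzy and
    multiscale entropy), cross-correlation baroreflex sensitivity (xBRS) with
    delay search, joint symbolic dynamics of pulse interval and systolic
    pressure (8x8 word matrix, diagonal and antidiagonal indices), and a
    repeated-measures statistical layer (Friedman ANOVA with Kendall's W,
    Bonferroni-corrected Wilcoxon post-hocs, Spearman matrices, linear
    mixed-effects models). A synthetic cardio-cerebral signal generator with
    known ground truth (baroreflex slope and delay, pressure-to-velocity
    transfer function, respiratory and Mayer-wave modulation, capnogram
    response to breathing rate) makes every analysis stage testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
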