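#' Write a recording to the interchange CSV dialect
#'
#' Columns `time_s,abp_mmHg,cbv_cm_s,ecg_mV,etco2_mmHg` (UTF-8, "." decimal);
#' optional channels missing from the recording are omitted from the header.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  cols <- c(abp = "abp_mmHg", cbv = "cbv_cm_s", ecg = "ecg_mV", etco2 = "etco2_mmHg")
  have <- intersect(names(cols), names(rec$channels))
  t <- signal_times(rec$channels[[have[1]]])
  # %.17g guarantees doubles survive the text round trip bit-exactly
  df <- data.frame(time_s = sprintf("%.17g", t))
  for (ch in have) df[[cols[[ch]]]] <- sprintf("%.17g", rec$channels[[ch]]$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multichannel recording
#'
#' Reads the CSV dialect written by [write_recording()] (header
#' `time_s,abp_mmHg,cbv_cm_s,ecg_mV,etco2_mmHg`; the pressure channel is
#' mandatory, the others optional). Sampling frequency is inferred from the
#' time column; recordings not sampled at `target_fs` are spline-resampled
#' with a warning. EDF input is not supported by this build.
#'
#' @param path file path.
#' @param format `"csv"` (default) or `"edf"`.
#' @param target_fs expected sampling frequency, Hz.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("csv", "edf"), target_fs = 200) {
  format <- match.arg(format)
  if (format == "edf")
    stop("EDF reading is not available in this build; convert to the CSV dialect",
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df)) stop("CSV must contain a `time_s` column", call. = FALSE)
  if (!"abp_mmHg" %in% names(df))
    stop("mandatory channel `abp_mmHg` missing", call. = FALSE)
  fs <- 1 / stats::median(diff(df$time_s))
  cols <- c(abp = "abp_mmHg", cbv = "cbv_cm_s", ecg = "ecg_mV", etco2 = "etco2_mmHg")
  units <- c(abp = "mmHg", cbv = "cm/s", ecg = "mV", etco2 = "mmHg")
  channels <- list()
  for (ch in names(cols)) {
    if (!cols[[ch]] %in% names(df)) next
    v <- df[[cols[[ch]]]]
    if (abs(fs - target_fs) > 0.01 * target_fs) {
      grid <- seq(df$time_s[1], df$time_s[nrow(df)], by = 1 / target_fs)
      v <- stats::spline(df$time_s, v, xout = grid, method = "fmm")$y
      channels[[ch]] <- uniform_signal(v, target_fs, t0 = grid[1],
                                       label = ch, units = units[[ch]])
    } else {
      channels[[ch]] <- uniform_signal(v, fs, t0 = df$time_s[1],
                                       label = ch, units = units[[ch]])
    }
  }
  if (abs(fs - target_fs) > 0.01 * target_fs)
    warning(sprintf("recording sampled at %.4g Hz; resampled to %g Hz", fs, target_fs))
  recording(channels, fs = channels[["abp"]]$fs)
}

#' Per-epoch metric extraction
#'
#' Runs the full analysis chain on one annotated epoch of a recording:
#' artifact-repaired beat detection, spectral heart rate, capnographic
#' respiratory rate with the +/- 1 breath/min compliance gate, transfer
#' function analysis (VLF and the epoch-appropriate breathing-frequency
#' band), heart rate variability (time, frequency, entropy; ECG-derived RR
#' when an ECG channel is present, pulse intervals otherwise), xBRS and
#' joint symbolic dynamics. Every metric is either a number or `NA` with a
#' reason recorded in the `flags` field; a non-compliant respiratory rate
#' marks the row `excluded` but the row is still emitted.
#'
#' @param rec a [recording()].
#' @param epoch label of the protocol state: `"baseline"`, `"6"`, `"10"` or
#'   `"15"`.
#' @param start_s,end_s epoch limits in seconds; defaults to the full
#'   recording.
#' @param participant participant identifier carried into the output row.
#' @return a one-row data frame (`metrics_row`) with physiology summaries,
#'   TFA band metrics (`coh_vlf`, `ps_vlf`, `gain_vlf`, `coh_bf`, `ps_bf`,
#'   `gain_bf`), HRV metrics, `xbrs`, `jsd_sym`, `jsd_diam`, `compliant`,
#'   `excluded` and a semicolon-separated `flags` string.
#' @export
run_epoch <- function(rec, epoch = c("baseline", "6", "10", "15"),
                      start_s = NULL, end_s = NULL, participant = "P1") {
  epoch <- match.arg(as.character(epoch), c("baseline", "6", "10", "15"))
  stopifnot(inherits(rec, "recording"))
  flags <- character(0)
  note <- function(f) flags <<- c(flags, f)
  ch <- rec$channels
  if (is.null(start_s)) start_s <- ch$abp$t0
  if (is.null(end_s)) end_s <- ch$abp$t0 + (rec$n - 1) / rec$fs
  sl <- lapply(ch, signal_window, from = start_s, to = end_s)
  dur <- end_s - start_s

  # beats from the pressure wave; beat-domain artifact repair
  sap <- tryCatch(detect_systolic_peaks(sl$abp), error = function(e) NULL)
  if (is.null(sap)) {
    note("no_beats")
    row <- empty_metrics_row(participant, epoch)
    row$flags <- paste(flags, collapse = ";")
    return(row)
  }
  sap <- repair_beat_values(sap)$series
  pi_raw <- pulse_intervals(sap)
  pi_rep <- repair_beat_values(pi_raw)$series

  hr <- tryCatch(as.numeric(estimate_hr_fft(sl$abp)), error = function(e) {
    note("hr_insufficient"); NA_real_ })

  resp <- if (!is.null(sl$etco2)) tryCatch(
    estimate_resp_rate(sl$etco2,
                       target_bpm = if (epoch == "baseline") NULL else as.numeric(epoch)),
    error = function(e) { note("no_breaths"); NULL }) else { note("no_etco2"); NULL }
  compliant <- if (is.null(resp)) NA else resp$compliant
  excluded <- isTRUE(!compliant)
  if (excluded) note("noncompliant_resp_rate")

  # transfer function analysis
  ps_vlf <- gain_vlf <- coh_vlf <- ps_bf <- gain_bf <- coh_bf <- NA_real_
  if (is.null(sl$cbv)) {
    note("no_cbv_tfa_skipped")
  } else if (dur < 102.5) {
    note("tfa_insufficient_data")
  } else {
    tfa <- tryCatch({
      abp4 <- beat_average_resample(sl$abp, sap)
      cbv4 <- beat_average_resample(sl$cbv, sap)
      n <- min(length(abp4$values), length(cbv4$values))
      abp4$values <- abp4$values[seq_len(n)]
      cbv4$values <- cbv4$values[seq_len(n)]
      cross_spectra(abp4, cbv4)
    }, error = function(e) { note("tfa_insufficient_data"); NULL })
    if (!is.null(tfa)) {
      bv <- band_metrics(tfa, vlf_band())
      if (bv$defined) { coh_vlf <- bv$coherence; ps_vlf <- bv$ps_deg; gain_vlf <- bv$gain }
      else note("vlf_all_bins_gated")
      band <- if (epoch == "baseline") {
        if (!is.null(resp)) bf_band(resp$rate_bpm, resp$sd_bpm, mode = "spontaneous")
        else NULL
      } else bf_band(as.numeric(epoch))
      if (is.null(band)) {
        note("bf_band_unavailable")
      } else {
        bb <- band_metrics(tfa, band)
        if (bb$defined) { coh_bf <- bb$coherence; ps_bf <- bb$ps_deg; gain_bf <- bb$gain }
        else note("bf_all_bins_gated")
      }
    }
  }

  # RR source for HRV: ECG when available, pulse intervals otherwise
  rr_hrv <- NULL
  if (!is.null(sl$ecg)) {
    rr_hrv <- tryCatch(detect_r_peaks(sl$ecg), error = function(e) NULL)
    if (is.null(rr_hrv)) note("ecg_no_r_peaks")
  }
  if (is.null(rr_hrv)) { rr_hrv <- pi_rep; note("hrv_from_pulse_intervals") }
  else rr_hrv <- repair_beat_values(rr_hrv)$series

  ht <- if (dur >= 120) tryCatch(hrv_time(rr_hrv), error = function(e) {
    note("hrv_time_insufficient"); NULL }) else { note("hrv_insufficient_epoch"); NULL }
  hf <- if (dur >= 120) tryCatch(hrv_freq(rr_hrv), error = function(e) {
    note("hrv_freq_insufficient"); NULL }) else NULL
  he <- if (dur >= 120) tryCatch(hrv_entropy(rr_hrv), error = function(e) {
    note("hrv_entropy_insufficient"); NULL }) else NULL

  xb <- if (dur >= 120) tryCatch(compute_xbrs(pi_rep, sap), error = function(e) {
    note("xbrs_insufficient"); NULL }) else NULL
  if (!is.null(xb) && !xb$defined) note("xbrs_no_windows_accepted")

  js <- if (dur >= 120 && length(pi_rep$times) > 4) {
    n_common <- min(length(pi_rep$values), length(sap$values) - 1)
    s_rr <- symbolize(pi_rep$values[seq_len(n_common)])
    s_sap <- symbolize(sap$values[1 + seq_len(n_common)])
    tryCatch(jsd_indices(build_word_matrix(s_rr, s_sap)),
             error = function(e) { note("jsd_insufficient"); NULL })
  } else NULL

  data.frame(
    participant = participant, epoch = epoch,
    mean_abp_mmHg = mean(sl$abp$values),
    mean_cbv_cm_s = if (!is.null(sl$cbv)) mean(sl$cbv$values) else NA_real_,
    hr_bpm = hr,
    mean_etco2_mmHg = if (!is.null(sl$etco2)) mean(sl$etco2$values) else NA_real_,
    etco2_endtidal_mmHg = if (!is.null(resp)) end_tidal_level(sl$etco2) else NA_real_,
    resp_rate_bpm = if (!is.null(resp)) resp$rate_bpm else NA_real_,
    coh_vlf = coh_vlf, ps_vlf = ps_vlf, gain_vlf = gain_vlf,
    coh_bf = coh_bf, ps_bf = ps_bf, gain_bf = gain_bf,
    sdnn_ms = val_or_na(ht, "sdnn_ms"), rmssd_ms = val_or_na(ht, "rmssd_ms"),
    meannn_ms = val_or_na(ht, "meannn_ms"),
    pnn20_pct = val_or_na(ht, "pnn20_pct"), pnn50_pct = val_or_na(ht, "pnn50_pct"),
    lf_ms2 = val_or_na(hf, "lf_ms2"), hf_ms2 = val_or_na(hf, "hf_ms2"),
    lfn = val_or_na(hf, "lfn"), hfn = val_or_na(hf, "hfn"),
    lf_hf = val_or_na(hf, "lf_hf"),
    apen = val_or_na(he, "apen"), sampen = val_or_na(he, "sampen"),
    fuzzyen = val_or_na(he, "fuzzyen"), msen = val_or_na(he, "msen"),
    xbrs = if (!is.null(xb) && xb$defined) xb$xbrs_ms_per_mmHg else NA_real_,
    xbrs_delay_s = if (!is.null(xb) && xb$defined) xb$delay_mode_s else NA_real_,
    jsd_sym = val_or_na(js, "jsd_sym"), jsd_diam = val_or_na(js, "jsd_diam"),
    compliant = compliant, excluded = excluded,
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE)
}

val_or_na <- function(lst, name) {
  if (is.null(lst) || is.null(lst[[name]])) NA_real_ else lst[[name]]
}

# mean per-breath maximum of the capnogram (capnography convention)
end_tidal_level <- function(etco2) {
  v <- etco2$values
  up <- breath_onsets(etco2)
  if (length(up) < 2L) return(max(v))
  mean(vapply(seq_len(length(up) - 1L),
              function(i) max(v[up[i]:(up[i + 1L] - 1L)]), numeric(1)))
}

empty_metrics_row <- function(participant, epoch) {
  data.frame(participant = participant, epoch = epoch,
             mean_abp_mmHg = NA_real_, mean_cbv_cm_s = NA_real_,
             hr_bpm = NA_real_, mean_etco2_mmHg = NA_real_,
             etco2_endtidal_mmHg = NA_real_, resp_rate_bpm = NA_real_,
             coh_vlf = NA_real_, ps_vlf = NA_real_, gain_vlf = NA_real_,
             coh_bf = NA_real_, ps_bf = NA_real_, gain_bf = NA_real_,
             sdnn_ms = NA_real_, rmssd_ms = NA_real_, meannn_ms = NA_real_,
             pnn20_pct = NA_real_, pnn50_pct = NA_real_,
             lf_ms2 = NA_real_, hf_ms2 = NA_real_, lfn = NA_real_,
             hfn = NA_real_, lf_hf = NA_real_,
             apen = NA_real_, sampen = NA_real_, fuzzyen = NA_real_,
             msen = NA_real_,
             xbrs = NA_real_, xbrs_delay_s = NA_real_,
             jsd_sym = NA_real_, jsd_diam = NA_real_,
             compliant = NA, excluded = TRUE, flags = "",
             stringsAsFactors = FALSE)
}

#' Build a manifest of recordings and epoch annotations
#'
#' @param participant character vector of participant ids.
#' @param path recording file path per row.
#' @param epoch epoch label per row (`baseline`, `6`, `10`, `15`).
#' @param start_s,end_s epoch limits, seconds.
#' @return a `data.frame` manifest accepted by [run_cohort()].
#' @export
manifest <- function(participant, path, epoch, start_s, end_s) {
  df <- data.frame(participant = participant, path = path,
                   epoch = as.character(epoch),
                   start_s = start_s, end_s = end_s,
                   stringsAsFactors = FALSE)
  if (any(df$end_s - df$start_s < 120))
    stop("every epoch must span at least 120 s", call. = FALSE)
  for (p in unique(df$participant)) {
    e <- df[df$participant == p, ]
    e <- e[order(e$start_s), ]
    if (nrow(e) > 1 && any(e$start_s[-1] < e$end_s[-nrow(e)] - 1e-9))
      stop("overlapping epochs for participant ", p, call. = FALSE)
  }
  df
}

#' Cohort-level analysis
#'
#' Extracts the per-epoch metrics row for every manifest entry, then, with
#' at least 3 participants, assembles the cohort outputs: median +/-
#' interquartile range per condition, Friedman tests with Kendall's W and
#' Bonferroni-corrected Wilcoxon post-hocs across the three paced rates,
#' Spearman matrices between autonomic and autoregulation metrics per
#' condition, and mixed-model tables for the phase-shift responses.
#' Non-compliant epochs are excluded from statistics (but present in the
#' raw rows) and every exclusion is logged.
#'
#' @param man a [manifest()] data frame.
#' @param out_dir optional directory; when given, writes `metrics.csv`,
#'   `summary.csv`, `friedman.csv`, `posthoc.csv`, `lmm_ps.csv`,
#'   `exclusions.log` and `results.json` there.
#' @param metrics metric columns carried into the cohort statistics.
#' @return a list: `rows` (per-epoch metrics), `summary` (median/IQR per
#'   condition), `friedman`, `posthoc`, `spearman` (per condition), `lmm`
#'   (per response), `exclusions`.
#' @export
run_cohort <- function(man, out_dir = NULL,
                       metrics = c("ps_vlf", "gain_vlf", "coh_vlf",
                                   "ps_bf", "gain_bf", "coh_bf",
                                   "sdnn_ms", "rmssd_ms", "meannn_ms",
                                   "pnn20_pct", "pnn50_pct", "lfn", "hfn",
                                   "lf_hf", "apen", "sampen", "fuzzyen",
                                   "msen", "xbrs", "jsd_sym", "jsd_diam")) {
  if (!nrow(man)) stop("empty manifest", call. = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
    rec <- read_recording(man$path[i])
    run_epoch(rec, man$epoch[i], man$start_s[i], man$end_s[i],
              participant = man$participant[i])
  }))
  exclusions <- rows[rows$excluded %in% TRUE,
                     c("participant", "epoch", "flags")]
  usable <- rows[!(rows$excluded %in% TRUE), ]
  conds <- c("6", "10", "15")
  n_part <- length(unique(usable$participant))

  summarize <- function(df) {
    do.call(rbind, lapply(metrics, function(mname) {
      do.call(rbind, lapply(unique(df$epoch), function(ep) {
        v <- df[[mname]][df$epoch == ep]
        v <- v[is.finite(v)]
        data.frame(metric = mname, epoch = ep, n = length(v),
                   median = if (length(v)) stats::median(v) else NA_real_,
                   iqr = if (length(v)) stats::IQR(v) else NA_real_)
      }))
    }))
  }
  out <- list(rows = rows, summary = summarize(usable),
              exclusions = exclusions)

  if (n_part >= 3) {
    wide <- function(mname) {
      m <- matrix(NA_real_, n_part, length(conds),
                  dimnames = list(unique(usable$participant), conds))
      for (i in seq_len(nrow(usable))) {
        r <- usable[i, ]
        if (r$epoch %in% conds)
          m[r$participant, r$epoch] <- r[[mname]]
      }
      m
    }
    fr <- do.call(rbind, lapply(metrics, function(mname) {
      m <- wide(mname)
      ok <- stats::complete.cases(m)
      if (sum(ok) < 3)
        return(data.frame(metric = mname, n = sum(ok), chi2 = NA, p = NA, W = NA))
      f <- friedman_test(m)
      data.frame(metric = mname, n = f$n, chi2 = f$chi2, p = f$p,
                 W = f$chi2 / (f$n * (f$k - 1)))
    }))
    ph <- do.call(rbind, lapply(metrics, function(mname) {
      m <- wide(mname)
      if (sum(stats::complete.cases(m)) < 6) return(NULL)
      cbind(metric = mname, wilcoxon_posthoc(m))
    }))
    ans_cols <- intersect(c("sdnn_ms", "rmssd_ms", "meannn_ms", "pnn20_pct",
                            "pnn50_pct", "xbrs", "lfn", "hfn", "lf_hf",
                            "jsd_sym", "jsd_diam", "msen", "apen", "sampen",
                            "fuzzyen"), metrics)
    ca_cols <- intersect(c("ps_vlf", "gain_vlf", "ps_bf", "gain_bf"), metrics)
    sp <- lapply(conds, function(ep) {
      d <- usable[usable$epoch == ep, ]
      if (nrow(d) < 10) return(NULL)
      spearman_matrix(d[, ans_cols], d[, ca_cols])
    })
    names(sp) <- conds
    lmm_data <- usable[usable$epoch %in% conds, ]
    lmm_data$resp_rate <- as.numeric(lmm_data$epoch)
    lmm_data$etco2 <- lmm_data$mean_etco2_mmHg
    lmm <- lapply(intersect(c("ps_vlf", "ps_bf"), metrics), function(resp) {
      tryCatch(lmm_table(lmm_data, resp, ans_cols), error = function(e) NULL)
    })
    names(lmm) <- intersect(c("ps_vlf", "ps_bf"), metrics)
    out$friedman <- fr; out$posthoc <- ph; out$spearman <- sp; out$lmm <- lmm
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rows, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(out$summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    if (!is.null(out$friedman))
      utils::write.csv(out$friedman, file.path(out_dir, "friedman.csv"), row.names = FALSE)
    if (!is.null(out$posthoc))
      utils::write.csv(out$posthoc, file.path(out_dir, "posthoc.csv"), row.names = FALSE)
    writeLines(apply(exclusions, 1, paste, collapse = "\t"),
               file.path(out_dir, "exclusions.log"))
    jsonlite::write_json(
      list(summary = out$summary, friedman = out$friedman),
      file.path(out_dir, "results.json"), dataframe = "rows", auto_unbox = TRUE)
  }
  out
}

#' Read an analysis configuration from YAML
#'
#' Loads tunables (Welch segment length, overlap, resampling rate, bands,
#' compliance tolerance, significance levels) from a YAML file, filling in
#' the package defaults for anything unspecified.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a named list of settings.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(welch_segment_s = 102.4, welch_overlap = 0.5,
                   resample_fs = 4, vlf = c(0.02, 0.07),
                   bf_halfwidth_hz = 0.02, compliance_tol_bpm = 1,
                   alpha = 0.05, posthoc_m = 3)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
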