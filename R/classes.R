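#' Uniformly sampled physiological signal
#'
#' Lightweight container for an evenly sampled channel (arterial pressure,
#' cerebral blood velocity, ECG, capnogram, ...). Values are stored together
#' with the sampling frequency and the time of the first sample so that
#' downstream operations can reconstruct absolute time.
#'
#' @param values numeric vector of samples, in the channel's units.
#' @param fs sampling frequency in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param label short channel label, e.g. `"abp"`.
#' @param units unit string, e.g. `"mmHg"`.
#' @return an object of class `uniform_signal`.
#' @export
uniform_signal <- function(values, fs, t0 = 0, label = "", units = "") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (length(values) < 2L)
    stop("`values` must contain at least two samples", call. = FALSE)
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs), t0 = as.numeric(t0),
         label = label, units = units),
    class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %s [%s]: %d samples @ %g Hz, t0 = %.3f s (%.1f s)\n",
              x$label, x$units, length(x$values), x$fs, x$t0,
              length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$values)

#' Sample times of a uniform signal
#' @param x a `uniform_signal`.
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Extract a time slice of a uniform signal
#' @param x a `uniform_signal`.
#' @param from,to slice limits in seconds (absolute time).
#' @return a `uniform_signal` covering `[from, to]`.
#' @export
signal_window <- function(x, from, to) {
  stopifnot(inherits(x, "uniform_signal"), to > from)
  t <- signal_times(x)
  keep <- which(t >= from - 1e-9 & t <= to + 1e-9)
  if (length(keep) < 2L) stop("requested window contains fewer than 2 samples", call. = FALSE)
  uniform_signal(x$values[keep], x$fs, t0 = t[keep[1L]], label = x$label, units = x$units)
}

#' Event-indexed beat-to-beat series
#'
#' Stores one value per cardiac beat (RR interval in ms, systolic pressure in
#' mmHg, beat-averaged pressure or velocity) anchored at strictly increasing
#' event times.
#'
#' @param times anchor times in seconds, strictly increasing.
#' @param values one value per anchor.
#' @param label series label, e.g. `"rr"` or `"sap"`.
#' @param units unit string.
#' @return an object of class `beat_series`.
#' @export
beat_series <- function(times, values, label = "", units = "") {
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label, units = units),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %s [%s]: %d beats over %.1f s\n",
              x$label, x$units, length(x$times),
              if (length(x$times) > 1) diff(range(x$times)) else 0))
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$times)

#' Restrict a beat series to a time window
#' @param x a `beat_series`.
#' @param from,to window limits in seconds.
#' @return a `beat_series`.
#' @export
beat_window <- function(x, from, to) {
  stopifnot(inherits(x, "beat_series"))
  keep <- x$times >= from - 1e-9 & x$times <= to + 1e-9
  beat_series(x$times[keep], x$values[keep], label = x$label, units = x$units)
}

#' Multichannel 200 Hz recording
#'
#' Bundles synchronized uniformly sampled channels. The arterial pressure
#' channel (`abp`) is mandatory for analysis; `cbv`, `ecg` and `etco2` are
#' optional and downstream stages flag metrics they cannot compute.
#'
#' @param channels named list of `uniform_signal` objects on one time grid.
#' @param fs common sampling frequency in Hz.
#' @return an object of class `recording`.
#' @export
recording <- function(channels, fs = 200) {
  stopifnot(is.list(channels), length(channels) > 0, !is.null(names(channels)))
  for (ch in channels) {
    stopifnot(inherits(ch, "uniform_signal"))
    if (abs(ch$fs - fs) > 1e-9)
      stop("all channels must share the recording sampling frequency", call. = FALSE)
  }
  n <- unique(vapply(channels, function(ch) length(ch$values), integer(1)))
  if (length(n) != 1L) stop("all channels must have equal length", call. = FALSE)
  structure(list(channels = channels, fs = fs, n = n), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels (%s), %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$n, x$fs, x$n / x$fs))
  invisible(x)
}

# internal: condition constructors used across modules
.err <- function(msg, class) {
  stop(structure(class = c(class, "breathca_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
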