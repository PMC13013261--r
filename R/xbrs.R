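#' Cross-correlation baroreflex sensitivity (xBRS)
#'
#' Implements the cross-correlation method: beat-to-beat systolic pressure
#' and pulse-interval series are resampled onto a common 1 Hz grid; in every
#' 10 s window (sliding by 1 s) the interval series is correlated with the
#' pressure series at delays of 0--3 s and the delay with the largest
#' positive Pearson correlation is selected. Windows are accepted when that
#' correlation is significant (p < 0.05) and contain no flagged ectopic
#' beat; the accepted window's regression slope (ms/mmHg) is recorded. The
#' per-epoch xBRS is the median accepted slope, the reported delay is the
#' modal selected delay among accepted windows.
#'
#' Ectopic flag: a pulse interval deviating more than 25% from the median of
#' its 10 nearest neighbours.
#'
#' @param rr `beat_series` of pulse intervals, ms.
#' @param sap `beat_series` of systolic pressures, mmHg, covering the same
#'   span.
#' @param delays_s candidate delays in seconds (default 0:3).
#' @param window_s window length, seconds (default 10).
#' @param alpha significance level for window acceptance.
#' @return an object of class `xbrs_result`: `xbrs_ms_per_mmHg` (median
#'   slope, `NA` when no window accepted), `delay_mode_s`, `n_windows_used`,
#'   `n_windows_total`, `defined`, and `windows` (data frame with `t_start`,
#'   `delay_s`, `r`, `p`, `slope`).
#' @export
compute_xbrs <- function(rr, sap, delays_s = 0:3, window_s = 10, alpha = 0.05) {
  stopifnot(inherits(rr, "beat_series"), inherits(sap, "beat_series"))
  t_lo <- max(rr$times[1], sap$times[1])
  t_hi <- min(rr$times[length(rr$times)], sap$times[length(sap$times)])
  if (t_hi - t_lo < 30)
    .err("need at least 30 s of overlapping beat data for xBRS", "breathca_insufficient_data")
  grid <- seq(ceiling(t_lo), floor(t_hi), by = 1)
  # nearest-beat staircase resampling: each second carries the value of the
  # closest beat (timing error at most half a beat, and no interpolation-
  # induced serial correlation that would inflate window significance)
  rr1 <- nearest_beat_values(rr, grid)
  sap1 <- nearest_beat_values(sap, grid)
  ect_times <- ectopic_times(rr)
  w <- as.integer(window_s)
  dmax <- max(delays_s)
  n <- length(grid)
  rows <- list()
  n_total <- 0L
  i0 <- 1L
  while (i0 + w - 1L + dmax <= n) {
    n_total <- n_total + 1L
    xs <- sap1[i0:(i0 + w - 1L)]
    best <- NULL
    for (d in delays_s) {
      ys <- rr1[(i0 + d):(i0 + d + w - 1L)]
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
      r <- stats::cor(xs, ys)
      if (is.null(best) || (is.finite(r) && r > best$r))
        best <- list(d = d, r = r, ys = ys)
    }
    if (!is.null(best) && is.finite(best$r) && best$r > 0) {
      tt <- best$r * sqrt((w - 2) / max(1 - best$r^2, 1e-15))
      p <- 2 * stats::pt(-abs(tt), df = w - 2)
      win_lo <- grid[i0]; win_hi <- grid[i0] + w - 1 + best$d
      has_ect <- any(ect_times >= win_lo & ect_times <= win_hi)
      if (p < alpha && !has_ect) {
        slope <- best$r * stats::sd(best$ys) / stats::sd(xs)
        rows[[length(rows) + 1L]] <-
          data.frame(t_start = grid[i0], delay_s = best$d,
                     r = best$r, p = p, slope = slope)
      }
    }
    i0 <- i0 + 1L
  }
  windows <- if (length(rows)) do.call(rbind, rows)
             else data.frame(t_start = numeric(0), delay_s = numeric(0),
                             r = numeric(0), p = numeric(0), slope = numeric(0))
  used <- nrow(windows)
  structure(list(
    xbrs_ms_per_mmHg = if (used) stats::median(windows$slope) else NA_real_,
    delay_mode_s = if (used) modal_value(windows$delay_s) else NA_real_,
    n_windows_used = used,
    n_windows_total = n_total,
    defined = used > 0L,
    windows = windows), class = "xbrs_result")
}

nearest_beat_values <- function(bs, grid) {
  idx <- findInterval(grid, bs$times)
  idx[idx < 1L] <- 1L
  nxt <- pmin(idx + 1L, length(bs$times))
  use_next <- abs(bs$times[nxt] - grid) < abs(bs$times[idx] - grid)
  idx[use_next] <- nxt[use_next]
  bs$values[idx]
}

modal_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

# pulse intervals deviating > 25% from the median of their 10 nearest
# neighbours are flagged as ectopic
ectopic_times <- function(rr, n_neighbors = 10L, tol = 0.25) {
  v <- rr$values
  n <- length(v)
  if (n < n_neighbors + 1L) return(numeric(0))
  half <- n_neighbors %/% 2L
  flagged <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    nb <- v[setdiff(lo:hi, i)]
    med <- stats::median(nb)
    if (med > 0 && abs(v[i] - med) > tol * med) flagged[i] <- TRUE
  }
  rr$times[flagged]
}

#' @export
print.xbrs_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<xbrs_result> xBRS = %.2f ms/mmHg (median of %d/%d windows), modal delay %g s\n",
                x$xbrs_ms_per_mmHg, x$n_windows_used, x$n_windows_total, x$delay_mode_s))
  else
    cat(sprintf("<xbrs_result> undefined: 0/%d windows accepted\n", x$n_windows_total))
  invisible(x)
}
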