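#' Binary symbolization of beat-to-beat changes
#'
#' Maps a beat-to-beat series to a binary symbol per transition: symbol n is
#' 1 when `x_n - x_{n+1} < l` (i.e. with the default threshold `l = 0`, 1 on
#' a strict increase and 0 on a decrease or tie).
#'
#' @param x a `beat_series` or numeric vector with at least 2 values.
#' @param l threshold (default 0).
#' @return integer vector of 0/1 symbols, length `n - 1`, with attribute
#'   `"source_label"`.
#' @export
symbolize <- function(x, l = 0) {
  lab <- if (inherits(x, "beat_series")) x$label else ""
  v <- rr_values(x)
  if (length(v) < 2L) stop("need at least 2 values to symbolize", call. = FALSE)
  if (any(!is.finite(v))) stop("non-finite values cannot be symbolized", call. = FALSE)
  s <- as.integer((v[-length(v)] - v[-1]) < l)
  attr(s, "source_label") <- lab
  s
}

# overlapping 3-symbol words, most significant bit first in time
words_from_symbols <- function(s, word_len = 3L) {
  n <- length(s)
  nw <- n - word_len + 1L
  w <- integer(nw)
  for (k in seq_len(word_len))
    w <- w + s[k:(k + nw - 1L)] * 2L^(word_len - k)
  w
}

#' Bivariate word distribution matrix of joint symbolic dynamics
#'
#' Builds overlapping words of length `word_len` (default 3, hence 8
#' possible words per series and 64 joint word types) from the RR and SAP
#' symbol sequences and tabulates their joint relative frequencies into an
#' 8 x 8 matrix `W`; rows index the RR word, columns the SAP word (binary,
#' most significant bit earliest in time). The optional `lag` shifts the SAP
#' sequence forward by that many symbols before pairing (default 0; the
#' beat-anchoring of the input series already realizes the convention that a
#' pressure change affects the subsequent RR interval).
#'
#' @param s_rr,s_sap binary symbol sequences of equal length (from
#'   [symbolize()]).
#' @param word_len word length (default 3).
#' @param lag alignment lag in symbols applied to the SAP sequence.
#' @return an object of class `word_matrix`: `w` (8 x 8 relative
#'   frequencies summing to 1), `n_words`.
#' @export
build_word_matrix <- function(s_rr, s_sap, word_len = 3L, lag = 0L) {
  if (length(s_rr) != length(s_sap))
    stop("symbol sequences must have equal length", call. = FALSE)
  if (lag > 0L) {
    s_rr <- s_rr[-seq_len(lag)]
    s_sap <- s_sap[seq_len(length(s_sap) - lag)]
  } else if (lag < 0L) {
    s_sap <- s_sap[-seq_len(-lag)]
    s_rr <- s_rr[seq_len(length(s_rr) + lag)]
  }
  if (length(s_rr) < word_len)
    .err("symbol sequence shorter than the word length", "breathca_insufficient_data")
  wr <- words_from_symbols(s_rr, word_len)
  ws <- words_from_symbols(s_sap, word_len)
  k <- 2L^word_len
  counts <- tabulate(wr * k + ws + 1L, nbins = k * k)
  w <- matrix(counts, k, k, byrow = TRUE,
              dimnames = list(rr_word = 0:(k - 1), sap_word = 0:(k - 1)))
  n_words <- length(wr)
  structure(list(w = w / n_words, n_words = n_words),
            class = "word_matrix")
}

#' Diagonal and antidiagonal indices of the word matrix
#'
#' `jsd_sym` (sum of the main diagonal) is the relative frequency of
#' baroreflex-like word types, where RR and SAP change in the same
#' direction pattern; `jsd_diam` (sum of the antidiagonal) captures
#' patterns opposed to baroreflex behaviour. For the 8 x 8 matrix the two
#' cell sets are disjoint, so `jsd_sym + jsd_diam <= 1`.
#'
#' @param wm a `word_matrix` from [build_word_matrix()].
#' @return a list: `jsd_sym`, `jsd_diam`.
#' @export
jsd_indices <- function(wm) {
  stopifnot(inherits(wm, "word_matrix"))
  k <- nrow(wm$w)
  list(jsd_sym = sum(diag(wm$w)),
       jsd_diam = sum(wm$w[cbind(seq_len(k), k:1)]))
}

#' Long-format export of a word matrix
#'
#' @param wm a `word_matrix`.
#' @return a data frame with columns `rr_word`, `sap_word`, `freq`, suitable
#'   for heatmap plotting or CSV export.
#' @export
word_matrix_long <- function(wm) {
  stopifnot(inherits(wm, "word_matrix"))
  k <- nrow(wm$w)
  data.frame(rr_word = rep(0:(k - 1), times = k),
             sap_word = rep(0:(k - 1), each = k),
             freq = as.vector(wm$w))
}

#' @export
print.word_matrix <- function(x, ...) {
  idx <- jsd_indices(x)
  cat(sprintf("<word_matrix> %d words; JSD_sym = %.3f, JSD_diam = %.3f\n",
              x$n_words, idx$jsd_sym, idx$jsd_diam))
  invisible(x)
}
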