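#' Friedman repeated-measures test
#'
#' Rank-based Friedman statistic with average-rank tie handling and the
#' classical tie correction; the p-value uses the chi-square approximation
#' with k - 1 degrees of freedom. Participants (rows) with any missing
#' condition are excluded listwise. Fully tied data yield statistic 0 and
#' p = 1.
#'
#' @param tab numeric matrix or data frame: rows = participants, columns =
#'   conditions.
#' @return a list: `chi2`, `p`, `n` (complete participants), `k`
#'   (conditions), `df`.
#' @export
friedman_test <- function(tab) {
  y <- as.matrix(tab)
  y <- y[stats::complete.cases(y), , drop = FALSE]
  n <- nrow(y); k <- ncol(y)
  if (k < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (n < 3L) stop("need at least 3 complete participants", call. = FALSE)
  r <- t(apply(y, 1L, rank))
  ties_penalty <- sum(apply(r, 1L, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  })) / (k - 1)
  denom <- n * k * (k + 1) - ties_penalty
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  chi2 <- if (denom <= 0) 0 else num / denom
  list(chi2 = chi2,
       p = if (denom <= 0) 1 else stats::pchisq(chi2, k - 1, lower.tail = FALSE),
       n = n, k = k, df = k - 1L)
}

#' Kendall's W effect size for repeated measures
#'
#' Concordance coefficient `W = chi2 / (n (k - 1))`, where chi2 is the
#' Friedman statistic; W is 1 under perfect agreement between participants'
#' condition orderings and 0 when all values are tied.
#'
#' @inheritParams friedman_test
#' @return Kendall's W in `[0, 1]`.
#' @export
kendalls_w <- function(tab) {
  f <- friedman_test(tab)
  f$chi2 / (f$n * (f$k - 1))
}

#' Bonferroni-corrected Wilcoxon signed-rank post-hoc comparisons
#'
#' Paired Wilcoxon signed-rank tests on every pair of conditions, declared
#' significant at the Bonferroni-corrected threshold `alpha / m` with m the
#' number of comparisons (3 pairs for the three paced rates, giving the
#' conventional corrected threshold of 0.0167 < 0.017). Zero differences
#' are dropped (Wilcoxon convention); the exact distribution is used for up
#' to 25 untied non-zero pairs, the normal approximation with continuity
#' correction otherwise. A pair with all differences zero reports p = 1.
#'
#' @param tab numeric matrix or data frame: rows = participants, columns =
#'   conditions (column names label the comparisons).
#' @param alpha family significance level (default 0.05).
#' @return a data frame with columns `pair`, `n_pairs`, `p`, `threshold`,
#'   `significant`.
#' @export
wilcoxon_posthoc <- function(tab, alpha = 0.05) {
  y <- as.matrix(tab)
  k <- ncol(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("cond", seq_len(k))
  prs <- utils::combn(k, 2)
  m <- ncol(prs)
  thr <- alpha / m
  out <- lapply(seq_len(m), function(j) {
    a <- y[, prs[1, j]]; b <- y[, prs[2, j]]
    ok <- stats::complete.cases(cbind(a, b))
    d <- a[ok] - b[ok]
    d <- d[d != 0]
    if (length(d) == 0L) {
      p <- 1
    } else {
      exact <- length(d) <= 25 && !any(duplicated(abs(d)))
      p <- suppressWarnings(
        stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value)
    }
    data.frame(pair = paste(colnames(y)[prs[1, j]], "vs", colnames(y)[prs[2, j]]),
               n_pairs = length(d), p = p, threshold = thr,
               significant = p < thr)
  })
  do.call(rbind, out)
}

#' Spearman correlation matrix between two metric blocks
#'
#' Rank correlation per (row metric, column metric) pair with
#' pairwise-complete observations; a constant column yields `NA` (flagged
#' undefined). P-values come from the t approximation (ties handled by
#' average ranks).
#'
#' @param ans data frame of autonomic metrics (columns = metrics).
#' @param ca data frame of cerebral-autoregulation metrics, same rows.
#' @param min_n minimum paired observations per cell (default 10).
#' @return a list of matrices `rho` and `p` (rows = `ans` metrics, columns =
#'   `ca` metrics), `NA` where undefined or under-powered.
#' @export
spearman_matrix <- function(ans, ca, min_n = 10L) {
  ans <- as.data.frame(ans); ca <- as.data.frame(ca)
  stopifnot(nrow(ans) == nrow(ca))
  rho <- matrix(NA_real_, ncol(ans), ncol(ca),
                dimnames = list(names(ans), names(ca)))
  p <- rho
  for (i in seq_len(ncol(ans))) for (j in seq_len(ncol(ca))) {
    x <- ans[[i]]; y <- ca[[j]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_n) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(rho = rho, p = p)
}

#' Linear mixed-effects model relating autoregulation to autonomic activity
#'
#' Fits `response ~ ans_metric + resp_rate + etco2 + (1 | participant)` by
#' REML (one autonomic metric at a time), and reports the marginal
#' (type-III) F and p per fixed effect with Satterthwaite degrees of
#' freedom. Singular fits are flagged but still returned.
#'
#' @param data long-format data frame with columns `participant`, the
#'   response, the autonomic metric, `resp_rate` and `etco2` (names
#'   configurable below).
#' @param response name of the autoregulation response column.
#' @param ans_metric name of the autonomic metric column.
#' @param rate_col,etco2_col,id_col column names for the respiratory rate,
#'   end-tidal CO2 and participant id.
#' @return a list: `fits` (data frame with one row per fixed effect: `term`,
#'   `F`, `p`, `df_num`, `df_den`), `estimates` (named fixed-effect
#'   coefficients), `singular` (logical), `model` (the fitted `lmerMod`).
#' @export
fit_lmm <- function(data, response, ans_metric,
                    rate_col = "resp_rate", etco2_col = "etco2",
                    id_col = "participant") {
  need <- c(response, ans_metric, rate_col, etco2_col, id_col)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[stats::complete.cases(data[, need]), need]
  names(d) <- c(".y", ".ans", ".rate", ".etco2", ".id")
  if (min(table(d$.id)) < 2 && length(unique(d$.id)) < 3)
    stop("need repeated observations per participant", call. = FALSE)
  fit <- suppressMessages(lmerTest::lmer(
    .y ~ .ans + .rate + .etco2 + (1 | .id), data = d, REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular random-effect fit; fixed-effect tests still reported")
  an <- stats::anova(fit, type = 3)
  fits <- data.frame(term = c(ans_metric, rate_col, etco2_col),
                     F = an[["F value"]],
                     p = an[["Pr(>F)"]],
                     df_num = an[["NumDF"]],
                     df_den = an[["DenDF"]])
  est <- lme4::fixef(fit)
  names(est) <- c("(Intercept)", ans_metric, rate_col, etco2_col)
  list(fits = fits, estimates = est, singular = singular, model = fit)
}

#' Mixed-model table across autonomic metrics
#'
#' Repeats [fit_lmm()] for each autonomic metric (one metric per fit) and
#' assembles the table of F and p values for the metric, respiratory rate
#' and end-tidal CO2 terms.
#'
#' @inheritParams fit_lmm
#' @param ans_metrics character vector of autonomic metric column names.
#' @return a data frame with one row per autonomic metric: `ans_metric`,
#'   `F_ans`, `p_ans`, `F_rate`, `p_rate`, `F_etco2`, `p_etco2`,
#'   `singular`.
#' @export
lmm_table <- function(data, response, ans_metrics,
                      rate_col = "resp_rate", etco2_col = "etco2",
                      id_col = "participant") {
  rows <- lapply(ans_metrics, function(metric) {
    res <- tryCatch(
      suppressWarnings(fit_lmm(data, response, metric, rate_col, etco2_col, id_col)),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(ans_metric = metric, F_ans = NA, p_ans = NA,
                        F_rate = NA, p_rate = NA, F_etco2 = NA, p_etco2 = NA,
                        singular = NA))
    f <- res$fits
    data.frame(ans_metric = metric,
               F_ans = f$F[1], p_ans = f$p[1],
               F_rate = f$F[2], p_rate = f$p[2],
               F_etco2 = f$F[3], p_etco2 = f$p[3],
               singular = res$singular)
  })
  do.call(rbind, rows)
}
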