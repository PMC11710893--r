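# The statistical battery used for workload contrasts: paired t with
# Cohen's d, one-way repeated-measures ANOVA with partial eta squared,
# Fisher protected LSD, Pearson correlation with strength categories, and
# Benjamini-Hochberg FDR. All statistics are computed from first
# principles (sums of squares, step-up formula) so that each has an
# independent oracle in the test suite.

#' Paired-sample t test with Cohen's d
#'
#' Two-sided paired t on differences `x - y`. Cohen's d uses the pooled
#' condition SD convention, `|mean(x) - mean(y)| / sqrt((sd(x)^2 +
#' sd(y)^2) / 2)` (sample SDs, n - 1); this convention reproduces the
#' effect sizes obtainable from condition-level summary statistics alone.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), one value per
#'   subject.
#' @return A `paired_t_result`: list with `t`, `df`, `p`, `d`,
#'   `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  d_i <- x - y
  sd_d <- stats::sd(d_i)
  if (sd_d == 0) stop("zero-variance differences: paired t undefined")
  t_stat <- mean(d_i) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  d <- abs(mean(x) - mean(y)) / sqrt((stats::sd(x)^2 + stats::sd(y)^2) / 2)
  structure(list(t = t_stat, df = n - 1L, p = p, d = d,
                 mean_diff = mean(d_i), n = n),
            class = "paired_t_result")
}

#' Cohen's d from summary statistics
#'
#' Pooled-SD effect size `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)` computed
#' directly from condition means and SDs (as printed in summary tables).
#'
#' @param m1,s1 Mean and SD of condition 1.
#' @param m2,s2 Mean and SD of condition 2.
#' @return Cohen's d (non-negative scalar).
#' @export
cohens_d_from_summary <- function(m1, s1, m2, s2) {
  abs(m1 - m2) / sqrt((s1^2 + s2^2) / 2)
}

#' One-way repeated-measures ANOVA
#'
#' Standard within-subject decomposition of a complete subject x level
#' matrix: `SS_total = SS_subjects + SS_effect + SS_error`,
#' `F = MS_effect / MS_error`, partial eta squared
#' `SS_effect / (SS_effect + SS_error)`. No sphericity correction is
#' applied by default; `gg = TRUE` applies the Greenhouse-Geisser epsilon
#' to the degrees of freedom of the p-value.
#'
#' @param data Numeric subject x level matrix, complete (no NA).
#' @param gg Apply Greenhouse-Geisser correction to the p-value
#'   (default FALSE).
#' @return An `rm_anova_result`: list with `F`, `df_effect`, `df_error`,
#'   `p`, `partial_eta_sq`, `ms_error`, `means`, `n`.
#' @export
rm_anova_one_way <- function(data, gg = FALSE) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing cells: repeated-measures ANOVA needs complete data")
  n <- nrow(data); a <- ncol(data)
  stopifnot(n >= 3, a >= 2)
  grand <- mean(data)
  level_means <- colMeans(data)
  subj_means <- rowMeans(data)
  ss_effect <- n * sum((level_means - grand)^2)
  ss_subj <- a * sum((subj_means - grand)^2)
  ss_total <- sum((data - grand)^2)
  ss_error <- ss_total - ss_effect - ss_subj
  df_effect <- a - 1L
  df_error <- (a - 1L) * (n - 1L)
  ms_effect <- ss_effect / df_effect
  ms_error <- ss_error / df_error
  F_stat <- if (ms_error > 0) ms_effect / ms_error else
    (if (ss_effect == 0) 0 else Inf)
  eps <- 1
  if (gg && a > 2) {
    S <- stats::cov(data)
    dbar <- mean(diag(S)); mbar <- mean(S)
    rowm <- rowMeans(S)
    num <- (a * (dbar - mbar))^2
    den <- (a - 1) * (sum(S^2) - 2 * a * sum(rowm^2) + a^2 * mbar^2)
    eps <- if (den > 0) num / den else 1
    eps <- min(max(eps, 1 / (a - 1)), 1)
  }
  p <- stats::pf(F_stat, eps * df_effect, eps * df_error,
                 lower.tail = FALSE)
  structure(list(F = F_stat, df_effect = df_effect, df_error = df_error,
                 p = p,
                 partial_eta_sq = ss_effect / (ss_effect + ss_error),
                 ms_error = ms_error, means = level_means, n = n,
                 gg_epsilon = eps),
            class = "rm_anova_result")
}

#' Fisher protected least significant difference
#'
#' Pairwise comparisons of levels after a repeated-measures omnibus test,
#' using the ANOVA error term: `t = (mean_i - mean_j) /
#' sqrt(2 * MS_error / n)` with `df = df_error`. Protection: pairwise
#' p-values are only reported when the omnibus p is below `alpha`;
#' otherwise each pair is flagged `protected = FALSE` and its p is NA.
#'
#' @param data Subject x level matrix (as for [rm_anova_one_way()]).
#' @param pairs Optional 2-column matrix of level index pairs; default all
#'   consecutive pairs `(1,2), (2,3), ...`.
#' @param alpha Protection threshold for the omnibus test (default 0.05).
#' @return A data.frame with columns `level_i`, `level_j`, `t`, `df`, `p`,
#'   `protected`; attribute `omnibus` holds the `rm_anova_result`.
#' @export
fisher_plsd <- function(data, pairs = NULL, alpha = 0.05) {
  data <- as.matrix(data)
  om <- rm_anova_one_way(data)
  a <- ncol(data); n <- nrow(data)
  if (is.null(pairs)) {
    pairs <- cbind(seq_len(a - 1), 2:a)
  }
  protected <- om$p < alpha
  res <- data.frame(level_i = pairs[, 1], level_j = pairs[, 2],
                    t = NA_real_, df = om$df_error, p = NA_real_,
                    protected = protected)
  if (protected) {
    se <- sqrt(2 * om$ms_error / n)
    res$t <- (om$means[pairs[, 1]] - om$means[pairs[, 2]]) / se
    res$p <- 2 * stats::pt(-abs(res$t), df = om$df_error)
  }
  attr(res, "omnibus") <- om
  res
}

#' Pearson correlation with strength category
#'
#' Product-moment correlation with a two-sided p-value via the t
#' transform. Strength categories follow the conventional absolute-R
#' thresholds: > 0.70 strong, 0.50-0.70 moderate, 0.30-0.50 weak,
#' otherwise negligible.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return A `correlation_result`: list with `R`, `p`, `n`, `strength`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  R <- stats::cor(x, y)
  t_stat <- R * sqrt((n - 2) / (1 - R^2))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  a <- abs(R)
  strength <- if (a > 0.70) "strong" else if (a >= 0.50) "moderate"
  else if (a >= 0.30) "weak" else "negligible"
  structure(list(R = R, p = p, n = n, strength = strength),
            class = "correlation_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values
#' `p_adj[(i)] = min_{j >= i} min(1, m * p[(j)] / j)` computed directly
#' from the definition, plus the rejection mask at level `q`.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @param q FDR level for the rejection mask (default 0.05).
#' @return A list with `p_adj` (same order as input) and `reject`.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  o <- order(pvalues)
  scaled <- pmin(1, m * pvalues[o] / seq_len(m))
  adj_sorted <- rev(cummin(rev(scaled)))
  p_adj <- numeric(m)
  p_adj[o] <- adj_sorted
  list(p_adj = p_adj, reject = p_adj <= q)
}

#' Electrode-wise paired band-power contrast
#'
#' For one band, runs a paired t test per channel (high vs low workload
#' across subjects, blocks averaged within subject x condition) and
#' applies Benjamini-Hochberg FDR across the channels. Reports per-channel
#' t, raw and adjusted p, and the count of significant channels per
#' direction.
#'
#' @param table A `band_power_table` covering both conditions.
#' @param band Band name (e.g. "theta").
#' @param cond_high,cond_low Condition labels (defaults "high", "low").
#' @param q FDR level (default 0.05).
#' @return A list with `by_channel` (data.frame: channel, t, p, p_adj,
#'   significant), `n_significant`, `n_sig_positive` (high > low),
#'   `n_sig_negative`.
#' @export
electrode_wise_contrast <- function(table, band, cond_high = "high",
                                    cond_low = "low", q = 0.05) {
  tb <- as.data.frame(table)
  tb <- tb[tb$band == band, ]
  if (nrow(tb) == 0) stop(sprintf("band '%s' not present in table", band))
  # average blocks within subject x condition x channel
  agg <- stats::aggregate(power ~ subject + condition + channel, data = tb,
                          FUN = mean)
  channels <- unique(agg$channel)
  res <- data.frame(channel = channels, t = NA_real_, p = NA_real_)
  for (i in seq_along(channels)) {
    ch <- agg[agg$channel == channels[i], ]
    hi <- ch[ch$condition == cond_high, ]
    lo <- ch[ch$condition == cond_low, ]
    hi <- hi[order(hi$subject), ]; lo <- lo[order(lo$subject), ]
    stopifnot(identical(hi$subject, lo$subject))
    tt <- paired_t(hi$power, lo$power)
    res$t[i] <- tt$t
    res$p[i] <- tt$p
  }
  adj <- fdr_bh(res$p, q = q)
  res$p_adj <- adj$p_adj
  res$significant <- adj$reject
  list(by_channel = res,
       n_significant = sum(res$significant),
       n_sig_positive = sum(res$significant & res$t > 0),
       n_sig_negative = sum(res$significant & res$t < 0))
}
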