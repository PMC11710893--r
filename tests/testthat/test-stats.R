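test_that("paired t matches the closed form and the stats::t.test oracle", {
  res <- paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$t, -2 / (1 / sqrt(3)), tolerance = 1e-9)  # -3.4641
  expect_identical(res$df, 2L)
  # oracle comparison on random fixtures
  set.seed(40)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(12, 0.3)
    ours <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  # permutation oracle: two-sided p consistent in order of magnitude
  set.seed(41)
  x <- rnorm(10); y <- x + rnorm(10, 1)
  pperm <- local({
    d <- x - y
    obs <- abs(mean(d))
    mean(replicate(4000, {
      s <- sample(c(-1, 1), 10, replace = TRUE)
      abs(mean(d * s)) >= obs - 1e-12
    }))
  })
  expect_lt(abs(paired_t(x, y)$p - pperm), 0.05)
  expect_error(paired_t(1:5, 1:5), "zero-variance")
  # Cohen's d pooled-condition convention from raw data and summaries
  expect_equal(paired_t(x, y)$d,
               cohens_d_from_summary(mean(x), sd(x), mean(y), sd(y)),
               tolerance = 1e-12)
})

test_that("repeated-measures ANOVA matches sums-of-squares oracles", {
  set.seed(42)
  Y <- matrix(rnorm(15), 5, 3) + outer(rnorm(5), rep(1, 3))
  res <- rm_anova_one_way(Y)
  # explicit sums-of-squares oracle
  grand <- mean(Y)
  ss_eff <- 5 * sum((colMeans(Y) - grand)^2)
  ss_sub <- 3 * sum((rowMeans(Y) - grand)^2)
  ss_err <- sum((Y - grand)^2) - ss_eff - ss_sub
  expect_equal(res$F, (ss_eff / 2) / (ss_err / 8), tolerance = 1e-9)
  expect_equal(res$partial_eta_sq, ss_eff / (ss_eff + ss_err),
               tolerance = 1e-9)
  # aov oracle
  df <- data.frame(y = as.vector(Y),
                   subj = factor(rep(1:5, 3)),
                   lvl = factor(rep(1:3, each = 5)))
  av <- summary(stats::aov(y ~ lvl + Error(subj), data = df))
  Ftab <- av[["Error: Within"]][[1]]
  expect_equal(res$F, Ftab["lvl", "F value"], tolerance = 1e-9)
  expect_equal(res$p, Ftab["lvl", "Pr(>F)"], tolerance = 1e-9)
  # two-level identity: F = (paired t)^2
  Y2 <- Y[, 1:2]
  expect_equal(rm_anova_one_way(Y2)$F,
               paired_t(Y2[, 1], Y2[, 2])$t^2, tolerance = 1e-9)
  expect_equal(rm_anova_one_way(Y2)$p,
               paired_t(Y2[, 1], Y2[, 2])$p, tolerance = 1e-9)
  # degenerate: identical columns
  Yc <- matrix(rnorm(5), 5, 3)
  expect_equal(rm_anova_one_way(Yc)$F, 0)
  expect_error(rm_anova_one_way(cbind(Y, NA)), "complete")
})

test_that("Fisher PLSD protects on the omnibus and uses the error term", {
  set.seed(43)
  # null fixture: protection withholds pairwise p-values
  repeat {
    Y0 <- matrix(rnorm(18), 6, 3)
    if (rm_anova_one_way(Y0)$p > 0.3) break
  }
  r0 <- fisher_plsd(Y0)
  expect_false(any(r0$protected))
  expect_true(all(is.na(r0$p)))
  # strong-effect fixture
  Y <- matrix(rnorm(24), 8, 3)
  Y[, 3] <- Y[, 3] + 3  # deviant level
  r <- fisher_plsd(Y, pairs = cbind(c(1, 1, 2), c(2, 3, 3)))
  expect_true(all(r$protected))
  om <- attr(r, "omnibus")
  se <- sqrt(2 * om$ms_error / 8)
  expect_equal(r$t[1], (mean(Y[, 1]) - mean(Y[, 2])) / se,
               tolerance = 1e-9)
  expect_identical(unique(r$df), om$df_error)
  # pairs against the deviant level carry the smallest p-values
  expect_true(max(r$p[2:3]) < r$p[1])
  # 2-level case: PLSD p equals the paired ANOVA p
  Y2 <- Y[, 1:2]
  Y2[, 2] <- Y2[, 2] + 2
  r2 <- fisher_plsd(Y2, pairs = cbind(1, 2))
  expect_equal(r2$p[1], rm_anova_one_way(Y2)$p, tolerance = 1e-9)
})

test_that("Pearson correlation categorizes strength by |R|", {
  x <- rnorm(20)
  res <- pearson_cor(x, x)
  expect_equal(res$R, 1)
  expect_identical(res$strength, "strong")
  # constructed orthogonal vector
  x0 <- x - mean(x)
  y <- rnorm(20)
  y0 <- (y - mean(y)) - x0 * sum(x0 * (y - mean(y))) / sum(x0^2)
  expect_lt(abs(pearson_cor(x0, y0)$R), 1e-12)
  # moderate-strength fixture by rotation: R = 0.54 exactly
  set.seed(44)
  a <- scale(rnorm(50)); b <- scale(resid(lm(rnorm(50) ~ a)))
  target <- 0.54
  y54 <- target * a + sqrt(1 - target^2) * b
  r54 <- pearson_cor(as.numeric(a), as.numeric(y54))
  expect_equal(r54$R, 0.54, tolerance = 1e-9)
  expect_identical(r54$strength, "moderate")
  # oracle comparison
  ct <- cor.test(as.numeric(a), as.numeric(y54))
  expect_equal(r54$p, ct$p.value, tolerance = 1e-9)
})

test_that("BH step-up matches the definition and p.adjust oracle", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$p_adj, rep(0.04, 4), tolerance = 1e-12)
  expect_equal(fdr_bh(0.37)$p_adj, 0.37)
  set.seed(45)
  for (i in 1:5) {
    p <- runif(25)^2
    ours <- fdr_bh(p)$p_adj
    expect_equal(ours, p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  # monotonicity: raising any raw p never increases rejections
  set.seed(46)
  p <- runif(10, 0, 0.2)
  base_rej <- sum(fdr_bh(p)$reject)
  for (i in 1:10) {
    p2 <- p
    p2[i] <- min(1, p2[i] * 3)
    expect_lte(sum(fdr_bh(p2)$reject), base_rej)
  }
})

test_that("electrode-wise contrasts localize effects and control the null", {
  lay <- make_layout()
  set.seed(47)
  n <- 14
  mk_table <- function(effect_channel = NULL, delta = 0) {
    rows <- list()
    for (cond in c("low", "high")) {
      base <- matrix(rnorm(n * 31, 10, 1), n, 31)
      if (cond == "high" && !is.null(effect_channel)) {
        base[, effect_channel] <- base[, effect_channel] + delta
      }
      rows[[cond]] <- data.frame(
        subject = rep(seq_len(n), 31),
        condition = cond, block = 1,
        channel = rep(lay$names, each = n),
        band = "theta", power = as.vector(base))
    }
    do.call(rbind, rows)
  }
  # planted single-channel effect carries the maximal |t|
  tb <- mk_table(effect_channel = 5, delta = 3)
  res <- electrode_wise_contrast(tb, "theta")
  expect_identical(res$by_channel$channel[which.max(abs(res$by_channel$t))],
                   lay$names[5])
  expect_gte(res$n_sig_positive, 1)
  # null tables: average rejections stay near zero
  rej <- vapply(1:20, function(i) {
    electrode_wise_contrast(mk_table(), "theta")$n_significant
  }, 0)
  expect_lte(mean(rej), 1)
})
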