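test_that("GFP is the per-sample population SD across channels", {
  expect_equal(compute_gfp(matrix(c(1, -1), 1, 2)), 1)
  expect_equal(compute_gfp(matrix(0, 1, 5)), 0)
  expect_equal(compute_gfp(matrix(c(1, 0, -1), 1, 3)), sqrt(2 / 3))
  # constant offsets do not contribute
  expect_equal(compute_gfp(matrix(c(11, 10, 9), 1, 3)), sqrt(2 / 3))
})

test_that("GFP peaks are strict interior local maxima", {
  expect_identical(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_length(find_gfp_peaks(1:10), 0)
  expect_length(find_gfp_peaks(c(1, 1, 1, 1)), 0)
  # rectified-oscillation oracle: |sin| at 10 Hz has two peaks per cycle;
  # count by brute force over 1 s at 250 Hz
  fs <- 250
  g <- abs(sin(2 * pi * 10 * (0:(fs - 1)) / fs))
  npk <- length(find_gfp_peaks(g))
  expect_gte(npk, 18)
  expect_lte(npk, 21)
})

test_that("modified k-means recovers planted clusters and small optima", {
  # zero-noise fixed point: 4 orthogonal maps repeated with random signs
  nch <- 8
  base <- diag(1, 4) %x% t(c(1, -1))  # 4 orthogonal zero-mean maps
  set.seed(10)
  M <- base[rep(1:4, each = 10), ] * sample(c(-1, 1), 40, replace = TRUE)
  km <- modified_kmeans(M, k = 4, n_restarts = 10, seed = 1)
  expect_equal(km$objective, 1, tolerance = 1e-12)
  cc <- abs(km$templates$templates %*% t(base / sqrt(rowSums(base^2))))
  expect_equal(sort(apply(cc, 1, max)), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # k = 1: template equals the dominant eigenvector of the scatter matrix
  M1 <- rand_maps(20, 6, seed = 11)
  km1 <- modified_kmeans(M1, k = 1, n_restarts = 3, seed = 2)
  Mn <- M1 / sqrt(rowSums(M1^2))
  ev <- eigen(crossprod(Mn), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(km1$templates$templates[1, ] * ev)), 1,
               tolerance = 1e-9)
  # brute-force oracle: global optimum on an 8-map, 4-channel, k = 2
  # instance
  M2 <- rand_maps(8, 4, seed = 12)
  km2 <- modified_kmeans(M2, k = 2, n_restarts = 50, seed = 3)
  expect_equal(km2$objective, brute_force_kmeans(M2, 2), tolerance = 1e-9)
  # error contract
  expect_error(modified_kmeans(M2, k = 9, n_restarts = 1, seed = 1),
               "exceeds")
  # determinism
  kma <- modified_kmeans(M2, k = 2, n_restarts = 5, seed = 4)
  kmb <- modified_kmeans(M2, k = 2, n_restarts = 5, seed = 4)
  expect_identical(kma$templates$templates, kmb$templates$templates)
})

test_that("grand-mean aggregation aligns permutations and polarity", {
  set.seed(13)
  common <- rand_maps(3, 10, seed = 14)
  common <- common / sqrt(rowSums(common^2))
  mk <- function(M) microstate_templates(M, labels = LETTERS[1:3])
  # identical sets under shuffled label order reproduce the common maps
  sets <- list(mk(common), mk(common[c(2, 3, 1), ]),
               mk(common[c(3, 1, 2), ]))
  gm <- aggregate_grand_mean(sets)
  cc <- abs(gm$templates %*% t(common))
  expect_equal(sort(apply(cc, 1, max)), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # polarity invariance: sign-flipping one subject changes nothing
  sets2 <- list(mk(common), mk(-common), mk(common))
  gm2 <- aggregate_grand_mean(sets2)
  expect_equal(abs(diag(gm2$templates %*% t(gm$templates))),
               rep(1, 3), tolerance = 1e-9, ignore_attr = TRUE)
  # brute-force oracle at k = 2: exhaustive permutation x polarity search
  s1 <- rand_maps(2, 6, seed = 15); s2 <- rand_maps(2, 6, seed = 16)
  s3 <- rand_maps(2, 6, seed = 17)
  norm2 <- function(M) M / sqrt(rowSums(M^2))
  s1 <- norm2(s1); s2 <- norm2(s2); s3 <- norm2(s3)
  gm3 <- aggregate_grand_mean(list(
    microstate_templates(s1, labels = c("A", "B")),
    microstate_templates(s2, labels = c("A", "B")),
    microstate_templates(s3, labels = c("A", "B"))))
  # exhaustive: all 2 perms x 4 sign patterns per subject relative to s1
  best <- -Inf
  for (p2 in list(1:2, 2:1)) for (p3 in list(1:2, 2:1)) {
    for (g2 in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      for (g3 in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
        m <- (s1 + s2[p2, ] * g2 + s3[p3, ] * g3) / 3
        m <- m - rowMeans(m)
        score <- sum(sqrt(rowSums(m^2)))  # alignment quality: mean-map norm
        if (score > best) best <- score
      }
    }
  }
  aligned_score <- local({
    # recompute the package alignment's mean-map norm via projection
    cc1 <- abs(gm3$templates %*% t(s1))
    sum1 <- 0
    for (s in list(s1, s2, s3)) {
      cc <- gm3$templates %*% t(s)
      # align each subject to the grand templates greedily over 2 perms
      sc1 <- abs(cc[1, 1]) + abs(cc[2, 2])
      sc2 <- abs(cc[1, 2]) + abs(cc[2, 1])
      sum1 <- sum1 + max(sc1, sc2)
    }
    sum1
  })
  # the aligned mean-map norm equals the exhaustive best (both measure
  # total |corr| of subjects to the consensus, scaled by 3)
  expect_equal(aligned_score / 3, best, tolerance = 1e-6)
})

test_that("canonical labeling recovers permutations", {
  lay <- make_layout()
  canon <- make_canonical_templates(lay)
  relab <- label_canonical(canon, canon)
  expect_identical(relab$labels, canon$labels)
  expect_equal(unname(attr(relab, "match_quality")), rep(1, 4),
               tolerance = 1e-12)
  # permuted input: inverse permutation recovered
  perm <- c(3, 1, 4, 2)
  shuffled <- microstate_templates(canon$templates[perm, ],
                                   labels = LETTERS[1:4])
  relab2 <- label_canonical(shuffled, canon)
  expect_equal(unname(relab2$templates), unname(canon$templates),
               tolerance = 1e-12)
  # sign flips do not disturb labeling
  flipped <- microstate_templates(canon$templates * c(-1, 1, -1, 1),
                                  labels = LETTERS[1:4])
  relab3 <- label_canonical(flipped, canon)
  expect_equal(abs(unname(relab3$templates)), abs(unname(canon$templates)),
               tolerance = 1e-12)
})

test_that("back-fitting labels by maximal absolute spatial correlation", {
  lay <- make_layout()
  canon <- make_canonical_templates(lay)
  Tn <- canon$templates
  X <- rbind(5 * Tn["B", ],          # scaled template B
             -3 * Tn["C", ],         # negated template C
             rep(0, 31),             # zero-variance sample
             2 * Tn["A", ])
  rec <- eeg_recording(X, 250, lay)
  seg <- backfit(rec, canon)
  expect_identical(seg$labels[1:2], c(2L, 3L))
  expect_equal(seg$abs_corr[1:2], c(1, 1), tolerance = 1e-9)
  # zero-variance sample carries the previous label
  expect_identical(seg$labels[3], 3L)
  expect_identical(seg$labels[4], 1L)
  # leading zero-variance sample takes the nearest valid label
  rec2 <- eeg_recording(rbind(rep(0, 31), 5 * Tn["D", ]), 250, lay)
  expect_identical(backfit(rec2, canon)$labels, c(4L, 4L))
  # random samples: winner matches the direct correlation formula
  set.seed(18)
  Xr <- matrix(rnorm(31 * 50), 50, 31)
  segr <- backfit(eeg_recording(Xr, 250, lay), canon)
  oracle <- apply(Xr, 1, function(x)
    which.max(abs(apply(Tn, 1, function(tm) cor(x, tm)))))
  expect_equal(segr$labels, unname(oracle))
})

test_that("temporal parameters match hand-computed run statistics", {
  seg <- seg_from_labels(c(1, 1, 2, 2, 2, 2, 1, 1), fs = 4, k = 2)
  tp <- temporal_parameters(seg)
  expect_equal(tp$duration_ms, c(500, 1000))
  expect_equal(tp$occurrence_per_s, c(1.0, 0.5))
  expect_equal(tp$coverage, c(0.5, 0.5))
  # all-one-class sequence
  seg1 <- seg_from_labels(rep(1, 12), fs = 4, k = 2)
  tp1 <- temporal_parameters(seg1)
  expect_equal(tp1$coverage, c(1, 0))
  expect_equal(tp1$occurrence_per_s[1], 1 / 3)
  expect_false(tp1$present[2])
  expect_equal(tp1$duration_ms[2], 0)
  # boundary cut: a run spanning a boundary splits into two segments
  segb <- seg_from_labels(c(1, 1, 1, 1), fs = 4, k = 1,
                          boundaries = c(1L, 3L))
  tpb <- temporal_parameters(segb)
  expect_equal(tpb$duration_ms[1], 500)
  expect_equal(tpb$occurrence_per_s[1], 2)
})

test_that("GEV matches its definition on constructed recordings", {
  lay <- make_layout()
  canon <- make_canonical_templates(lay)
  Tn <- canon$templates
  # every sample a scaled template: GEV = 1
  set.seed(19)
  scales <- runif(40, 0.5, 3)
  labs <- sample(1:4, 40, replace = TRUE)
  X <- Tn[labs, ] * scales
  rec <- eeg_recording(X, 250, lay)
  seg <- backfit(rec, canon)
  expect_equal(compute_gev(seg, rec, canon), 1, tolerance = 1e-9)
  # 5-sample hand-computed oracle
  X5 <- rbind(2 * Tn["A", ], Tn["B", ] + 0.3 * Tn["C", ], -Tn["C", ],
              0.5 * Tn["D", ] - 0.2 * Tn["A", ], 1.5 * Tn["B", ])
  rec5 <- eeg_recording(X5, 250, lay)
  seg5 <- backfit(rec5, canon)
  g <- compute_gfp(rec5)
  corr <- vapply(1:5, function(i)
    abs(cor(X5[i, ], Tn[seg5$labels[i], ])), 0)
  expect_equal(compute_gev(seg5, rec5, canon),
               sum((g * corr)^2) / sum(g^2), tolerance = 1e-9)
})

test_that("transition probabilities count segment-level changes", {
  seg <- seg_from_labels(c(1, 1, 2, 1, 1, 2, 2), fs = 4, k = 2)
  P <- transition_probabilities(seg)
  expect_equal(unclass(P)[1, 2], 1)
  expect_equal(unclass(P)[2, 1], 1)
  expect_equal(diag(unclass(P)), c(0, 0), ignore_attr = TRUE)
  # A,B,C,A: each observed transition has probability 1 from its source
  seg3 <- seg_from_labels(c(1, 2, 3, 1), fs = 4, k = 3)
  P3 <- unclass(transition_probabilities(seg3))
  expect_equal(P3[1, 2], 1)
  expect_equal(P3[2, 3], 1)
  expect_equal(P3[3, 1], 1)
  # rows sum to one (or are flagged NA when the class never departs)
  rs <- rowSums(P3)
  expect_equal(rs[is.finite(rs)], rep(1, sum(is.finite(rs))),
               ignore_attr = TRUE)
  # boundaries suppress cross-join transitions
  segb <- seg_from_labels(c(1, 1, 2, 2), fs = 4, k = 2,
                          boundaries = c(1L, 3L))
  expect_error(transition_probabilities(segb), "at least 2 segments")
})

test_that("segmentation is polarity- and scale-invariant", {
  cfg <- pure_state_config(duration_s = 8, snr_db = 20, seed = 21)
  out <- synthesize_recording(cfg)
  rec <- out$rec
  canon <- cfg$templates
  seg <- backfit(rec, canon)
  neg <- eeg_recording(-rec$data, rec$fs, rec$layout)
  segn <- backfit(neg, canon)
  expect_identical(segn$labels, seg$labels)
  expect_equal(segn$abs_corr, seg$abs_corr, tolerance = 1e-12)
  expect_equal(compute_gev(segn, neg, canon),
               compute_gev(seg, rec, canon), tolerance = 1e-12)
  sc <- eeg_recording(2.5 * rec$data, rec$fs, rec$layout)
  segs <- backfit(sc, canon)
  expect_identical(segs$labels, seg$labels)
  expect_equal(segs$gfp, 2.5 * seg$gfp, tolerance = 1e-9)
  expect_equal(compute_gev(segs, sc, canon),
               compute_gev(seg, rec, canon), tolerance = 1e-12)
  # parameter identities: coverages sum to 1; duration x occurrence =
  # coverage up to boundary quantization
  tp <- temporal_parameters(seg)
  expect_equal(sum(tp$coverage), 1, tolerance = 1e-9)
  expect_equal(tp$duration_ms / 1000 * tp$occurrence_per_s, tp$coverage,
               tolerance = 1e-9)
  # transitions of the planted and recovered sequences: rows sum to 1
  P <- unclass(transition_probabilities(seg))
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("GEV is non-decreasing in k on a fixed recording", {
  cfg <- pure_state_config(duration_s = 6, snr_db = 5, seed = 22)
  out <- synthesize_recording(cfg)
  pm <- extract_gfp_peak_maps(out$rec)
  gevs <- vapply(1:6, function(k)
    modified_kmeans(pm, k = k, n_restarts = 15, seed = 30 + k)$gev, 0)
  expect_true(all(diff(gevs) > -1e-6))
})

test_that("peak-domain back-fitting extends peak labels to midpoints", {
  lay <- make_layout()
  canon <- make_canonical_templates(lay)
  Tn <- canon$templates
  # planted: three dwells (A, B, C) with one GFP peak each at 2, 5, 8
  amp <- c(1, 3, 1, 1, 4, 1, 1, 2, 1)
  planted <- rep(c(1L, 2L, 3L), each = 3)
  X <- Tn[planted, ] * amp
  rec <- eeg_recording(X, 250, lay)
  seg <- backfit(rec, canon, fit_at = "peaks")
  expect_identical(seg$labels, planted)
  # at realistic noise, peak fitting recovers run structure far better
  # than per-sample fitting: durations stay near the planted dwell means
  # instead of fragmenting
  cfg <- pure_state_config(duration_s = 15, snr_db = 5, seed = 23)
  out <- synthesize_recording(cfg)
  sa <- backfit(out$rec, cfg$templates, fit_at = "all")
  sp <- backfit(out$rec, cfg$templates, fit_at = "peaks")
  dur <- function(s) mean(temporal_parameters(s)$duration_ms)
  planted <- mean(cfg$mean_durations_ms)
  expect_lt(abs(dur(sp) - planted), abs(dur(sa) - planted))
  # and segments are far less fragmented
  expect_lt(length(rle(sp$labels)$values),
            0.8 * length(rle(sa$labels)$values))
})
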