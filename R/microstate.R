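# Microstate analysis: GFP, GFP-peak map extraction, polarity-invariant
# modified k-means, two-level (subject -> grand mean) clustering, canonical
# labeling, back-fitting, temporal parameters, GEV and transition syntax.
#
# Spatial correlation between two average-referenced topographies reduces to
# the normalized dot product; polarity invariance means similarity is the
# squared (or absolute) correlation throughout.

#' Global field power
#'
#' GFP(t) is the population standard deviation of the voltage across
#' channels at sample t (for average-referenced data, the RMS across
#' channels).
#'
#' @param rec An `eeg_recording` (or samples x channels matrix).
#' @return Numeric vector of per-sample GFP values.
#' @export
compute_gfp <- function(rec) {
  X <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  mu <- rowMeans(X)
  sqrt(rowMeans((X - mu)^2))
}

#' Strict local maxima of a GFP series
#'
#' Indices i with `gfp[i-1] < gfp[i] > gfp[i+1]`; endpoints are never
#' peaks.
#'
#' @param gfp Numeric vector (length >= 3).
#' @return Integer vector of peak indices.
#' @export
find_gfp_peaks <- function(gfp) {
  n <- length(gfp)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[gfp[i] > gfp[i - 1] & gfp[i] > gfp[i + 1]]
}

#' Extract GFP-peak topographies
#'
#' Pulls the scalp maps at the strict local maxima of the GFP series: the
#' high signal-to-noise topographies that enter clustering.
#'
#' @param rec An `eeg_recording` (average-referenced).
#' @return A `topography_set`: list with `maps` (map x channel matrix),
#'   `gfp_values`, `peak_index`, `source` metadata.
#' @export
extract_gfp_peak_maps <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  g <- compute_gfp(rec)
  pk <- find_gfp_peaks(g)
  if (length(pk) == 0) stop("no GFP peaks found")
  structure(list(maps = rec$data[pk, , drop = FALSE], gfp_values = g[pk],
                 peak_index = pk, source = rec$meta),
            class = "topography_set")
}

# row-normalize average-referenced maps; drops zero-variance rows
normalize_maps <- function(M) {
  M <- M - rowMeans(M)
  nrm <- sqrt(rowSums(M^2))
  keep <- nrm > 0
  list(maps = M[keep, , drop = FALSE] / nrm[keep], keep = keep)
}

# mean squared spatial correlation of normalized maps to their assigned
# templates -- the clustering objective
kmeans_objective <- function(Mn, Tn, assign) {
  cc <- Mn %*% t(Tn)
  mean(cc[cbind(seq_len(nrow(Mn)), assign)]^2)
}

# dominant eigenvector of t(M) %*% M for the maps in one cluster
dominant_map <- function(Mn) {
  S <- crossprod(Mn)
  ev <- eigen(S, symmetric = TRUE)
  v <- ev$vectors[, 1]
  v - mean(v)  # stays (numerically) zero-mean; re-centred for safety
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' The classical modified k-means for microstates: maps are normalized;
#' the assignment step labels each map by its maximum squared spatial
#' correlation to the templates; the update step replaces each template by
#' the dominant eigenvector of the scatter matrix of its assigned maps
#' (the polarity-invariant mean map). Iterates until the objective (mean
#' squared correlation of maps to assigned templates) changes by less than
#' `tol`, keeps the best of `n_restarts` random initializations.
#' Deterministic given `seed`. An emptied cluster is re-seeded from the
#' currently worst-fit map.
#'
#' @param maps A `topography_set` (or map x channel matrix).
#' @param k Number of classes (default 4).
#' @param n_restarts Random restarts (default 50).
#' @param seed Integer RNG seed.
#' @param tol Convergence tolerance on the objective (default 1e-6).
#' @param max_iter Maximum iterations per restart (default 100).
#' @return A list with `templates` (a `microstate_templates`),
#'   `assignments` (per-map class index), `objective` (mean squared
#'   correlation) and `gev` (GFP-weighted explained variance of the
#'   clustered maps).
#' @export
modified_kmeans <- function(maps, k = 4, n_restarts = 50, seed = 1,
                            tol = 1e-6, max_iter = 100) {
  if (inherits(maps, "topography_set")) {
    M <- maps$maps; w <- maps$gfp_values
  } else {
    M <- as.matrix(maps); w <- NULL
  }
  nm <- normalize_maps(M)
  Mn <- nm$maps
  n <- nrow(Mn)
  if (k > n) stop(sprintf("k = %d exceeds number of maps (%d)", k, n))
  if (is.null(w)) w <- compute_gfp(M)[nm$keep] else w <- w[nm$keep]

  one_run <- function() {
    Tn <- Mn[sample.int(n, k), , drop = FALSE]
    obj <- -Inf
    assign <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      cc2 <- (Mn %*% t(Tn))^2
      assign <- max.col(cc2, ties.method = "first")
      # re-seed empty clusters from the worst-fit map
      best <- cc2[cbind(seq_len(n), assign)]
      for (j in seq_len(k)) {
        if (!any(assign == j)) {
          worst <- which.min(best)
          Tn[j, ] <- Mn[worst, ]
          assign[worst] <- j
          best[worst] <- 1
        }
      }
      for (j in seq_len(k)) {
        v <- dominant_map(Mn[assign == j, , drop = FALSE])
        Tn[j, ] <- v / sqrt(sum(v^2))
      }
      cc2 <- (Mn %*% t(Tn))^2
      assign <- max.col(cc2, ties.method = "first")
      obj_new <- mean(cc2[cbind(seq_len(n), assign)])
      if (obj_new - obj < tol) { obj <- obj_new; break }
      obj <- obj_new
    }
    list(Tn = Tn, assign = assign, obj = obj)
  }

  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- one_run()
    if (is.null(best) || run$obj > best$obj) best <- run
  }
  cc <- Mn %*% t(best$Tn)
  corr_best <- abs(cc[cbind(seq_len(n), best$assign)])
  gev <- sum((w * corr_best)^2) / sum(w^2)
  tmpl <- microstate_templates(best$Tn, labels = LETTERS[seq_len(k)],
                               level = "subject",
                               channel_names = colnames(M))
  list(templates = tmpl, assignments = best$assign,
       objective = best$obj, gev = gev)
}

# all permutations of 1..n (n small)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# best label permutation of rows of A onto rows of B by total |corr|
# (exhaustive over k! -- k is 4 here)
best_permutation <- function(A, B) {
  k <- nrow(A)
  cc <- abs(A %*% t(B))  # unit-norm zero-mean rows assumed
  perms <- permutations(k)
  scores <- apply(perms, 1, function(p) sum(cc[cbind(p, seq_len(k))]))
  p <- perms[which.max(scores), ]
  list(perm = p, score = max(scores),
       match = cc[cbind(p, seq_len(k))])
}

#' Grand-mean clustering of subject template sets
#'
#' Aligns each subject's k maps to a common labeling by exhaustive
#' permutation search (maximizing total absolute spatial correlation to the
#' evolving mean maps, with polarity fixed by the sign of the correlation)
#' and averages the aligned maps; iterates alignment and averaging until
#' the assignment stabilizes. Polarity-invariant: sign-flipped subject maps
#' give identical grand templates (up to overall sign).
#'
#' @param subject_sets List of `microstate_templates`, all with the same k
#'   and channel count.
#' @param seed Integer seed (initial reference = first subject's set).
#' @param max_iter Maximum alignment rounds (default 20).
#' @return A `microstate_templates` with level "grand_mean".
#' @export
aggregate_grand_mean <- function(subject_sets, seed = 1, max_iter = 20) {
  stopifnot(length(subject_sets) >= 1)
  mats <- lapply(subject_sets, function(s) s$templates)
  k <- nrow(mats[[1]])
  stopifnot(all(vapply(mats, nrow, 0L) == k))
  ref <- mats[[1]]
  prev_perms <- NULL
  for (it in seq_len(max_iter)) {
    aligned <- vector("list", length(mats))
    perms <- matrix(0L, length(mats), k)
    for (s in seq_along(mats)) {
      bp <- best_permutation(mats[[s]], ref)
      A <- mats[[s]][bp$perm, , drop = FALSE]
      # fix polarity toward the reference
      sg <- sign(rowSums(A * ref))
      sg[sg == 0] <- 1
      aligned[[s]] <- A * sg
      perms[s, ] <- bp$perm
    }
    mean_maps <- Reduce(`+`, aligned) / length(aligned)
    mean_maps <- mean_maps - rowMeans(mean_maps)
    mean_maps <- mean_maps / sqrt(rowSums(mean_maps^2))
    if (!is.null(prev_perms) && identical(prev_perms, perms)) {
      ref <- mean_maps
      break
    }
    prev_perms <- perms
    ref <- mean_maps
  }
  microstate_templates(ref, labels = LETTERS[seq_len(k)],
                       level = "grand_mean",
                       channel_names = colnames(mats[[1]]))
}

#' Canonical A-D labeling of a template set
#'
#' Finds the one-to-one assignment of templates onto the canonical maps
#' maximizing total absolute spatial correlation (exhaustive over the k!
#' permutations) and relabels the set accordingly.
#'
#' @param templates A `microstate_templates`.
#' @param canon The canonical reference set (same channel space), e.g.
#'   [make_canonical_templates()] output.
#' @return The relabeled `microstate_templates`; attribute `match_quality`
#'   holds the per-class absolute correlation to the canonical map.
#' @export
label_canonical <- function(templates, canon) {
  stopifnot(ncol(templates$templates) == ncol(canon$templates))
  bp <- best_permutation(templates$templates, canon$templates)
  maps <- templates$templates[bp$perm, , drop = FALSE]
  out <- microstate_templates(maps, labels = canon$labels,
                              level = templates$level,
                              channel_names = colnames(canon$templates))
  attr(out, "match_quality") <- stats::setNames(bp$match, canon$labels)
  out
}

#' Back-fit templates to a recording
#'
#' Converts the recording into a per-sample microstate label series by
#' absolute Pearson spatial correlation to the templates (polarity
#' ignored). Two fitting domains are supported:
#' \describe{
#'   \item{`"all"`}{every sample is labeled by its own maximal
#'     |correlation|. Zero-variance samples carry the previous sample's
#'     label (the first such sample takes the label of the nearest valid
#'     one); ties break toward the lowest class index.}
#'   \item{`"peaks"`}{only the GFP peaks — the high signal-to-noise
#'     topographies — are labeled, and each peak's label is extended to
#'     the midpoints between neighboring peaks. This is how microstate
#'     toolboxes implement peak-domain back-fitting; it is far more
#'     robust to sensor noise, which otherwise fragments the label series
#'     with spurious single-sample states.}
#' }
#'
#' @param rec An `eeg_recording` (average-referenced).
#' @param templates A canonical-labeled `microstate_templates`.
#' @param fit_at `"all"` (default) or `"peaks"`.
#' @return A `segmentation` object: list with `labels` (per-sample class
#'   index, 1-based), `abs_corr` (per-sample |correlation| to the
#'   assigned template), `gfp`, `fs`, `class_labels`, `boundaries`
#'   (epoch-join sample starts, default just 1).
#' @export
backfit <- function(rec, templates, fit_at = c("all", "peaks")) {
  stopifnot(inherits(rec, "eeg_recording"))
  fit_at <- match.arg(fit_at)
  X <- rec$data - rowMeans(rec$data)
  nrm <- sqrt(rowSums(X^2))
  Tn <- templates$templates               # unit-norm, zero-mean rows
  cc <- X %*% t(Tn)
  valid <- nrm > 0
  cc[valid, ] <- cc[valid, ] / nrm[valid]
  acc <- abs(cc)
  lab <- max.col(acc, ties.method = "first")
  if (fit_at == "peaks") {
    g <- compute_gfp(rec)
    pk <- find_gfp_peaks(g)
    if (length(pk) >= 2) {
      # extend each peak's label to the midpoints between peaks
      mids <- floor((pk[-1] + pk[-length(pk)]) / 2)
      starts <- c(1L, mids + 1L)
      ends <- c(mids, nrow(X))
      lab <- rep(lab[pk], ends - starts + 1L)
    }
  }
  bc <- acc[cbind(seq_len(nrow(X)), lab)]
  if (any(!valid)) {
    bc[!valid] <- 0
    if (fit_at == "all") {
      lab[!valid] <- NA_integer_
      lab <- carry_labels(lab)
      bc[!valid] <- 0
    }
  }
  structure(list(labels = lab, abs_corr = bc, gfp = compute_gfp(rec),
                 fs = rec$fs, class_labels = templates$labels,
                 boundaries = 1L),
            class = "segmentation")
}

# fill NA labels: carry forward; leading NAs take the first valid label
carry_labels <- function(lab) {
  valid <- which(!is.na(lab))
  if (length(valid) == 0) stop("no valid samples to label")
  if (valid[1] > 1) lab[seq_len(valid[1] - 1)] <- lab[valid[1]]
  for (i in which(is.na(lab))) lab[i] <- lab[i - 1]
  lab
}

# split a label sequence at boundaries into runs; returns data.frame of
# (class, length) run-length segments, never merging across boundaries
label_runs <- function(labels, boundaries = 1L) {
  bnd <- sort(unique(c(1L, boundaries, length(labels) + 1L)))
  segs <- list()
  for (i in seq_len(length(bnd) - 1)) {
    chunk <- labels[bnd[i]:(bnd[i + 1] - 1L)]
    r <- rle(chunk)
    segs[[i]] <- data.frame(class = r$values, len = r$lengths)
  }
  do.call(rbind, segs)
}

#' Microstate temporal parameters
#'
#' Maximal runs of identical labels are segments (runs are cut at epoch
#' boundaries and never span them). Per class: `duration_ms` = mean segment
#' length in ms, `occurrence_per_s` = segments per second,
#' `coverage` = fraction of samples. A class with no segments gets
#' duration 0 (flagged in `present`), occurrence 0, coverage 0.
#'
#' @param seg A `segmentation` object.
#' @return A `microstate_params` object: data.frame with one row per class
#'   (`class`, `duration_ms`, `occurrence_per_s`, `coverage`, `present`)
#'   and attribute `total_gev` when set by the caller.
#' @export
temporal_parameters <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  k <- length(seg$class_labels)
  runs <- label_runs(seg$labels, seg$boundaries)
  total_s <- length(seg$labels) / seg$fs
  out <- data.frame(class = seg$class_labels,
                    duration_ms = 0, occurrence_per_s = 0, coverage = 0,
                    present = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    rj <- runs$len[runs$class == j]
    if (length(rj) > 0) {
      out$duration_ms[j] <- mean(rj) / seg$fs * 1000
      out$occurrence_per_s[j] <- length(rj) / total_s
      out$coverage[j] <- sum(rj) / length(seg$labels)
      out$present[j] <- TRUE
    }
  }
  class(out) <- c("microstate_params", "data.frame")
  out
}

#' Global explained variance of a segmentation
#'
#' `GEV = sum_t (GFP(t) * corr(map_t, template_label(t)))^2 /
#' sum_t GFP(t)^2` with polarity-invariant spatial correlation.
#'
#' @param seg A `segmentation` from [backfit()].
#' @param rec The `eeg_recording` that was segmented.
#' @param templates The `microstate_templates` used.
#' @return GEV as a fraction in `[0, 1]`.
#' @export
compute_gev <- function(seg, rec, templates) {
  stopifnot(length(seg$labels) == nrow(rec$data))
  X <- rec$data - rowMeans(rec$data)
  nrm <- sqrt(rowSums(X^2))
  cc <- X %*% t(templates$templates)
  corr <- numeric(nrow(X))
  v <- nrm > 0
  corr[v] <- abs(cc[cbind(seq_len(nrow(X)), seg$labels)][v] / nrm[v])
  g <- seg$gfp
  sum((g * corr)^2) / sum(g^2)
}

#' Microstate transition probabilities
#'
#' Counts transitions between consecutive segments (segment resolution, so
#' self-transitions are impossible by construction; transitions are not
#' counted across epoch boundaries). `P[i, j]` is the fraction of
#' departures from class i that land in class j; a class with no departures
#' has an undefined row (all NA, flagged).
#'
#' @param seg A `segmentation` object.
#' @return A `transition_matrix`: k x k matrix with zero diagonal and
#'   attribute `counts`.
#' @export
transition_probabilities <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  k <- length(seg$class_labels)
  runs <- label_runs(seg$labels, seg$boundaries)
  counts <- matrix(0, k, k,
                   dimnames = list(seg$class_labels, seg$class_labels))
  bnd <- sort(unique(c(1L, seg$boundaries, length(seg$labels) + 1L)))
  # rebuild per-chunk run sequences to avoid cross-boundary pairs
  for (i in seq_len(length(bnd) - 1)) {
    r <- rle(seg$labels[bnd[i]:(bnd[i + 1] - 1L)])$values
    if (length(r) >= 2) {
      for (t in seq_len(length(r) - 1)) {
        counts[r[t], r[t + 1]] <- counts[r[t], r[t + 1]] + 1
      }
    }
  }
  if (sum(counts) < 1) stop("need at least 2 segments for transitions")
  P <- counts / rowSums(counts)
  P[rowSums(counts) == 0, ] <- NA_real_
  attr(P, "counts") <- counts
  class(P) <- c("transition_matrix", class(P))
  P
}
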