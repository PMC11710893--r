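# shared fixtures and independent oracles

# random average-referenced maps (rows) on nch channels
rand_maps <- function(n, nch, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n * nch), n, nch)
  M - rowMeans(M)
}

# brute-force polarity-invariant k-means optimum: enumerate all k^n
# assignments; per cluster the optimal template is the dominant
# eigenvector of the scatter of the normalized maps, contributing its top
# eigenvalue; objective = mean squared correlation (matches the package's
# clustering objective). Independent of the iterative implementation.
brute_force_kmeans <- function(M, k) {
  M <- M - rowMeans(M)
  Mn <- M / sqrt(rowSums(M^2))
  n <- nrow(Mn)
  best <- -Inf
  grid <- rep(list(seq_len(k)), n)
  assigns <- as.matrix(expand.grid(grid))
  for (r in seq_len(nrow(assigns))) {
    a <- assigns[r, ]
    if (length(unique(a)) < k) next
    tot <- 0
    for (j in seq_len(k)) {
      S <- crossprod(Mn[a == j, , drop = FALSE])
      tot <- tot + max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    }
    obj <- tot / n
    if (obj > best) best <- obj
  }
  best
}

# quick synthetic recording without background band activity (pure
# microstate signal + sensor noise), for recovery tests
pure_state_config <- function(duration_s, snr_db, seed, ...) {
  synthetic_config(duration_s = duration_s, snr_db = snr_db, seed = seed,
                   band_components = c(delta = 0, theta = 0, alpha = 0,
                                       beta = 0), ...)
}

# build an eeg_recording from a plain matrix on an n-channel toy layout
toy_recording <- function(data, fs = 250) {
  nch <- ncol(data)
  lay <- make_layout()
  stopifnot(nch == 31)
  eeg_recording(data, fs, lay)
}

# segmentation object from a bare label sequence (for parameter tests)
seg_from_labels <- function(labels, fs, k = max(labels),
                            boundaries = 1L) {
  structure(list(labels = as.integer(labels),
                 abs_corr = rep(1, length(labels)),
                 gfp = rep(1, length(labels)), fs = fs,
                 class_labels = LETTERS[seq_len(k)],
                 boundaries = as.integer(boundaries)),
            class = "segmentation")
}
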