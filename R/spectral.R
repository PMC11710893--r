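#' Classical EEG frequency bands
#'
#' Default band edges: delta 0.5-3 Hz, theta 4-7 Hz, alpha 8-13 Hz,
#' beta 14-30 Hz. Edges are inclusive on both ends when bins are selected.
#' Note that with a 1-40 Hz analysis band-pass the effective delta content
#' starts at 1 Hz; the band definition is kept at its conventional 0.5 Hz
#' lower edge regardless.
#'
#' @return A data.frame with columns `band`, `f_lo`, `f_hi`.
#' @export
default_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta"),
             f_lo = c(0.5, 4, 8, 14),
             f_hi = c(3, 7, 13, 30),
             stringsAsFactors = FALSE)
}

#' Periodogram of an epoch set
#'
#' Unwindowed (rectangular) periodogram per epoch and channel:
#' `P(k) = |X(k)|^2 / N` with `X` the raw DFT of the `N`-sample epoch.
#' All `N` DFT bins are retained so that Parseval's identity
#' `mean(x^2) = sum(P) / N` holds exactly.
#'
#' @param epochs An `eeg_epochs` object.
#' @return A `spectral_estimate`: list with `P` (epoch x channel x
#'   frequency array, microvolts squared), `freqs` (bin frequencies
#'   `0 .. (N-1) * fs / N`), `N`, `fs`.
#' @export
periodogram <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$epochs)
  n_ep <- d[1]; N <- d[2]; nch <- d[3]
  if (n_ep < 1) stop("no epochs")
  P <- array(NA_real_, dim = c(n_ep, nch, N))
  for (i in seq_len(n_ep)) {
    X <- stats::mvfft(epochs$epochs[i, , ])   # N x nch DFT
    P[i, , ] <- t(Mod(X)^2 / N)
  }
  structure(list(P = P, freqs = (seq_len(N) - 1) * epochs$fs / N,
                 N = N, fs = epochs$fs, layout = epochs$layout,
                 meta = epochs$meta),
            class = "spectral_estimate")
}

#' Band-averaged power
#'
#' For each band, the mean of `P(k)` over the non-negative-frequency bins
#' with `f_lo <= freq <= f_hi` (inclusive), then the arithmetic mean across
#' epochs. Returns one row per channel and band.
#'
#' @param spec A `spectral_estimate` from [periodogram()].
#' @param bands A band data.frame as from [default_bands()].
#' @return A data.frame (`band_power_table`) with columns `subject`,
#'   `condition`, `block`, `channel`, `band`, `power` (microvolts squared).
#'   Metadata columns are filled from the estimate's `meta` (NA when
#'   absent).
#' @export
band_average <- function(spec, bands = default_bands()) {
  stopifnot(inherits(spec, "spectral_estimate"))
  nyq <- spec$fs / 2
  ch_names <- if (!is.null(spec$layout)) spec$layout$names else
    paste0("ch", seq_len(dim(spec$P)[2]))
  meta_or <- function(field) {
    v <- spec$meta[[field]]
    if (is.null(v)) NA else v
  }
  rows <- list()
  for (b in seq_len(nrow(bands))) {
    sel <- spec$freqs >= bands$f_lo[b] & spec$freqs <= bands$f_hi[b] &
      spec$freqs <= nyq
    if (!any(sel))
      stop(sprintf("band '%s' (%g-%g Hz) contains no DFT bins at %g Hz resolution",
                   bands$band[b], bands$f_lo[b], bands$f_hi[b],
                   spec$fs / spec$N))
    # mean over bins then over epochs (arithmetic means commute)
    pw <- apply(spec$P[, , sel, drop = FALSE], 2, mean)
    rows[[b]] <- data.frame(subject = meta_or("subject"),
                            condition = meta_or("condition"),
                            block = meta_or("block"),
                            channel = ch_names,
                            band = bands$band[b],
                            power = pw,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("band_power_table", "data.frame")
  out
}

#' Total average band power
#'
#' Unweighted mean of band power across all channels (and blocks, when the
#' table holds several) per subject, condition and band — the "total
#' average power" summary used for condition contrasts.
#'
#' @param table A `band_power_table` (rows may span several subjects,
#'   conditions and blocks).
#' @return A data.frame with columns `subject`, `condition`, `band`,
#'   `power`.
#' @export
total_average_power <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("channel", "band", "power") %in% names(table)))
  agg <- stats::aggregate(power ~ subject + condition + band,
                          data = as.data.frame(table), FUN = mean)
  agg[order(agg$subject, agg$condition, agg$band), , drop = FALSE]
}
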