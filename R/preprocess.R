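#' Resample a recording
#'
#' Anti-aliased polyphase resampling (upsample / windowed-sinc FIR /
#' downsample at the rational ratio `target_fs / fs`). Only downsampling is
#' supported; `target_fs == fs` returns the input unchanged. Output length
#' is `round(n * target_fs / fs)`.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target sampling frequency in Hz.
#' @return The resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs)
    stop("upsampling not supported: target_fs must be <= fs")
  if (target_fs == rec$fs) return(rec)
  r <- target_fs / rec$fs
  # rational approximation of the ratio
  den <- 1:1000
  err <- abs(r * den - round(r * den))
  M0 <- den[which(err < 1e-9)[1]]
  if (is.na(M0)) stop("resampling ratio is not a small rational")
  L <- round(r * M0)
  g <- gcd_int(L, M0)
  L <- L / g; M <- M0 / g
  out <- apply(rec$data, 2, function(col) resample_poly(col, L, M))
  eeg_recording(out, target_fs, rec$layout, rec$meta)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Band-pass plus notch filtering
#'
#' Zero-phase (forward-backward) filtering with a Butterworth high-pass at
#' `lo`, a Butterworth low-pass at `hi` (4 poles each), and a second-order
#' IIR notch at `notch`. Zero-phase filtering preserves microstate timing;
#' the forward-backward pass squares the magnitude response, so effective
#' attenuation is twice the single-pass value in dB.
#'
#' @param rec An `eeg_recording`.
#' @param lo,hi Band-pass edges in Hz (`0 < lo < hi < fs/2`).
#' @param notch Notch frequency in Hz, or `NULL` to skip.
#' @param order High/low-pass Butterworth order (default 4 each).
#' @return The filtered `eeg_recording`.
#' @export
filter_band_notch <- function(rec, lo = 1, hi = 40, notch = 50, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(lo > 0 && lo < hi && hi < rec$fs / 2))
    stop("invalid band: need 0 < lo < hi < fs/2")
  sos <- c(butter_sos(order, lo, rec$fs, "high"),
           butter_sos(order, hi, rec$fs, "low"))
  if (!is.null(notch)) {
    if (notch <= 0 || notch >= rec$fs / 2) stop("invalid notch frequency")
    sos <- c(sos, notch_sos(notch, rec$fs))
  }
  out <- filtfilt_mat(sos, rec$data)
  eeg_recording(out, rec$fs, rec$layout, rec$meta)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel.
#' Idempotent.
#'
#' @param rec An `eeg_recording` (>= 2 channels).
#' @return The re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"), ncol(rec$data) >= 2)
  out <- rec$data - rowMeans(rec$data)
  eeg_recording(out, rec$fs, rec$layout, rec$meta)
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive non-overlapping windows of `length_s` seconds; a trailing
#' partial window is discarded.
#'
#' @param rec An `eeg_recording`.
#' @param length_s Epoch length in seconds (default 2).
#' @return An `eeg_epochs` object.
#' @export
epoch_recording <- function(rec, length_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(length_s * rec$fs)
  n_ep <- nrow(rec$data) %/% len
  if (n_ep < 1) stop("recording shorter than one epoch")
  nch <- ncol(rec$data)
  ep <- array(NA_real_, dim = c(n_ep, len, nch))
  for (i in seq_len(n_ep)) {
    ep[i, , ] <- rec$data[(i - 1) * len + seq_len(len), ]
  }
  eeg_epochs(ep, rec$fs, length_s, layout = rec$layout, meta = rec$meta)
}

#' Amplitude-based epoch rejection
#'
#' Drops every epoch whose peak absolute amplitude on any channel exceeds
#' `threshold_uv` (the standard >100 microvolt artifact rule). The returned
#' `kept_mask` marks survivors in the input epoch order.
#'
#' @param epochs An `eeg_epochs` object.
#' @param threshold_uv Rejection threshold in microvolts (default 100).
#' @return An `eeg_epochs` object containing only surviving epochs.
#' @export
reject_amplitude <- function(epochs, threshold_uv = 100) {
  stopifnot(inherits(epochs, "eeg_epochs"), threshold_uv > 0)
  peak <- apply(abs(epochs$epochs), 1, max)
  keep <- peak <= threshold_uv
  if (!any(keep))
    stop(sprintf("all %d epochs exceed %g uV; nothing left after rejection",
                 length(keep), threshold_uv))
  eeg_epochs(epochs$epochs[keep, , , drop = FALSE], epochs$fs,
             epochs$epoch_length_s, kept_mask = keep,
             layout = epochs$layout, meta = epochs$meta)
}

#' Standard preprocessing chain
#'
#' Runs the default offline chain: resample to `target_fs`, zero-phase
#' band-pass `lo`-`hi` Hz plus `notch` Hz notch, cut into `epoch_s`-second
#' epochs, reject epochs exceeding `reject_uv`, and apply the common
#' average reference (re-referencing commutes with epoching, so applying it
#' after epoching is equivalent to before).
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Resampling target in Hz (default 250).
#' @param lo,hi,notch Filter parameters in Hz (defaults 1, 40, 50).
#' @param epoch_s Epoch length in seconds (default 2).
#' @param reject_uv Amplitude rejection threshold in microvolts
#'   (default 100).
#' @return An `eeg_epochs` object of cleaned, average-referenced epochs.
#' @export
preprocess <- function(rec, target_fs = 250, lo = 1, hi = 40, notch = 50,
                       epoch_s = 2, reject_uv = 100) {
  rec <- resample_recording(rec, target_fs)
  rec <- filter_band_notch(rec, lo, hi, notch)
  ep <- epoch_recording(rec, epoch_s)
  ep <- reject_amplitude(ep, reject_uv)
  # common average reference applied per sample within each epoch
  ep$epochs <- ep$epochs - as.vector(rowMeans(ep$epochs, dims = 2))
  ep
}

#' Concatenate surviving epochs back into a continuous recording
#'
#' Inverse of [epoch_recording()] for surviving epochs: stacks them in time
#' order. Used to segment microstates on a continuous signal; epoch joins
#' are reported so downstream run statistics can avoid counting transitions
#' across discontinuities.
#'
#' @param epochs An `eeg_epochs` object.
#' @return A list with `rec` (an `eeg_recording`) and `boundaries`
#'   (1-based sample indices at which a new epoch begins).
#' @export
concatenate_epochs <- function(epochs) {
  d <- dim(epochs$epochs)
  n_ep <- d[1]; len <- d[2]; nch <- d[3]
  dat <- matrix(NA_real_, nrow = n_ep * len, ncol = nch)
  for (i in seq_len(n_ep)) {
    dat[(i - 1) * len + seq_len(len), ] <- epochs$epochs[i, , ]
  }
  rec <- eeg_recording(dat, epochs$fs, epochs$layout, epochs$meta)
  list(rec = rec, boundaries = (seq_len(n_ep) - 1L) * len + 1L)
}
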