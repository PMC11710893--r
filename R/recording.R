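#' Multichannel EEG recording container
#'
#' @param data samples x channels numeric matrix, physical units microvolts.
#' @param fs Sampling frequency in Hz.
#' @param layout An `eeg_layout` whose channel count matches `ncol(data)`.
#' @param meta Named list of metadata (subject, condition, block, seed, ...).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, layout, meta = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("recording data must be finite numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  if (!inherits(layout, "eeg_layout"))
    stop("layout must be an eeg_layout")
  if (ncol(data) != length(layout$names))
    stop(sprintf("channel count mismatch: data has %d, layout has %d",
                 ncol(data), length(layout$names)))
  colnames(data) <- layout$names
  structure(list(data = data, fs = fs, layout = layout, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Epoched EEG container
#'
#' @param epochs epoch x sample x channel numeric array.
#' @param fs Sampling frequency in Hz.
#' @param epoch_length_s Epoch length in seconds.
#' @param kept_mask Logical vector over the original epochs (which survived
#'   rejection); defaults to all TRUE.
#' @param layout,meta As in [eeg_recording()].
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(epochs, fs, epoch_length_s, kept_mask = NULL,
                       layout = NULL, meta = list()) {
  stopifnot(length(dim(epochs)) == 3L)
  if (dim(epochs)[2] != round(fs * epoch_length_s))
    stop("epoch sample count does not match fs * epoch_length_s")
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, dim(epochs)[1])
  structure(list(epochs = epochs, fs = fs, epoch_length_s = epoch_length_s,
                 kept_mask = kept_mask, layout = layout, meta = meta),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> %d epochs x %d samples x %d channels @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}
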