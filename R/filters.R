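# IIR/FIR primitives. No DSP package ships with this stack, so Butterworth
# design (bilinear transform, second-order sections) and zero-phase
# filtering are implemented here on top of stats::filter, which does the
# per-sample recursions in C.

# Butterworth analog prototype poles (unit circle, left half plane)
butter_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

# bilinear transform of an analog biquad (b0+b1 s+b2 s^2)/(a0+a1 s+a2 s^2)
# with s = K (1 - z^-1)/(1 + z^-1)
bilinear_biquad <- function(b, a, K) {
  tr <- function(c3) c(c3[1] + c3[2] * K + c3[3] * K^2,
                       2 * c3[1] - 2 * c3[3] * K^2,
                       c3[1] - c3[2] * K + c3[3] * K^2)
  B <- tr(b); A <- tr(a)
  list(b = B / A[1], a = A / A[1])
}

# Butterworth low/high-pass as a list of second-order sections.
# fc in Hz, fs in Hz. Odd orders get a first-order section padded to biquad.
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  K <- 1
  wc <- tan(pi * fc / fs)  # prewarped, for K = 1
  poles <- butter_poles(order)
  sos <- list()
  # conjugate pairs
  idx <- which(Im(poles) > 1e-12)
  for (p in poles[idx]) {
    re <- Re(p)
    if (type == "low") {
      b <- c(wc^2, 0, 0)
      a <- c(wc^2, -2 * re * wc, 1)
    } else {
      b <- c(0, 0, 1)
      a <- c(wc^2, -2 * re * wc, 1)
    }
    sos[[length(sos) + 1L]] <- bilinear_biquad(b, a, K)
  }
  if (order %% 2 == 1) {  # real pole at -1
    if (type == "low") {
      b <- c(wc, 0, 0); a <- c(wc, 1, 0)
    } else {
      b <- c(0, 1, 0); a <- c(wc, 1, 0)
    }
    sos[[length(sos) + 1L]] <- bilinear_biquad(b, a, K)
  }
  sos
}

# second-order IIR notch (zero on the unit circle at f0); q = f0 / bandwidth
notch_sos <- function(f0, fs, q = 25) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(list(b = b / a[1], a = a / a[1]))
}

# direct-form filtering with zero initial conditions; FIR part via
# convolution, AR part via the recursive mode of stats::filter. Accepts a
# vector or a samples x channels matrix (columns filtered independently,
# all in C via stats::filter).
filter_ba <- function(b, a, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  nb <- length(b)
  Xp <- rbind(matrix(0, nb - 1, ncol(X)), X)
  V <- stats::filter(Xp, b, method = "convolution", sides = 1)
  V <- unclass(V)[(nb - 1) + seq_len(n), , drop = FALSE]
  if (length(a) > 1) {
    V <- unclass(stats::filter(V, -a[-1], method = "recursive"))
  }
  if (vec) as.numeric(V) else matrix(as.numeric(V), n, ncol(X))
}

# forward-backward (zero phase) filtering through a cascade of sections.
# Edge transients are suppressed by padding with an even reflection of the
# signal tapered to zero (a DC-free extension, so narrowband sections do
# not ring on an offset step). Vector or samples x channels matrix.
sos_filtfilt <- function(sos, x, padlen = NULL) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  if (is.null(padlen)) padlen <- min(n - 1L, 1000L)
  if (padlen > 0) {
    ramp <- 0.5 * (1 + cos(seq(0, pi, length.out = padlen)))
    left <- rev(ramp) * X[seq(padlen + 1, 2), , drop = FALSE]
    right <- ramp * X[seq(n - 1, n - padlen), , drop = FALSE]
    Xp <- rbind(left, X, right)
  } else {
    Xp <- X
  }
  Xp <- sosfilt_cpp(sos, Xp)
  Xp <- Xp[rev(seq_len(nrow(Xp))), , drop = FALSE]
  Xp <- sosfilt_cpp(sos, Xp)
  Xp <- Xp[rev(seq_len(nrow(Xp))), , drop = FALSE]
  out <- Xp[padlen + seq_len(n), , drop = FALSE]
  if (vec) as.numeric(out) else out
}

# filter a samples x channels matrix through a cascade, zero phase
filtfilt_mat <- function(sos, x, padlen = NULL) {
  sos_filtfilt(sos, x, padlen = padlen)
}

# windowed-sinc lowpass FIR, odd length, Hamming window, unit DC gain
fir_lowpass <- function(ntaps, cutoff) {  # cutoff normalized to Nyquist
  stopifnot(ntaps %% 2 == 1)
  m <- (ntaps - 1) / 2
  k <- seq(-m, m)
  h <- cutoff * sinc(cutoff * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# rational-ratio polyphase resampling (upsample L, FIR lowpass, downsample M)
# with linear-phase delay compensation; output length round(n * L / M)
resample_poly <- function(x, L, M) {
  n <- length(x)
  n_out <- round(n * L / M)
  if (L == 1 && M == 1) return(x)
  up <- numeric(n * L)
  up[seq(1, by = L, length.out = n)] <- x * L
  cutoff <- 1 / max(L, M)            # relative to upsampled Nyquist
  half <- 10 * max(L, M)
  ntaps <- 2 * half + 1
  h <- fir_lowpass(ntaps, cutoff)
  pad <- c(rep(0, half), up, rep(0, half))
  y <- stats::filter(pad, h, method = "convolution", sides = 1)
  y <- as.numeric(y)[(ntaps - 1) + seq_len(n * L)]  # delay-centred
  y[seq(1, by = M, length.out = n_out)]
}
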