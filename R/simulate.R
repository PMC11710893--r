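# Synthetic multichannel EEG with planted microstate dynamics and band
# structure. The generator is a stand-in for real recordings: the study
# data it emulates are not deposited, so every structural choice here
# (geometric dwell law, band-limited noise carrier, dipolar template maps)
# is an explicit modelling decision documented in the methods vignette.

#' Synthetic generator configuration
#'
#' @param layout An `eeg_layout` (default [make_layout()]).
#' @param templates Planted `microstate_templates` (default
#'   [make_canonical_templates()] on `layout`).
#' @param mean_durations_ms Per-class mean dwell times in ms (default 80
#'   for each of the four classes).
#' @param transition_matrix Row-stochastic k x k matrix with zero diagonal
#'   (default: uniform off-diagonal).
#' @param carrier_band Two-element band `[f_lo, f_hi]` in Hz for the
#'   oscillatory carrier (default alpha, 8-13 Hz).
#' @param snr_db Signal-to-noise ratio in dB: RMS of the microstate signal
#'   over RMS of the spatially white sensor noise, both after average
#'   reference (default 10).
#' @param fs Sampling frequency in Hz (default 250).
#' @param duration_s Recording length in seconds (default 180, one task
#'   block).
#' @param seed Integer seed.
#' @param band_components Named per-band RMS amplitudes (microvolts) of
#'   independent per-channel band-limited background activity; these carry
#'   the spectral contrasts.
#' @param band_gain Named per-band multiplicative power gains applied to
#'   `band_components` (amplitude scales by `sqrt(gain)`); default all 1.
#' @param carrier_rms_uv RMS amplitude of the microstate carrier summed
#'   over channels (default 25).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(layout = make_layout(),
                             templates = make_canonical_templates(layout),
                             mean_durations_ms = c(A = 80, B = 80,
                                                   C = 80, D = 80),
                             transition_matrix = NULL,
                             carrier_band = c(8, 13),
                             snr_db = 10,
                             fs = 250,
                             duration_s = 180,
                             seed = 1,
                             band_components = c(delta = 3, theta = 2.5,
                                                 alpha = 2, beta = 1.5),
                             band_gain = c(delta = 1, theta = 1,
                                           alpha = 1, beta = 1),
                             carrier_rms_uv = 25) {
  k <- nrow(templates$templates)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (k - 1), k, k)
    diag(transition_matrix) <- 0
  }
  stopifnot(length(mean_durations_ms) == k,
            all(mean_durations_ms > 0),
            nrow(transition_matrix) == k,
            ncol(transition_matrix) == k,
            all(abs(diag(transition_matrix)) == 0),
            all(abs(rowSums(transition_matrix) - 1) < 1e-12),
            fs > 2 * carrier_band[2],
            duration_s > 0)
  if (snr_db < -40) stop("snr_db below -40 dB: unusable configuration")
  structure(list(layout = layout, templates = templates,
                 mean_durations_ms = mean_durations_ms,
                 transition_matrix = transition_matrix,
                 carrier_band = carrier_band, snr_db = snr_db, fs = fs,
                 duration_s = duration_s, seed = as.integer(seed),
                 band_components = band_components, band_gain = band_gain,
                 carrier_rms_uv = carrier_rms_uv),
            class = "synthetic_config")
}

#' Stationary class occupancy of a semi-Markov configuration
#'
#' Time-stationary occupancy: the stationary distribution `nu` of the
#' embedded transition chain weighted by the mean dwell times,
#' `pi_i = nu_i d_i / sum_j nu_j d_j`.
#'
#' @param transition_matrix Row-stochastic matrix, zero diagonal.
#' @param mean_durations_ms Per-class mean dwell times.
#' @return Numeric occupancy vector summing to 1.
#' @export
stationary_occupancy <- function(transition_matrix, mean_durations_ms) {
  e <- eigen(t(transition_matrix))
  i <- which.min(abs(e$values - 1))
  nu <- abs(Re(e$vectors[, i]))
  nu <- nu / sum(nu)
  p <- nu * mean_durations_ms
  p / sum(p)
}

#' Sample a semi-Markov microstate label sequence
#'
#' Dwell lengths are geometric (memoryless) with per-class mean
#' `fs * mean_duration_ms / 1000` samples, minimum 1 sample; the successor
#' class is drawn from the corresponding row of the transition matrix. The
#' initial class is drawn from the stationary occupancy. Deterministic
#' given the config seed.
#'
#' @param cfg A `synthetic_config`.
#' @param n_samples Optional override of `fs * duration_s`.
#' @return Integer vector of class indices (1-based), length `n_samples`.
#' @export
sample_state_sequence <- function(cfg, n_samples = NULL) {
  if (is.null(n_samples)) n_samples <- round(cfg$fs * cfg$duration_s)
  Tm <- cfg$transition_matrix
  if (any(rowSums(Tm) == 0)) stop("degenerate transition row (all zero)")
  k <- nrow(Tm)
  mean_len <- cfg$fs * cfg$mean_durations_ms / 1000
  # geometric with support >= 1 and mean m: 1 + Geom(p = 1/m), needs m >= 1
  p_geo <- 1 / pmax(mean_len, 1)
  set.seed(cfg$seed)
  start_p <- stationary_occupancy(Tm, cfg$mean_durations_ms)
  state <- sample.int(k, 1, prob = start_p)
  labels <- integer(n_samples)
  pos <- 1L
  while (pos <= n_samples) {
    len <- 1L + stats::rgeom(1, p_geo[state])
    end <- min(pos + len - 1L, n_samples)
    labels[pos:end] <- state
    pos <- end + 1L
    state <- sample.int(k, 1, prob = Tm[state, ])
  }
  labels
}

# band-limited Gaussian noise via spectral masking: white Gaussian columns,
# DFT bins outside [f_lo, f_hi] zeroed, inverse transform, global RMS
# normalized to 1. Exactly band-limited and fast for long recordings.
band_limited_noise <- function(n, fs, band, ncols = 1) {
  X <- matrix(stats::rnorm(n * ncols), n, ncols)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # fold to physical frequency
  mask <- f >= band[1] & f <= band[2]
  Xf <- stats::mvfft(X) * mask
  Y <- Re(stats::mvfft(Xf, inverse = TRUE)) / n
  Y <- Y / sqrt(mean(Y^2))
  if (ncols == 1) as.numeric(Y) else Y
}

#' Synthesize one recording from a configuration
#'
#' The signal is `x(t) = template[label(t)] * a(t) + background + noise`:
#' `a(t)` is a band-limited Gaussian carrier (unit RMS, scaled to
#' `carrier_rms_uv`); the background is independent per-channel
#' band-limited noise for each classical band with RMS
#' `band_components * sqrt(band_gain)`; the sensor noise is spatially white
#' Gaussian scaled so that the carrier-signal-to-noise ratio equals
#' `snr_db` after average reference. The output is average-referenced.
#'
#' @param cfg A `synthetic_config`.
#' @return A list with `rec` (an `eeg_recording`) and `truth` (a
#'   `ground_truth` list: `label_sequence`, `templates`,
#'   `transition_matrix`, `mean_durations_ms`, `band_power_gain`,
#'   `occupancy`).
#' @export
synthesize_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- round(cfg$fs * cfg$duration_s)
  labels <- sample_state_sequence(cfg, n)   # consumes cfg$seed
  nch <- length(cfg$layout$names)
  Tn <- cfg$templates$templates

  carrier <- band_limited_noise(n, cfg$fs, cfg$carrier_band) *
    cfg$carrier_rms_uv
  sig <- Tn[labels, , drop = FALSE] * carrier

  bands <- default_bands()
  bg <- matrix(0, n, nch)
  for (b in seq_len(nrow(bands))) {
    nm <- bands$band[b]
    amp <- cfg$band_components[[nm]] * sqrt(cfg$band_gain[[nm]])
    if (amp > 0) {
      comp <- band_limited_noise(n, cfg$fs,
                                 c(bands$f_lo[b], bands$f_hi[b]),
                                 ncols = nch)
      bg <- bg + amp * comp
    }
  }

  noise <- matrix(stats::rnorm(n * nch), n, nch)
  # average-reference all parts, then set noise scale against the carrier
  avg_ref <- function(M) M - rowMeans(M)
  sig <- avg_ref(sig); bg <- avg_ref(bg); noise <- avg_ref(noise)
  rms_sig <- sqrt(mean(sig^2))
  target_noise_rms <- rms_sig / 10^(cfg$snr_db / 20)
  noise <- noise / sqrt(mean(noise^2)) * target_noise_rms

  data <- sig + bg + noise
  rec <- eeg_recording(data, cfg$fs, cfg$layout,
                       meta = list(seed = cfg$seed))
  truth <- structure(list(label_sequence = labels,
                          templates = cfg$templates,
                          transition_matrix = cfg$transition_matrix,
                          mean_durations_ms = cfg$mean_durations_ms,
                          band_power_gain = cfg$band_gain,
                          occupancy = stationary_occupancy(
                            cfg$transition_matrix,
                            cfg$mean_durations_ms)),
                     class = "ground_truth")
  list(rec = rec, truth = truth)
}

# default planted contrasts between workload conditions; the high
# condition raises theta/beta power, shortens microstate B, makes D more
# frequent, and shifts syntax from A<->B toward C<->D
workload_condition_params <- function(condition = c("low", "high")) {
  condition <- match.arg(condition)
  if (condition == "low") {
    Tm <- rbind(c(0, .40, .30, .30),
                c(.40, 0, .30, .30),
                c(.35, .35, 0, .30),
                c(.35, .35, .30, 0))
    list(mean_durations_ms = c(A = 80, B = 80, C = 80, D = 70),
         transition_matrix = Tm,
         band_gain = c(delta = 1, theta = 1, alpha = 1, beta = 1))
  } else {
    Tm <- rbind(c(0, .25, .35, .40),
                c(.25, 0, .35, .40),
                c(.275, .275, 0, .45),
                c(.275, .275, .45, 0))
    list(mean_durations_ms = c(A = 80, B = 60, C = 80, D = 70),
         transition_matrix = Tm,
         band_gain = c(delta = 1, theta = 1.5, alpha = 1, beta = 1.4))
  }
}

#' Paired low/high workload scenario
#'
#' Per subject and condition, generates `blocks_per_condition` recordings
#' (task blocks). The high condition plants, relative to low: higher theta
#' and beta band power, shorter microstate-B dwell (hence lower B coverage),
#' more frequent D (higher occurrence and coverage), lower A-B transition
#' probability and higher C-D. Subject heterogeneity enters as lognormal
#' jitter on dwell means and band gains.
#'
#' @param n_subjects Number of subjects (>= 2; default 36).
#' @param seed Master seed; per-subject/condition/block seeds derive from
#'   it.
#' @param block_s Block length in seconds (default 180, two 3-min blocks
#'   mirroring the task protocol).
#' @param blocks_per_condition Blocks per condition (default 2).
#' @param snr_db Sensor SNR in dB (default 10).
#' @param subject_sd Lognormal sigma of between-subject jitter
#'   (default 0.1).
#' @return A `workload_scenario`: list with `recordings` (list of
#'   `eeg_recording`s, meta carries subject/condition/block), `truths`
#'   (matching `ground_truth`s), `condition_params`, `n_subjects`, `seed`.
#' @export
make_workload_scenario <- function(n_subjects = 36, seed = 1,
                                   block_s = 180,
                                   blocks_per_condition = 2,
                                   snr_db = 10, subject_sd = 0.1) {
  stopifnot(n_subjects >= 2)
  layout <- make_layout()
  templates <- make_canonical_templates(layout)
  recordings <- list()
  truths <- list()
  set.seed(as.integer(seed))
  # per-subject jitter factors, identical across conditions
  dur_jit <- matrix(exp(stats::rnorm(n_subjects * 4, 0, subject_sd)),
                    n_subjects, 4)
  gain_jit <- matrix(exp(stats::rnorm(n_subjects * 4, 0, subject_sd)),
                     n_subjects, 4)
  idx <- 1L
  for (s in seq_len(n_subjects)) {
    for (cond in c("low", "high")) {
      pars <- workload_condition_params(cond)
      dur <- pars$mean_durations_ms * dur_jit[s, ]
      gain <- pars$band_gain * gain_jit[s, ]
      for (b in seq_len(blocks_per_condition)) {
        blk_seed <- (seed * 97L + s * 17L + ifelse(cond == "high", 7L, 0L) +
                       b * 3L) %% .Machine$integer.max
        cfg <- synthetic_config(layout = layout, templates = templates,
                                mean_durations_ms = dur,
                                transition_matrix =
                                  pars$transition_matrix,
                                snr_db = snr_db, duration_s = block_s,
                                seed = blk_seed, band_gain = gain)
        out <- synthesize_recording(cfg)
        out$rec$meta <- list(subject = s, condition = cond, block = b,
                             seed = blk_seed)
        recordings[[idx]] <- out$rec
        truths[[idx]] <- out$truth
        idx <- idx + 1L
      }
    }
  }
  structure(list(recordings = recordings, truths = truths,
                 condition_params = list(low = workload_condition_params("low"),
                                         high = workload_condition_params("high")),
                 n_subjects = n_subjects, seed = seed,
                 blocks_per_condition = blocks_per_condition),
            class = "workload_scenario")
}
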