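# End-to-end orchestration: simulate -> preprocess -> spectral + microstate
# -> statistics, plus the plain-text recording container (CSV matrix + JSON
# sidecar) used for interchange.

#' Pipeline run configuration
#'
#' Collects every stage parameter so that a run is reproducible from the
#' config alone.
#'
#' @param n_subjects Number of synthetic subjects (default 36).
#' @param seed Master seed (default 1).
#' @param block_s Task-block length in seconds (default 180).
#' @param blocks_per_condition Blocks per condition (default 2).
#' @param snr_db Generator SNR in dB (default 10).
#' @param target_fs,lo,hi,notch,epoch_s,reject_uv Preprocessing parameters
#'   (defaults 250, 1, 40, 50, 2, 100).
#' @param k,n_restarts Microstate clustering parameters (defaults 4, 50).
#' @param fit_at Back-fitting domain, `"peaks"` (default; the GFP-peak
#'   labeling with midpoint extension that microstate toolboxes use) or
#'   `"all"` (label every sample independently).
#' @param fdr_q FDR level (default 0.05).
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 36, seed = 1, block_s = 180,
                       blocks_per_condition = 2, snr_db = 10,
                       target_fs = 250, lo = 1, hi = 40, notch = 50,
                       epoch_s = 2, reject_uv = 100, k = 4,
                       n_restarts = 50, fdr_q = 0.05,
                       fit_at = c("peaks", "all")) {
  fit_at <- match.arg(fit_at)
  structure(as.list(environment()), class = "run_config")
}

# preprocess one recording and return average-referenced epochs
preprocess_with_config <- function(rec, cfg) {
  preprocess(rec, target_fs = cfg$target_fs, lo = cfg$lo, hi = cfg$hi,
             notch = cfg$notch, epoch_s = cfg$epoch_s,
             reject_uv = cfg$reject_uv)
}

#' Run the full analysis pipeline on a workload scenario
#'
#' Generates (or accepts) a paired low/high workload scenario, preprocesses
#' every block, computes the band-power table, performs the two-level
#' microstate analysis (subject-level polarity-invariant k-means on pooled
#' GFP-peak maps, grand-mean clustering, canonical A-D labeling,
#' back-fitting), derives temporal and syntax parameters per subject,
#' condition and block, and runs the statistical battery on the condition
#' contrast plus the band-power / microstate-parameter correlations.
#'
#' @param cfg A `run_config`.
#' @param scenario Optional pre-built `workload_scenario` (otherwise
#'   generated from `cfg`).
#' @return A `run_report`: list of tidy data.frames (`band_contrast`,
#'   `electrode_counts`, `microstate_contrast`, `transition_contrast`,
#'   `correlations`, `bandpower`, `microstate_params`), the grand
#'   templates, and provenance (`config`, seeds).
#' @export
run_pipeline <- function(cfg = run_config(), scenario = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(scenario)) {
    scenario <- make_workload_scenario(
      n_subjects = cfg$n_subjects, seed = cfg$seed, block_s = cfg$block_s,
      blocks_per_condition = cfg$blocks_per_condition, snr_db = cfg$snr_db)
  }

  # ---- preprocess + spectral, and collect peak maps per subject --------
  bp_rows <- list()
  cond_data <- list()   # key subj|cond -> list(rec matrices, boundaries)
  peak_maps <- list()   # per subject pooled GFP-peak maps
  for (i in seq_along(scenario$recordings)) {
    rec <- scenario$recordings[[i]]
    meta <- rec$meta
    ep <- preprocess_with_config(rec, cfg)
    bp_rows[[i]] <- band_average(periodogram(ep))
    cc <- concatenate_epochs(ep)
    key <- paste(meta$subject, meta$condition, sep = "|")
    entry <- cond_data[[key]]
    if (is.null(entry)) entry <- list(data = list(), boundaries = list(),
                                      n = 0L, blocks = integer(0))
    entry$data[[length(entry$data) + 1L]] <- cc$rec$data
    entry$boundaries[[length(entry$boundaries) + 1L]] <- cc$boundaries
    entry$blocks <- c(entry$blocks, meta$block)
    cond_data[[key]] <- entry
    pm <- extract_gfp_peak_maps(cc$rec)
    skey <- as.character(meta$subject)
    peak_maps[[skey]] <- if (is.null(peak_maps[[skey]])) {
      pm
    } else {
      structure(list(maps = rbind(peak_maps[[skey]]$maps, pm$maps),
                     gfp_values = c(peak_maps[[skey]]$gfp_values,
                                    pm$gfp_values),
                     peak_index = NA, source = list(subject = meta$subject)),
                class = "topography_set")
    }
  }
  bandpower <- do.call(rbind, bp_rows)

  # ---- two-level microstate clustering --------------------------------
  subjects <- sort(as.integer(names(peak_maps)))
  subject_sets <- lapply(as.character(subjects), function(s) {
    modified_kmeans(peak_maps[[s]], k = cfg$k,
                    n_restarts = cfg$n_restarts,
                    seed = cfg$seed + as.integer(s))$templates
  })
  grand <- aggregate_grand_mean(subject_sets, seed = cfg$seed)
  layout <- scenario$recordings[[1]]$layout
  grand <- label_canonical(grand, make_canonical_templates(layout))

  # ---- back-fit per subject x condition, parameters per block ---------
  ms_rows <- list(); tr_rows <- list()
  for (key in names(cond_data)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    subj <- as.integer(parts[1]); cond <- parts[2]
    entry <- cond_data[[key]]
    ord <- order(entry$blocks)
    dat <- do.call(rbind, entry$data[ord])
    offs <- cumsum(c(0L, vapply(entry$data[ord], nrow, 0L)))
    bound_all <- unlist(lapply(seq_along(ord), function(j)
      entry$boundaries[[ord[j]]] + offs[j]))
    rec_cond <- eeg_recording(dat, cfg$target_fs, layout,
                              meta = list(subject = subj,
                                          condition = cond))
    seg <- backfit(rec_cond, grand, fit_at = cfg$fit_at)
    seg$boundaries <- as.integer(bound_all)
    pars <- temporal_parameters(seg)
    gev <- compute_gev(seg, rec_cond, grand)
    trans <- transition_probabilities(seg)
    ms_rows[[length(ms_rows) + 1L]] <- data.frame(
      subject = subj, condition = cond, block = NA_integer_,
      class = pars$class, duration_ms = pars$duration_ms,
      occurrence_per_s = pars$occurrence_per_s, coverage = pars$coverage,
      gev = gev, stringsAsFactors = FALSE)
    k <- nrow(trans)
    tr_rows[[length(tr_rows) + 1L]] <- data.frame(
      subject = subj, condition = cond,
      from = rep(rownames(trans), each = k),
      to = rep(colnames(trans), k),
      p = as.vector(t(unclass(trans))), stringsAsFactors = FALSE)
    # per-block parameters (for the correlation analysis)
    for (j in seq_along(ord)) {
      idx <- (offs[j] + 1L):offs[j + 1L]
      sub_seg <- structure(list(
        labels = seg$labels[idx], abs_corr = seg$abs_corr[idx],
        gfp = seg$gfp[idx], fs = seg$fs, class_labels = seg$class_labels,
        boundaries = as.integer(entry$boundaries[[ord[j]]])),
        class = "segmentation")
      bp <- temporal_parameters(sub_seg)
      ms_rows[[length(ms_rows) + 1L]] <- data.frame(
        subject = subj, condition = cond, block = entry$blocks[ord[j]],
        class = bp$class, duration_ms = bp$duration_ms,
        occurrence_per_s = bp$occurrence_per_s, coverage = bp$coverage,
        gev = NA_real_, stringsAsFactors = FALSE)
    }
  }
  microstate_params <- do.call(rbind, ms_rows)
  transitions <- do.call(rbind, tr_rows)

  # ---- statistics ------------------------------------------------------
  report <- list(
    bandpower = bandpower,
    microstate_params = microstate_params,
    transitions = transitions,
    grand_templates = grand,
    band_contrast = band_contrast_stats(bandpower),
    electrode_counts = electrode_count_stats(bandpower, cfg$fdr_q),
    microstate_contrast = microstate_contrast_stats(microstate_params),
    transition_contrast = transition_contrast_stats(transitions),
    correlations = correlation_stats(bandpower, microstate_params),
    config = cfg)
  class(report) <- "run_report"
  report
}

# paired t per band on total average power (high - low)
band_contrast_stats <- function(bandpower) {
  tot <- total_average_power(bandpower)
  out <- list()
  for (b in unique(tot$band)) {
    tb <- tot[tot$band == b, ]
    hi <- tb[tb$condition == "high", ]; lo <- tb[tb$condition == "low", ]
    hi <- hi[order(hi$subject), ]; lo <- lo[order(lo$subject), ]
    tt <- paired_t(hi$power, lo$power)
    out[[b]] <- data.frame(band = b, mean_low = mean(lo$power),
                           mean_high = mean(hi$power),
                           mean_diff = tt$mean_diff, t = tt$t, df = tt$df,
                           p = tt$p, d = tt$d, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

electrode_count_stats <- function(bandpower, q = 0.05) {
  out <- list()
  for (b in unique(bandpower$band)) {
    ec <- electrode_wise_contrast(bandpower, b, q = q)
    out[[b]] <- data.frame(band = b, n_significant = ec$n_significant,
                           n_sig_positive = ec$n_sig_positive,
                           n_sig_negative = ec$n_sig_negative,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# paired t per class and parameter on the condition-level values
microstate_contrast_stats <- function(ms) {
  ms <- ms[is.na(ms$block), ]
  rows <- list()
  add <- function(param, cls, hi, lo) {
    tt <- paired_t(hi, lo)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = param, class = cls, mean_low = mean(lo),
      mean_high = mean(hi), mean_diff = tt$mean_diff, t = tt$t,
      df = tt$df, p = tt$p, d = tt$d, stringsAsFactors = FALSE)
  }
  for (cls in unique(ms$class)) {
    mc <- ms[ms$class == cls, ]
    hi <- mc[mc$condition == "high", ]; lo <- mc[mc$condition == "low", ]
    hi <- hi[order(hi$subject), ]; lo <- lo[order(lo$subject), ]
    add("duration_ms", cls, hi$duration_ms, lo$duration_ms)
    add("occurrence_per_s", cls, hi$occurrence_per_s, lo$occurrence_per_s)
    add("coverage", cls, hi$coverage, lo$coverage)
  }
  gv <- unique(ms[, c("subject", "condition", "gev")])
  hi <- gv[gv$condition == "high", ]; lo <- gv[gv$condition == "low", ]
  hi <- hi[order(hi$subject), ]; lo <- lo[order(lo$subject), ]
  add("gev", "all", hi$gev, lo$gev)
  do.call(rbind, rows)
}

transition_contrast_stats <- function(tr) {
  rows <- list()
  for (f in unique(tr$from)) for (to in unique(tr$to)) {
    if (f == to) next
    tc <- tr[tr$from == f & tr$to == to, ]
    hi <- tc[tc$condition == "high", ]; lo <- tc[tc$condition == "low", ]
    hi <- hi[order(hi$subject), ]; lo <- lo[order(lo$subject), ]
    if (anyNA(hi$p) || anyNA(lo$p)) next
    tt <- paired_t(hi$p, lo$p)
    rows[[length(rows) + 1L]] <- data.frame(
      from = f, to = to, mean_low = mean(lo$p), mean_high = mean(hi$p),
      mean_diff = tt$mean_diff, t = tt$t, p = tt$p, d = tt$d,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# correlations between per-block total band power and per-block microstate
# parameters, observations pooled over subject x condition x block
correlation_stats <- function(bandpower, ms) {
  bp <- stats::aggregate(power ~ subject + condition + block + band,
                         data = as.data.frame(bandpower), FUN = mean)
  msb <- ms[!is.na(ms$block), ]
  rows <- list()
  for (b in unique(bp$band)) {
    bpb <- bp[bp$band == b, ]
    for (cls in unique(msb$class)) {
      for (param in c("duration_ms", "occurrence_per_s", "coverage")) {
        mm <- msb[msb$class == cls, c("subject", "condition", "block",
                                      param)]
        mg <- merge(bpb, mm, by = c("subject", "condition", "block"))
        ct <- pearson_cor(mg$power, mg[[param]])
        rows[[length(rows) + 1L]] <- data.frame(
          band = b, class = cls, parameter = param, R = ct$R, p = ct$p,
          n = ct$n, strength = ct$strength, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a recording to the plain-text container
#'
#' Data matrix as CSV (one column per channel, header = channel names) and
#' a JSON sidecar with `fs`, `channel_names`, `montage_name` and the
#' recording metadata. Lossless up to float formatting precision.
#'
#' @param rec An `eeg_recording`.
#' @param path Path stem; writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  data.table::fwrite(data.table::as.data.table(rec$data),
                     paste0(path, ".csv"))
  sidecar <- list(fs = rec$fs, channel_names = rec$layout$names,
                  montage_name = rec$layout$montage_name, meta = rec$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording from the plain-text container
#'
#' @param path Path stem as used by [write_recording()].
#' @param layout Layout to validate against (default [make_layout()]).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, layout = make_layout()) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stop("sidecar JSON not found: ",
                                       sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$fs)) stop("sidecar missing fs")
  dat <- as.matrix(data.table::fread(paste0(path, ".csv")))
  if (!identical(colnames(dat), layout$names))
    stop("channel names in container do not match layout")
  eeg_recording(dat, side$fs, layout, meta = as.list(side$meta))
}

#' Write the report tables of a pipeline run
#'
#' One tidy CSV per table plus a JSON summary with the configuration.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("bandpower", "microstate_params", "transitions",
            "band_contrast", "electrode_counts", "microstate_contrast",
            "transition_contrast", "correlations")
  for (tb in tabs) {
    data.table::fwrite(as.data.frame(report[[tb]]),
                       file.path(dir, paste0(tb, ".csv")))
  }
  summary <- list(config = unclass(report$config),
                  grand_template_labels = report$grand_templates$labels,
                  canonical_match =
                    as.list(attr(report$grand_templates, "match_quality")))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("Band-power contrast (high vs low):\n")
  print(x$band_contrast, row.names = FALSE)
  cat("\nMicrostate parameter contrasts (high vs low):\n")
  print(x$microstate_contrast, row.names = FALSE)
  invisible(x)
}
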