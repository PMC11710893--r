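#' Microstate template set constructor
#'
#' Wraps a k x channel matrix of topographies as a `microstate_templates`
#' object. Each map is forced to the average-reference convention (zero mean
#' across channels) and unit L2 norm.
#'
#' @param maps k x channel numeric matrix.
#' @param labels Character vector of class labels (default `LETTERS[1:k]`).
#' @param level One of "subject", "grand_mean", "canonical".
#' @param channel_names Optional channel names (stored as colnames).
#' @return A `microstate_templates` object.
#' @export
microstate_templates <- function(maps, labels = NULL,
                                 level = c("subject", "grand_mean",
                                           "canonical"),
                                 channel_names = NULL) {
  level <- match.arg(level)
  maps <- as.matrix(maps)
  if (!is.null(channel_names)) colnames(maps) <- channel_names
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("template map with zero norm")
  maps <- maps / nrm
  if (is.null(labels)) labels <- LETTERS[seq_len(nrow(maps))]
  rownames(maps) <- labels
  structure(list(templates = maps, labels = labels, level = level),
            class = "microstate_templates")
}

#' @export
print.microstate_templates <- function(x, ...) {
  cat(sprintf("<microstate_templates> k = %d, %d channels, level = %s\n",
              nrow(x$templates), ncol(x$templates), x$level))
  invisible(x)
}

#' Canonical four-class microstate topographies
#'
#' Analytic stand-ins for the four canonical microstate classes, built as
#' dipolar patterns on the spherical montage: each map is the cosine of the
#' angle between the electrode position and a class-specific axis
#' (average-referenced, unit norm). Axes are chosen so that
#' \itemize{
#'   \item A is a right-frontal to left-posterior configuration,
#'   \item B is its left-right mirror (left-frontal to right-posterior),
#'   \item C is a left-right symmetric anterior-posterior configuration,
#'   \item D has a frontocentral maximum (near-radial axis).
#' }
#' These are not fitted to any dataset; they serve as canonical references
#' for labeling and as planted ground truth in the synthetic generator.
#' Pairwise absolute spatial correlations are below 0.7.
#'
#' @param layout An `eeg_layout`.
#' @return A `microstate_templates` object with labels A-D,
#'   level "canonical".
#' @export
make_canonical_templates <- function(layout) {
  axis_map <- function(u) {
    u <- u / sqrt(sum(u^2))
    as.numeric(layout$positions %*% u)
  }
  deg <- pi / 180
  # A/B axes 55 deg off the midline keep |corr| with C below 0.7
  maps <- rbind(
    A = axis_map(c(sin(55 * deg), cos(55 * deg), 0)),
    B = axis_map(c(-sin(55 * deg), cos(55 * deg), 0)),
    C = axis_map(c(0, 1, 0)),
    D = axis_map(c(0, 0.35, 1))
  )
  microstate_templates(maps, labels = c("A", "B", "C", "D"),
                       level = "canonical", channel_names = layout$names)
}
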