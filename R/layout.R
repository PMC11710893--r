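#' Standard 31-channel 10-20 montage
#'
#' Builds the 31-electrode layout used throughout the package: the classic
#' 10-20 positions plus the intermediate frontocentral / centroparietal rows
#' (FC, CP) and POz. Electrode coordinates are idealized unit-sphere
#' positions derived from the proportional 10-20 scheme (x = right,
#' y = anterior, z = superior); they are geometric stand-ins, not digitized
#' head positions, and are used for template construction and left-right
#' symmetry operations only.
#'
#' @return An object of class `eeg_layout`: a list with `names` (31 channel
#'   labels), `positions` (31 x 3 matrix of unit vectors, rownames = channel
#'   names), and `montage_name`.
#' @export
#' @examples
#' lay <- make_layout()
#' lay$names
make_layout <- function() {
  # inclination from vertex (deg), azimuth from front midline (deg, + = right)
  sph <- function(incl, azim) {
    i <- incl * pi / 180
    a <- azim * pi / 180
    c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
  }
  # spherical midpoint of unit vectors
  smid <- function(...) {
    v <- colMeans(do.call(rbind, list(...)))
    v / sqrt(sum(v^2))
  }

  pos <- list(
    Fpz = sph(72, 0),    Fp1 = sph(72, -18), Fp2 = sph(72, 18),
    F7  = sph(72, -54),  F8  = sph(72, 54),
    T7  = sph(72, -90),  T8  = sph(72, 90),
    P7  = sph(72, -126), P8  = sph(72, 126),
    O1  = sph(72, -162), O2  = sph(72, 162), Oz = sph(72, 180),
    Fz  = sph(36, 0),    Cz  = sph(0, 0),    Pz = sph(36, 180),
    C3  = sph(36, -90),  C4  = sph(36, 90)
  )
  pos$F3  <- smid(pos$Fz, pos$F7)
  pos$F4  <- smid(pos$Fz, pos$F8)
  pos$P3  <- smid(pos$Pz, pos$P7)
  pos$P4  <- smid(pos$Pz, pos$P8)
  pos$CPz <- smid(pos$Cz, pos$Pz)
  pos$POz <- smid(pos$Pz, pos$Oz)
  pos$FC1 <- smid(pos$Fz, pos$Cz, pos$F3, pos$C3)
  pos$FC2 <- smid(pos$Fz, pos$Cz, pos$F4, pos$C4)
  pos$FC5 <- smid(pos$F7, pos$T7, pos$F3, pos$C3)
  pos$FC6 <- smid(pos$F8, pos$T8, pos$F4, pos$C4)
  pos$CP1 <- smid(pos$Pz, pos$Cz, pos$P3, pos$C3)
  pos$CP2 <- smid(pos$Pz, pos$Cz, pos$P4, pos$C4)
  pos$CP5 <- smid(pos$P7, pos$T7, pos$P3, pos$C3)
  pos$CP6 <- smid(pos$P8, pos$T8, pos$P4, pos$C4)

  names31 <- c("Fp1", "Fp2", "Fpz", "F7", "F8", "F3", "F4", "Fz",
               "FC5", "FC6", "FC1", "FC2", "T7", "T8", "C3", "C4", "Cz",
               "CP5", "CP6", "CP1", "CP2", "CPz", "P7", "P8", "P3", "P4",
               "Pz", "POz", "O1", "O2", "Oz")
  P <- do.call(rbind, pos[names31])
  rownames(P) <- names31

  structure(list(names = names31, positions = P,
                 montage_name = "standard 10-20 (31 ch)"),
            class = "eeg_layout")
}

#' Left-right mirror permutation of a layout
#'
#' Returns the channel index permutation that swaps each left-hemisphere
#' electrode with its right-hemisphere homologue (midline channels map to
#' themselves). Used for symmetry checks on topographies.
#'
#' @param layout An `eeg_layout`.
#' @return Integer vector `p` such that `map[p]` is the left-right mirrored
#'   topography.
#' @export
mirror_lr_permutation <- function(layout) {
  pairs <- list(c("Fp1", "Fp2"), c("F7", "F8"), c("F3", "F4"),
                c("FC5", "FC6"), c("FC1", "FC2"), c("T7", "T8"),
                c("C3", "C4"), c("CP5", "CP6"), c("CP1", "CP2"),
                c("P7", "P8"), c("P3", "P4"), c("O1", "O2"))
  p <- seq_along(layout$names)
  names(p) <- layout$names
  for (pr in pairs) {
    p[pr[1]] <- match(pr[2], layout$names)
    p[pr[2]] <- match(pr[1], layout$names)
  }
  unname(p)
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat(sprintf("<eeg_layout> %s: %d channels\n", x$montage_name,
              length(x$names)))
  cat(" ", paste(x$names, collapse = " "), "\n")
  invisible(x)
}
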