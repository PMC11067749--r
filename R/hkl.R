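# Reflection containers and SHELX-style fixed-width reflection files.

#' Reflection set constructor
#'
#' A data frame of indexed amplitudes/intensities with sigmas. The
#' `observed` flag is I > 3 sigma(I) when intensities are present,
#' otherwise TRUE.
#'
#' @param hkl n x 3 integer matrix.
#' @param cell `unit_cell` used to attach d-spacings.
#' @param Fobs Amplitudes (exclusive with `Iobs`).
#' @param Iobs Intensities.
#' @param sigma Standard uncertainties of the supplied quantity.
#' @param phase Optional model phases (radians).
#' @return Data frame of class `reflection_set` with columns
#'   h, k, l, d, Fobs or Iobs, sigma, observed (+ phase).
#' @export
reflection_set <- function(hkl, cell, Fobs = NULL, Iobs = NULL,
                           sigma = NULL, phase = NULL) {
  H <- rbind_hkl(hkl)
  d <- d_spacing(cell, H)
  if (is.null(sigma)) sigma <- rep(0, nrow(H))
  if (any(sigma < 0)) stop("sigmas must be >= 0")
  out <- data.frame(h = H[, 1], k = H[, 2], l = H[, 3], d = d, sigma = sigma)
  if (!is.null(Fobs) && !is.null(Iobs)) stop("supply Fobs or Iobs, not both")
  if (!is.null(Fobs)) {
    out$Fobs <- Fobs
    out$observed <- TRUE
  } else if (!is.null(Iobs)) {
    out$Iobs <- Iobs
    out$observed <- Iobs > 3 * sigma
  } else {
    stop("supply Fobs or Iobs")
  }
  if (!is.null(phase)) out$phase <- phase
  class(out) <- c("reflection_set", "data.frame")
  out
}

#' Write a SHELX-style reflection file
#'
#' Fixed-width `h k l value sigma` rows (HKLF 3 for amplitudes, HKLF 4
#' for intensities), format `%4d%4d%4d%8.2f%8.2f`.
#'
#' @param refl A `reflection_set` (or data frame with the same columns).
#' @param path Output path.
#' @param hklf 3 to write `Fobs`, 4 to write `Iobs`.
#' @export
write_shelx_hkl <- function(refl, path, hklf = if ("Iobs" %in% names(refl)) 4 else 3) {
  val <- if (hklf == 4) refl$Iobs else refl$Fobs
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", refl$h, refl$k, refl$l, val, refl$sigma)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0, 0, 0, 0, 0)), path)
  invisible(path)
}

#' Read a SHELX-style reflection file
#'
#' @param path File path.
#' @param cell `unit_cell` for d-spacings.
#' @param hklf 3 (amplitudes) or 4 (intensities).
#' @return A `reflection_set`.
#' @export
read_shelx_hkl <- function(path, cell, hklf = 4) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  h <- as.integer(substr(lines, 1, 4))
  k <- as.integer(substr(lines, 5, 8))
  l <- as.integer(substr(lines, 9, 12))
  v <- as.numeric(substr(lines, 13, 20))
  sig <- as.numeric(substr(lines, 21, 28))
  keep <- !(h == 0 & k == 0 & l == 0)
  H <- cbind(h, k, l)[keep, , drop = FALSE]
  if (hklf == 4) {
    reflection_set(H, cell, Iobs = v[keep], sigma = sig[keep])
  } else {
    reflection_set(H, cell, Fobs = v[keep], sigma = sig[keep])
  }
}

#' Write a phase-bearing reflection file
#'
#' Extended text format for theoretical structure-factor sets:
#' whitespace-separated `h k l F phase_deg` with a one-line header.
#'
#' @param refl Data frame with h, k, l, `Fobs` and `phase` (radians).
#' @param path Output path.
#' @export
write_phased_hkl <- function(refl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# h k l F phase_deg", con)
  writeLines(sprintf("%5d %5d %5d %14.6f %12.4f", refl$h, refl$k, refl$l,
                     refl$Fobs, refl$phase * 180 / pi), con)
  invisible(path)
}

#' Read a phase-bearing reflection file
#' @param path File path.
#' @param cell `unit_cell`.
#' @return A `reflection_set` with a `phase` column (radians).
#' @export
read_phased_hkl <- function(path, cell) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("h", "k", "l", "F", "phase_deg"))
  reflection_set(as.matrix(tab[, 1:3]), cell, Fobs = tab$F,
                 sigma = rep(0, nrow(tab)), phase = tab$phase_deg * pi / 180)
}
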