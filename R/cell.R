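#' Unit cell with metric tensors
#'
#' Builds a unit cell object carrying the direct and reciprocal metric
#' tensors, the cell volume and an orthogonalization (Cartesianization)
#' matrix. Angles are in degrees, lengths in Angstrom.
#'
#' @param a,b,c Cell lengths (Angstrom), > 0.
#' @param alpha,beta,gamma Cell angles (degrees), in (0, 180).
#' @return An object of class `unit_cell` with elements `abc`, `angles`,
#'   `G` (direct metric), `Gstar` (reciprocal metric), `volume` (A^3),
#'   `ortho` (3x3 matrix: fractional -> Cartesian, columns are the cell
#'   vectors in an orthonormal frame) and `recip_ortho` (reciprocal cell
#'   vectors as rows; `recip_ortho %*% h` is the Cartesian scattering
#'   vector of reflection h, length 1/d).
#' @export
build_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(ang[1] * pi / 180); cb <- cos(ang[2] * pi / 180); cg <- cos(ang[3] * pi / 180)
  sg <- sin(ang[3] * pi / 180)
  G <- matrix(c(a * a,      a * b * cg, a * c * cb,
                a * b * cg, b * b,      b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  detG <- det(G)
  if (!is.finite(detG) || detG <= 0) {
    stop("direct metric tensor is not positive definite for these parameters")
  }
  vol <- sqrt(detG)
  # standard PDB-style orthogonalization: a along x, b in xy plane
  cs <- (ca - cb * cg) / sg
  M <- matrix(c(a, b * cg, c * cb,
                0, b * sg, c * cs,
                0, 0,      c * sqrt(max(0, 1 - cb^2 - cs^2))), 3, 3, byrow = TRUE)
  structure(list(abc = c(a = a, b = b, c = c),
                 angles = c(alpha = alpha, beta = beta, gamma = gamma),
                 G = G, Gstar = solve(G), volume = vol,
                 ortho = M, recip_ortho = t(solve(M))),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.2f A^3\n",
              x$abc[1], x$abc[2], x$abc[3],
              x$angles[1], x$angles[2], x$angles[3], x$volume))
  invisible(x)
}

#' Resolution d-spacing of reflections
#'
#' 1/d^2 = h' Gstar h. Accepts a single hkl triple or an n x 3 matrix.
#'
#' @param cell A `unit_cell`.
#' @param hkl Integer triple or n x 3 matrix of Miller indices.
#' @return d in Angstrom (vector for a matrix input).
#' @export
d_spacing <- function(cell, hkl) {
  H <- rbind_hkl(hkl)
  if (any(rowSums(H != 0) == 0)) {
    stop("d-spacing undefined for the (0,0,0) index")
  }
  inv_d2 <- rowSums((H %*% cell$Gstar) * H)
  1 / sqrt(inv_d2)
}

# normalize hkl input to a numeric n x 3 matrix
rbind_hkl <- function(hkl) {
  H <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3, byrow = TRUE)
  storage.mode(H) <- "double"
  if (ncol(H) != 3) stop("hkl must have three columns")
  H
}

#' Cartesian scattering vectors for reflections
#'
#' @param cell A `unit_cell`.
#' @param hkl n x 3 index matrix.
#' @return n x 3 matrix of reciprocal vectors in the orthonormal frame
#'   (rows; length of each row is 1/d).
#' @export
recip_cartesian <- function(cell, hkl) {
  H <- rbind_hkl(hkl)
  H %*% t(cell$recip_ortho)
}
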