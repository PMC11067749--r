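# Real spherical harmonics (orthonormal, Cartesian polynomial forms) and
# the density-normalized d_lm used by the Hansen-Coppens pseudoatom model.

#' Orthonormal real spherical harmonic y_lm
#'
#' Evaluated on unit direction vectors via Cartesian polynomials
#' (0 <= l <= 4). Normalized so that the integral of y_lm^2 over the
#' sphere is 1.
#'
#' @param l,m Indices, 0 <= l <= 4, -l <= m <= l.
#' @param dir Unit direction(s): length-3 vector or n x 3 matrix.
#' @return Numeric vector of values.
#' @export
real_spherical_harmonic <- function(l, m, dir) {
  D <- if (is.matrix(dir)) dir else matrix(dir, ncol = 3)
  x <- D[, 1]; y <- D[, 2]; z <- D[, 3]
  if (l < 0 || l > 4 || abs(m) > l) stop("invalid (l, m): ", l, ",", m)
  sq <- sqrt
  switch(paste(l, m),
    "0 0" = rep(0.5 * sq(1 / pi), length(x)),
    "1 -1" = sq(3 / (4 * pi)) * y,
    "1 0"  = sq(3 / (4 * pi)) * z,
    "1 1"  = sq(3 / (4 * pi)) * x,
    "2 -2" = 0.5 * sq(15 / pi) * x * y,
    "2 -1" = 0.5 * sq(15 / pi) * y * z,
    "2 0"  = 0.25 * sq(5 / pi) * (3 * z^2 - 1),
    "2 1"  = 0.5 * sq(15 / pi) * x * z,
    "2 2"  = 0.25 * sq(15 / pi) * (x^2 - y^2),
    "3 -3" = 0.25 * sq(35 / (2 * pi)) * y * (3 * x^2 - y^2),
    "3 -2" = 0.5 * sq(105 / pi) * x * y * z,
    "3 -1" = 0.25 * sq(21 / (2 * pi)) * y * (5 * z^2 - 1),
    "3 0"  = 0.25 * sq(7 / pi) * (5 * z^3 - 3 * z),
    "3 1"  = 0.25 * sq(21 / (2 * pi)) * x * (5 * z^2 - 1),
    "3 2"  = 0.25 * sq(105 / pi) * (x^2 - y^2) * z,
    "3 3"  = 0.25 * sq(35 / (2 * pi)) * x * (x^2 - 3 * y^2),
    "4 -4" = 0.75 * sq(35 / pi) * x * y * (x^2 - y^2),
    "4 -3" = 0.75 * sq(35 / (2 * pi)) * y * z * (3 * x^2 - y^2),
    "4 -2" = 0.75 * sq(5 / pi) * x * y * (7 * z^2 - 1),
    "4 -1" = 0.75 * sq(5 / (2 * pi)) * y * z * (7 * z^2 - 3),
    "4 0"  = 3 / 16 * sq(1 / pi) * (35 * z^4 - 30 * z^2 + 3),
    "4 1"  = 0.75 * sq(5 / (2 * pi)) * x * z * (7 * z^2 - 3),
    "4 2"  = 3 / 8 * sq(5 / pi) * (x^2 - y^2) * (7 * z^2 - 1),
    "4 3"  = 0.75 * sq(35 / (2 * pi)) * x * z * (x^2 - 3 * y^2),
    "4 4"  = 3 / 16 * sq(35 / pi) * (x^4 - 6 * x^2 * y^2 + y^4))
}

# Density-normalization factors C_lm with d_lm = C_lm * y_lm, chosen so that
# integral |d_lm| dOmega = 2 for l > 0 and d_00 = 1/(4 pi) (monopole carries
# unit charge). Frozen from a 48000-point composite Gauss-Legendre quadrature
# of integral |y_lm| dOmega; the test suite re-derives them independently.
.dlm_norm <- local({
  C <- c(
    0.282094791773878,                                          # 0 0
    0.651470015406850, 0.651470015870560, 0.651470015406850,    # 1
    0.686468424647827, 0.686468423496538, 0.655529058485662,    # 2: -2 -1 0
    0.686468423496538, 0.686468424647827,                       # 2: 1 2
    0.719291233434387, 0.691895136958641, 0.700877437685230,    # 3: -3 -2 -1
    0.656134210899497, 0.700877437685230, 0.691895136958641,    # 3: 0 1 2
    0.719291233434387,                                          # 3: 3
    0.748998456701370, 0.706162517109071, 0.698795568562086,    # 4: -4 -3 -2
    0.708474651597857, 0.656209910304308, 0.708474651597857,    # 4: -1 0 1
    0.698795568562086, 0.706162517109071, 0.748998456701370)    # 4: 2 3 4
  lm <- do.call(rbind, lapply(0:4, function(l) cbind(l, seq(-l, l))))
  data.frame(l = lm[, 1], m = lm[, 2], C = C)
})

#' Density-normalized real spherical harmonic d_lm
#'
#' The angular functions of the Hansen-Coppens deformation density:
#' `d_lm = C_lm * y_lm` with C_lm fixed so that the integral of |d_lm|
#' over the sphere equals 2 for l > 0 (a population P_lm then transfers
#' one electron from the negative to the positive lobes), and
#' d_00 = 1/(4 pi).
#'
#' @inheritParams real_spherical_harmonic
#' @return Numeric vector of values.
#' @export
density_normalized_harmonic <- function(l, m, dir) {
  i <- which(.dlm_norm$l == l & .dlm_norm$m == m)
  if (!length(i)) stop("invalid (l, m): ", l, ",", m)
  .dlm_norm$C[i] * real_spherical_harmonic(l, m, dir)
}

#' Multipole index set permitted by a site-symmetry symbol
#'
#' Local site symmetries supported: `"1"` (none), `"m"` (mirror = local
#' xy plane, z -> -z), `"3m"` (three-fold axis along local z plus a
#' vertical mirror killing the sine terms) and `"cyl"` (cylindrical:
#' bond-directed m = 0 terms only). Selection rules: under z -> -z a
#' harmonic is even iff l + |m| is even; under a three-fold rotation it
#' is invariant iff |m| is a multiple of 3; the vertical mirror (y -> -y)
#' removes m < 0.
#'
#' @param site_symmetry One of "1", "m", "3m", "cyl".
#' @param l_max Highest l to include.
#' @return Data frame with columns `l`, `m` of permitted multipoles
#'   (l >= 1; the monopole population is handled separately).
#' @export
allowed_multipoles <- function(site_symmetry, l_max = 4) {
  if (!site_symmetry %in% c("1", "m", "3m", "cyl")) {
    stop("unknown site-symmetry symbol: ", site_symmetry)
  }
  lm <- do.call(rbind, lapply(seq_len(l_max), function(l) cbind(l = l, m = seq(-l, l))))
  lm <- as.data.frame(lm)
  keep <- switch(site_symmetry,
    "1"   = rep(TRUE, nrow(lm)),
    "m"   = (lm$l + abs(lm$m)) %% 2 == 0,
    "3m"  = (abs(lm$m) %% 3 == 0) & (lm$m >= 0),
    "cyl" = lm$m == 0)
  lm[keep, , drop = FALSE]
}

#' Point-group generator matrices for a site-symmetry symbol
#'
#' Used by tests to verify [allowed_multipoles()] by brute force.
#'
#' @param site_symmetry One of "1", "m", "3m".
#' @return List of 3x3 orthogonal matrices acting on local directions.
#' @export
site_symmetry_generators <- function(site_symmetry) {
  c3 <- 2 * pi / 3
  switch(site_symmetry,
    "1"  = list(),
    "m"  = list(diag(c(1, 1, -1))),
    "3m" = list(matrix(c(cos(c3), -sin(c3), 0, sin(c3), cos(c3), 0, 0, 0, 1),
                       3, 3, byrow = TRUE),
                diag(c(1, -1, 1))),
    stop("no generator list for symbol: ", site_symmetry))
}
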