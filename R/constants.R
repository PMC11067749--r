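# Fundamental constants (CODATA 2018). All crystallographic math in the
# package uses Angstrom / Angstrom^-1 and s = sin(theta)/lambda.
.const <- list(
  h      = 6.62607015e-34,   # Planck, J s
  m0     = 9.1093837015e-31, # electron rest mass, kg
  e      = 1.602176634e-19,  # elementary charge, C
  c      = 2.99792458e8,     # speed of light, m/s
  a0     = 0.529177210903    # Bohr radius, Angstrom
)

#' Mott-Bethe constant in the s = sin(theta)/lambda convention
#'
#' Derived from the Bohr radius as 1/(8 pi^2 a0), in Angstrom * Angstrom^-2,
#' so that `f_e(s) = mott_bethe_constant() * (Z - f_x(s)) / s^2` yields an
#' electron scattering amplitude in Angstrom. Numerically about 0.023934.
#'
#' @return Scalar constant (Angstrom^-1 units when divided by s^2 in A^-2).
#' @export
mott_bethe_constant <- function() {
  1 / (8 * pi^2 * .const$a0)
}

#' Relativistic electron wavelength
#'
#' de Broglie wavelength of an electron accelerated through `kv` kilovolts,
#' including the relativistic correction:
#' lambda = h / sqrt(2 m0 e V (1 + e V / (2 m0 c^2))).
#'
#' @param kv Accelerating voltage in kilovolts (> 0).
#' @param relativistic If `FALSE`, drop the relativistic correction term.
#' @return Wavelength in Angstrom. 200 kV gives 0.0251 A.
#' @export
electron_wavelength <- function(kv, relativistic = TRUE) {
  stopifnot(is.numeric(kv), kv > 0)
  V <- kv * 1e3
  corr <- if (relativistic) 1 + .const$e * V / (2 * .const$m0 * .const$c^2) else 1
  lam_m <- .const$h / sqrt(2 * .const$m0 * .const$e * V * corr)
  lam_m * 1e10
}

#' Relativistic mass factor gamma = 1 + eV/(m0 c^2)
#'
#' Used to scale the electron-crystal interaction in the dynamical theory.
#'
#' @param kv Accelerating voltage in kilovolts.
#' @return Dimensionless factor (1.391 at 200 kV).
#' @export
relativistic_gamma <- function(kv) {
  stopifnot(kv > 0)
  1 + .const$e * kv * 1e3 / (.const$m0 * .const$c^2)
}
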