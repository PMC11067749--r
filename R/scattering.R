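# Mott-Bethe conversion, Debye-Waller factors, and IAM pseudoatoms.

#' Mott-Bethe conversion of X-ray to electron scattering factors
#'
#' `f_e(s) = C (Z - f_x(s)) / s^2` with `C = 1/(8 pi^2 a0)` in the
#' s = sin(theta)/lambda convention. Valid for s > 0; the s = 0 monopole
#' limit of a neutral atom is finite but is not needed for reflection
#' data (the 000 beam is excluded throughout).
#'
#' @param Z Atomic number of the atom the form factor belongs to.
#' @param f_x X-ray form factor value(s) (electrons), may be complex.
#' @param s sin(theta)/lambda (A^-1), > 0, same length as `f_x`.
#' @return Electron scattering factor in Angstrom.
#' @export
mott_bethe <- function(Z, f_x, s) {
  if (any(s <= 0)) stop("mott_bethe requires s > 0 (000 beam excluded)")
  mott_bethe_constant() * (Z - f_x) / s^2
}

#' Debye-Waller attenuation factor
#'
#' Isotropic: `exp(-8 pi^2 U_iso s^2)`. Anisotropic:
#' `exp(-2 pi^2 sum_ij U_ij h_i h_j a*_i a*_j)` with `U_ij` in the
#' standard reciprocal-basis convention.
#'
#' @param cell A `unit_cell`.
#' @param site An `atom_site` (its `uiso`/`uaniso` is used).
#' @param hkl n x 3 index matrix (possibly non-integer after symmetry
#'   rotation).
#' @param check_psd Reject non-positive-semidefinite tensors (refinement
#'   trial steps disable the check and rely on residual rejection).
#' @return Attenuation factors in (0, 1].
#' @export
debye_waller <- function(cell, site, hkl, check_psd = TRUE) {
  H <- rbind_hkl(hkl)
  if (is.null(site$uaniso)) {
    s2 <- rowSums((H %*% cell$Gstar) * H) / 4   # s^2 = 1/(4 d^2)
    exp(-8 * pi^2 * site$uiso * s2)
  } else {
    astar <- sqrt(diag(cell$Gstar))
    U <- u6_to_mat(site$uaniso)
    if (check_psd &&
        min(eigen(U, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      stop("anisotropic U tensor not positive semidefinite")
    }
    M <- U * outer(astar, astar)
    exp(-2 * pi^2 * rowSums((H %*% M) * H))
  }
}

#' Spherical (IAM-like) pseudoatom model for an element
#'
#' A neutral independent-atom model: core + valence monopole populations
#' from the packaged shell table, no deformation terms, kappa = 1.
#'
#' @param label Site label.
#' @param element Element symbol.
#' @return A `multipole_model` with empty deformation table.
#' @export
iam_model <- function(label, element) {
  sh <- element_shells()[[element]]
  if (is.null(sh)) stop("no shell table for element ", element)
  multipole_model(label, element, P_val = sh$P_val, site_symmetry = "1")
}

#' IAM model set covering every site of a structure
#' @param structure A `crystal_structure`.
#' @return Named list of `multipole_model`.
#' @export
iam_models <- function(structure) {
  out <- lapply(structure$sites, function(s) iam_model(s$label, s$element))
  names(out) <- vapply(structure$sites, `[[`, "", "label")
  out
}
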