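# Synthetic-data generators: a 1-methyluracil-like fixture crystal in Ibam,
# ground-truth multipole parameter tiers, and seeded reflection simulation.
# Every generator is a pure function of (arguments, seed).

#' Fixture crystal structure (1-methyluracil-like, Ibam)
#'
#' A hand-built planar pyrimidinedione with an N-methyl group, placed in
#' a body-centred orthorhombic cell so that the molecule lies on the
#' z = 0 mirror plane (every atom except the out-of-plane methyl
#' hydrogen H7b) and N3-H3...O4 forms a linear intermolecular hydrogen
#' bond (H...O = 1.85 A) across an in-plane inversion centre. Cell
#' constants and coordinates are plausible literature-like values, not
#' data from any specific experiment; X-H distances follow standard
#' neutron values.
#'
#' @param h_adp Isotropic U for hydrogen atoms (A^2).
#' @return A `crystal_structure` with anisotropic non-H ADPs.
#' @export
fixture_structure <- function(h_adp = 0.028) {
  cell <- build_cell(13.3, 13.7, 6.20)
  sg <- packaged_space_group("Ibam")
  xyz <- list(
    N1  = c(0.238683, 0.168437, 0),
    C2  = c(0.342664, 0.169257, 0),
    O2  = c(0.388046, 0.246646, 0),
    N3  = c(0.394639, 0.082666, 0),
    H3  = c(0.473023, 0.082666, 0),
    C4  = c(0.342286, -0.004554, 0),
    O4  = c(0.387879, -0.082666, 0),
    C5  = c(0.234023, -0.003283, 0),
    H5  = c(0.192387, -0.071066, 0),
    C6  = c(0.185060, 0.082201, 0),
    H6  = c(0.103291, 0.083615, 0),
    C7  = c(0.184114, 0.261411, 0),
    H7a = c(0.104003, 0.247412, 0),
    H7b = c(0.204118, 0.302936, 0.143257))
  # plausible 100 K ADPs; mirror sites require U13 = U23 = 0
  u_nonh <- list(
    N1 = c(0.0140, 0.0125, 0.0185, 0.0012, 0, 0),
    C2 = c(0.0138, 0.0128, 0.0170, -0.0008, 0, 0),
    O2 = c(0.0185, 0.0150, 0.0260, -0.0030, 0, 0),
    N3 = c(0.0130, 0.0132, 0.0185, 0.0010, 0, 0),
    C4 = c(0.0140, 0.0126, 0.0165, 0.0006, 0, 0),
    O4 = c(0.0190, 0.0145, 0.0255, 0.0032, 0, 0),
    C5 = c(0.0145, 0.0135, 0.0180, -0.0006, 0, 0),
    C6 = c(0.0148, 0.0138, 0.0182, 0.0008, 0, 0),
    C7 = c(0.0165, 0.0150, 0.0230, 0.0030, 0, 0))
  sites <- lapply(names(xyz), function(lb) {
    el <- substr(lb, 1, 1)
    if (el == "H") {
      atom_site(lb, "H", xyz[[lb]], uiso = h_adp)
    } else {
      atom_site(lb, el, xyz[[lb]], uaniso = u_nonh[[lb]])
    }
  })
  crystal_structure(cell, sg, sites)
}

# local-frame specs for the fixture pseudoatoms: non-H atoms get x toward a
# bonded neighbour and z perpendicular to the molecular plane (mirror = local
# xy plane); hydrogens get z along the bond (cylindrical); the methyl carbon
# gets z along the three-fold N1-C7 axis.
.fixture_frames <- function() {
  list(
    N1  = list(ref1 = "C2", ref2 = "C6", axis1 = "x", axis2 = "y"),
    C2  = list(ref1 = "O2", ref2 = "N1", axis1 = "x", axis2 = "y"),
    O2  = list(ref1 = "C2", ref2 = "N3", axis1 = "x", axis2 = "y"),
    N3  = list(ref1 = "H3", ref2 = "C2", axis1 = "x", axis2 = "y"),
    H3  = list(ref1 = "N3", ref2 = "C2", axis1 = "z", axis2 = "x"),
    C4  = list(ref1 = "O4", ref2 = "N3", axis1 = "x", axis2 = "y"),
    O4  = list(ref1 = "C4", ref2 = "C5", axis1 = "x", axis2 = "y"),
    C5  = list(ref1 = "C6", ref2 = "C4", axis1 = "x", axis2 = "y"),
    H5  = list(ref1 = "C5", ref2 = "C4", axis1 = "z", axis2 = "x"),
    C6  = list(ref1 = "C5", ref2 = "N1", axis1 = "x", axis2 = "y"),
    H6  = list(ref1 = "C6", ref2 = "N1", axis1 = "z", axis2 = "x"),
    C7  = list(ref1 = "N1", ref2 = "H7a", axis1 = "z", axis2 = "x"),
    H7a = list(ref1 = "C7", ref2 = "N1", axis1 = "z", axis2 = "x"),
    H7b = list(ref1 = "C7", ref2 = "N1", axis1 = "z", axis2 = "x"))
}

#' Ground-truth multipole parameter tiers for the fixture
#'
#' Three internally consistent Hansen-Coppens parameter sets emulating a
#' databank-transferred model, a gas-phase tailored model and a
#' crystal-field model. All tiers are neutral (populations sum to the
#' electron count); they differ only in deformation populations, with
#' the largest differences deliberately placed on the hydrogen-bond
#' actors H3 and O4 (bond-directed dipoles), so tier comparisons probe
#' sensitivity to intermolecular polarization.
#'
#' @param level "databank", "tailored" or "crystal".
#' @return Named list of `multipole_model` covering every fixture site.
#' @export
fixture_multipoles <- function(level = c("databank", "tailored", "crystal")) {
  level <- match.arg(level)
  fr <- .fixture_frames()
  pv <- c(N1 = 5.25, C2 = 3.70, O2 = 6.45, N3 = 5.20, H3 = 0.85,
          C4 = 3.75, O4 = 6.50, C5 = 4.05, H5 = 0.85, C6 = 3.95,
          H6 = 0.85, C7 = 4.05, H7a = 0.85, H7b = 0.85)
  kap <- c(C = 1.010, N = 1.000, O = 0.985, H = 1.150)
  kpp <- c(C = 0.920, N = 0.960, O = 1.000, H = 1.200)
  # base (databank-like) deformation populations
  ring_plm <- function(d11, q20, q22) {
    data.frame(l = c(1, 2, 2, 3, 4), m = c(1, 0, 2, 1, 0),
               P = c(d11, q20, q22, 0.02, 0.01))
  }
  h_plm <- function(d10) data.frame(l = c(1, 2), m = c(0, 0), P = c(d10, 0.03))
  plm <- list(
    N1  = ring_plm(0.03, -0.06, 0.02),
    C2  = ring_plm(0.04, -0.10, 0.03),
    O2  = ring_plm(0.08, -0.08, 0.02),
    N3  = ring_plm(0.03, -0.06, 0.02),
    H3  = h_plm(0.12),
    C4  = ring_plm(0.04, -0.10, 0.03),
    O4  = ring_plm(0.08, -0.08, 0.02),
    C5  = ring_plm(0.03, -0.09, 0.02),
    H5  = h_plm(0.12),
    C6  = ring_plm(0.03, -0.09, 0.02),
    H6  = h_plm(0.12),
    C7  = data.frame(l = c(1, 2, 3, 3), m = c(0, 0, 0, 3),
                     P = c(0.05, -0.04, 0.02, 0.06)),
    H7a = h_plm(0.10),
    H7b = h_plm(0.10))
  # tier perturbations, concentrated on the hydrogen-bond dipoles
  bump <- function(tab, l, m, dP) {
    i <- which(tab$l == l & tab$m == m)
    tab$P[i] <- tab$P[i] + dP
    tab
  }
  if (level == "tailored") {
    plm$H3 <- bump(plm$H3, 1, 0, -0.040)
    plm$O4 <- bump(plm$O4, 1, 1, -0.030)
    plm$O2 <- bump(plm$O2, 1, 1, -0.010)
  } else if (level == "crystal") {
    plm$H3 <- bump(plm$H3, 1, 0, 0.050)
    plm$O4 <- bump(plm$O4, 1, 1, 0.040)
    plm$O2 <- bump(plm$O2, 1, 1, 0.010)
  }
  sym <- function(lb) {
    el <- substr(lb, 1, 1)
    if (el == "H") "cyl" else if (lb == "C7") "3m" else "m"
  }
  out <- lapply(names(pv), function(lb) {
    el <- substr(lb, 1, 1)
    multipole_model(lb, el, P_val = pv[[lb]], plm = plm[[lb]],
                    kappa = kap[[el]], kappa_prime = kpp[[el]],
                    site_symmetry = sym(lb), frame = fr[[lb]],
                    l_max = if (el == "H") 2 else 4)
  })
  names(out) <- names(pv)
  out
}

#' Simulate a reflection data set from a structure and model
#'
#' Generates the symmetry-unique reflection list to `d_min`, computes
#' model structure factors, applies an optional incompleteness mask
#' (an orientation-cone exclusion around c* emulating a missing wedge,
#' plus seeded random thinning to the target completeness) and optional
#' Gaussian noise on intensities with sigma = max(sigma_floor, c_frac *
#' F^2). With `noise = "none"` amplitudes and model phases are returned
#' (suitable for phase-constrained multipole fitting).
#'
#' @param structure A `crystal_structure`.
#' @param models Model set used for generation.
#' @param d_min Resolution limit (A).
#' @param radiation "electron" or "xray".
#' @param completeness Target completeness in (0, 1].
#' @param cone_deg Semi-angle (degrees) of the exclusion cone around c*
#'   (0 disables it).
#' @param noise "none" or "gaussianF2".
#' @param sigma_floor Floor of sigma(F^2).
#' @param c_frac Fractional part of sigma(F^2).
#' @param seed Integer seed (all randomness derives from it).
#' @return List with `refl` (a `reflection_set`; intensities when noisy,
#'   phased amplitudes when noise-free) and `truth` (generation ledger:
#'   structure, models, radiation, seed, true F).
#' @export
simulate_reflections <- function(structure, models, d_min = 0.8,
                                 radiation = "electron",
                                 completeness = 1, cone_deg = 0,
                                 noise = c("none", "gaussianF2"),
                                 sigma_floor = 1.0, c_frac = 0.02,
                                 seed = 1) {
  noise <- match.arg(noise)
  stopifnot(completeness > 0, completeness <= 1)
  uni <- unique_reflections(structure$cell, structure$sg, d_min)
  H <- as.matrix(uni[, c("h", "k", "l")])
  keep <- rep(TRUE, nrow(H))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (cone_deg > 0) {
    g <- recip_cartesian(structure$cell, H)
    cosang <- abs(g[, 3]) / sqrt(rowSums(g^2))
    keep <- keep & cosang < cos(cone_deg * pi / 180)
  }
  frac_now <- mean(keep)
  if (completeness < frac_now) {
    idx <- which(keep)
    n_drop <- round((frac_now - completeness) * nrow(H))
    keep[sample(idx, n_drop)] <- FALSE
  }
  H <- H[keep, , drop = FALSE]
  Fc <- structure_factor(structure, models, H, radiation)
  if (noise == "none") {
    refl <- reflection_set(H, structure$cell, Fobs = Mod(Fc),
                           sigma = rep(0, nrow(H)), phase = Arg(Fc))
  } else {
    I0 <- Mod(Fc)^2
    sig <- pmax(sigma_floor, c_frac * I0)
    refl <- reflection_set(H, structure$cell,
                           Iobs = I0 + stats::rnorm(length(I0)) * sig,
                           sigma = sig)
  }
  list(refl = refl,
       truth = list(structure = structure, models = models,
                    radiation = radiation, F_true = Fc, seed = seed,
                    d_min = d_min))
}

#' Simulate dynamical diffraction frames
#'
#' Generates precession-averaged Bloch-wave frame intensities for a set
#' of beam orientations (by default one [001] zone-axis frame plus
#' off-zone tilts), applies per-frame scales and Gaussian noise, and
#' records the ground truth. Each frame also carries its kinematical
#' deviation: an intensity-weighted amplitude R factor between the
#' dynamical pattern and scaled kinematical |F_e|, which is largest for
#' zone-axis frames where many strong beams are coupled.
#'
#' @param structure A `crystal_structure`.
#' @param models Scattering model set used for generation.
#' @param t_nm True crystal thickness (nm).
#' @param orientations List of unit beam directions; `NULL` gives
#'   `n_frames` defaults (zone axis + tilts).
#' @param n_frames Number of default orientations.
#' @param phi_deg Precession semi-angle (degrees).
#' @param noise_frac Fractional Gaussian noise on intensities (0 = none).
#' @param kv Voltage (kilovolts).
#' @param d_min,S_max,RS_max Beam-selection settings.
#' @param n_azimuth Precession azimuth samples.
#' @param crystal Crystal tag attached to every frame.
#' @param seed Integer seed.
#' @return List with `frames` (for [refine_thickness_scale()]) and
#'   `truth` (t_nm, scales, kin_deviation per frame, seed).
#' @export
simulate_frames <- function(structure, models, t_nm = 120,
                            orientations = NULL, n_frames = 4,
                            phi_deg = 0.7, noise_frac = 0.02, kv = 200,
                            d_min = 1.1, S_max = 0.012, RS_max = 0.75,
                            n_azimuth = 24, crystal = "xtal1", seed = 1) {
  lambda <- electron_wavelength(kv)
  if (is.null(orientations)) {
    zone <- zone_axis_orientation(structure$cell, c(0, 0, 1))
    orientations <- c(list(zone), lapply(seq_len(n_frames - 1), function(i) {
      tilt_orientation(zone, 2.5 + 1.5 * i, 47 * i)
    }))
  }
  cand <- all_reflections(structure$cell, structure$sg, d_min)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frames <- list()
  scales <- numeric(0)
  kin_dev <- numeric(0)
  for (fi in seq_along(orientations)) {
    dir <- orientations[[fi]]
    beams <- select_beams(structure$cell, cand, dir, lambda, phi_deg,
                          d_min, S_max, RS_max)
    pat <- precession_average(structure, models, beams, dir, kv, t_nm,
                              phi_deg, n_azimuth)
    I_dyn <- pat$I[-1]
    H <- as.matrix(pat[-1, c("h", "k", "l")])
    # kinematical deviation: intensity-weighted amplitude R between the
    # dynamical pattern and scaled kinematical amplitudes (strong beams
    # carry the multiple-scattering redistribution)
    Fe <- Mod(structure_factor(structure, models, H, "electron"))
    A_dyn <- sqrt(pmax(0, I_dyn))
    w <- I_dyn
    sc_kin <- sum(w * A_dyn * Fe) / sum(w * Fe^2)
    kin_dev <- c(kin_dev, 100 * sum(w * abs(A_dyn - sc_kin * Fe)) / sum(w * A_dyn))
    sc <- stats::runif(1, 0.8, 1.2)
    I_sc <- sc * I_dyn
    sig <- pmax(noise_frac * I_sc, 1e-12)
    I_obs <- if (noise_frac > 0) I_sc + stats::rnorm(length(I_sc)) * sig else I_sc
    frames[[fi]] <- list(beam_dir = dir, hkl = H, Iobs = I_obs, sigma = sig,
                         crystal = crystal, phi_deg = phi_deg,
                         n_azimuth = n_azimuth)
    scales <- c(scales, sc)
  }
  list(frames = frames,
       truth = list(t_nm = t_nm, scales = scales, kin_deviation = kin_dev,
                    seed = seed, kv = kv))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
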