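# N-beam Bloch-wave dynamical intensities for a parallel or precessing
# incident beam, excitation-error beam selection, and thickness/scale
# refinement against frame intensities. No absorption (the structure
# matrix is Hermitian).

#' Beam direction of a real-space zone axis
#'
#' @param cell A `unit_cell`.
#' @param uvw Integer zone-axis indices.
#' @return Unit vector (Cartesian frame) along the zone axis; the
#'   incident beam travels along this direction.
#' @export
zone_axis_orientation <- function(cell, uvw) {
  v <- as.numeric(cell$ortho %*% uvw)
  v / sqrt(sum(v^2))
}

#' Tilt a beam direction
#'
#' Rotates `dir` by `tilt_deg` about an axis perpendicular to it
#' (azimuth `azimuth_deg` in the perpendicular plane).
#'
#' @param dir Unit beam direction.
#' @param tilt_deg Tilt angle (degrees).
#' @param azimuth_deg Azimuth of the tilt axis (degrees).
#' @return Tilted unit vector.
#' @export
tilt_orientation <- function(dir, tilt_deg, azimuth_deg = 0) {
  n0 <- dir / sqrt(sum(dir^2))
  ref <- if (abs(n0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n0) * n0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n0[2] * e1[3] - n0[3] * e1[2],
          n0[3] * e1[1] - n0[1] * e1[3],
          n0[1] * e1[2] - n0[2] * e1[1])
  th <- tilt_deg * pi / 180
  az <- azimuth_deg * pi / 180
  cos(th) * n0 + sin(th) * (cos(az) * e1 + sin(az) * e2)
}

#' Excitation error S_g
#'
#' Signed distance of reciprocal-lattice points from the Ewald sphere:
#' `S_g = (K^2 - |k0 + g|^2) / (2K)` with `k0 = K * dir`, `K = 1/lambda`.
#' Positive when g lies inside the sphere. For a zone-axis orientation
#' and g in the zero layer this reduces to `-g^2 lambda / 2`.
#'
#' @param cell A `unit_cell`.
#' @param dir Incident-beam unit direction (Cartesian frame).
#' @param lambda Wavelength (A).
#' @param hkl n x 3 index matrix.
#' @return S_g in A^-1.
#' @export
excitation_error <- function(cell, dir, lambda, hkl) {
  K <- 1 / lambda
  k0 <- K * dir / sqrt(sum(dir^2))
  g <- recip_cartesian(cell, hkl)
  kg <- g + matrix(k0, nrow(g), 3, byrow = TRUE)
  (K^2 - rowSums(kg^2)) / (2 * K)
}

#' Relative excitation error RS_g over a precession cycle
#'
#' `RS_g = |S_g(central)| / max_alpha |S_g(alpha)|` where the incident
#' beam precesses on a cone of semi-angle `phi_deg` about the central
#' direction; the azimuthal maximum is located on a dense grid.
#'
#' @param cell A `unit_cell`.
#' @param dir Central beam direction.
#' @param lambda Wavelength (A).
#' @param phi_deg Precession semi-angle (degrees), > 0.
#' @param hkl n x 3 index matrix.
#' @param n_azimuth Azimuth grid size (>= 360).
#' @return RS_g values (dimensionless).
#' @export
relative_excitation_error <- function(cell, dir, lambda, phi_deg, hkl,
                                      n_azimuth = 720) {
  if (phi_deg <= 0) stop("RS_g undefined for zero precession angle")
  S0 <- abs(excitation_error(cell, dir, lambda, hkl))
  Smax <- rep(0, nrow(rbind_hkl(hkl)))
  for (az in (seq_len(n_azimuth) - 1) * 360 / n_azimuth) {
    nd <- tilt_orientation(dir, phi_deg, az)
    Smax <- pmax(Smax, abs(excitation_error(cell, nd, lambda, hkl)))
  }
  S0 / Smax
}

#' Full reflection list (all equivalents) to a resolution limit
#'
#' Unlike [unique_reflections()], keeps every symmetry-equivalent index;
#' used to build dynamical beam candidates.
#'
#' @inheritParams unique_reflections
#' @return Data frame h, k, l, d.
#' @export
all_reflections <- function(cell, sg, d_min) {
  lim <- ceiling(cell$abc / d_min) + 1
  grid <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2], l = -lim[3]:lim[3])
  H <- as.matrix(grid)
  H <- H[rowSums(H != 0) > 0, , drop = FALSE]
  d <- d_spacing(cell, H)
  keep <- d >= d_min & !systematic_absent(sg, H)
  data.frame(h = H[keep, 1], k = H[keep, 2], l = H[keep, 3], d = d[keep])
}

#' Select dynamical beams by excitation-error criteria
#'
#' Keeps candidate reflections with d >= d_min, |S_g| <= S_max and (for
#' a precessing beam) RS_g <= RS_max, prepends the 000 beam and orders
#' deterministically by |g| then lexicographic hkl.
#'
#' @param cell A `unit_cell`.
#' @param candidates Data frame with h, k, l (e.g. [all_reflections()]).
#' @param dir Central beam direction.
#' @param lambda Wavelength (A).
#' @param phi_deg Precession semi-angle (0 disables the RS_g cut).
#' @param d_min Resolution cutoff (A).
#' @param S_max Maximum |excitation error| (A^-1).
#' @param RS_max Maximum relative excitation error.
#' @param max_beams Hard cap on the matrix size.
#' @return Data frame of class `beam_set`: h, k, l, d, S_g, RS_g (000
#'   row first).
#' @export
select_beams <- function(cell, candidates, dir, lambda, phi_deg = 0,
                         d_min = 0.56, S_max = 0.02, RS_max = 0.75,
                         max_beams = 500) {
  stopifnot(d_min > 0, S_max > 0, RS_max > 0)
  H <- as.matrix(candidates[, c("h", "k", "l")])
  d <- d_spacing(cell, H)
  S <- excitation_error(cell, dir, lambda, H)
  keep <- d >= d_min & abs(S) <= S_max
  RS <- rep(NA_real_, nrow(H))
  if (phi_deg > 0 && any(keep)) {
    RS[keep] <- relative_excitation_error(cell, dir, lambda, phi_deg,
                                          H[keep, , drop = FALSE])
    keep[keep] <- RS[keep] <= RS_max
  }
  if (!any(keep)) stop("no beams beyond 000 pass the selection criteria")
  H <- H[keep, , drop = FALSE]
  gl <- 1 / d[keep]
  ord <- order(gl, H[, 1], H[, 2], H[, 3])
  out <- data.frame(h = c(0, H[ord, 1]), k = c(0, H[ord, 2]),
                    l = c(0, H[ord, 3]), d = c(Inf, d[keep][ord]),
                    S_g = c(0, S[keep][ord]), RS_g = c(NA, RS[keep][ord]))
  if (nrow(out) > max_beams) {
    stop("beam count ", nrow(out), " exceeds the cap of ", max_beams)
  }
  class(out) <- c("beam_set", "data.frame")
  out
}

# Fourier potential coefficients U_g (A^-2) for all pairwise beam
# differences: U_g = gamma * F_e(g) / (pi V)
.structure_matrix_U <- function(structure, models, beams, gamma) {
  H <- as.matrix(beams[, c("h", "k", "l")])
  n <- nrow(H)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i != idx$j, ]
  D <- H[idx$i, , drop = FALSE] - H[idx$j, , drop = FALSE]
  key <- apply(D, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  Duni <- D[uk, , drop = FALSE]
  Fd <- structure_factor(structure, models, Duni, "electron")
  Ud <- gamma * Fd / (pi * structure$cell$volume)
  names(Ud) <- key[uk]
  U <- matrix(0i, n, n)
  U[cbind(idx$i, idx$j)] <- Ud[key]
  U
}

#' Bloch-wave intensities for one beam configuration
#'
#' Diagonalizes the (Hermitian, zero-absorption) structure matrix
#' `A = diag(S_g) + U_(g-h) / (2K)` and propagates the entrance beam:
#' `I_g(t) = |sum_j C_gj conj(C_0j) exp(2 pi i gamma_j t)|^2`.
#' Intensities sum to 1 at every thickness.
#'
#' @param S_g Excitation errors (A^-1), first entry the 000 beam (0).
#' @param U Complex Hermitian matrix of potential coefficients (A^-2)
#'   with zero diagonal, `U[i,j] = U_(g_i - g_j)`.
#' @param K 1/lambda (A^-1).
#' @param t_nm Crystal thickness in nm (may be a vector).
#' @return Matrix of intensities (length(t_nm) x n_beams).
#' @export
bloch_intensities <- function(S_g, U, K, t_nm) {
  n <- length(S_g)
  stopifnot(nrow(U) == n, ncol(U) == n)
  if (max(abs(U - Conj(t(U)))) > 1e-10 * max(1, max(abs(U)))) {
    stop("structure matrix not Hermitian (absorption is not supported)")
  }
  A <- U / (2 * K)
  diag(A) <- S_g
  eg <- eigen(A, symmetric = TRUE)
  C <- eg$vectors
  eps <- Conj(C[1, ])
  tA <- t_nm * 10
  out <- matrix(0, length(tA), n)
  for (ti in seq_along(tA)) {
    psi <- C %*% (exp(2i * pi * eg$values * tA[ti]) * eps)
    out[ti, ] <- Mod(psi)^2
  }
  out
}

#' Dynamical intensities for a frame (with optional precession average)
#'
#' Builds the beam structure matrix once and returns a closure over the
#' thickness so that thickness refinement can reuse the eigensystems.
#'
#' @param structure A `crystal_structure`.
#' @param models Scattering model set.
#' @param beams A `beam_set` from [select_beams()].
#' @param dir Central beam direction.
#' @param kv Accelerating voltage (kilovolts).
#' @param phi_deg Precession semi-angle (0 = static beam).
#' @param n_azimuth Azimuth samples for the precession average.
#' @return List with `intensity(t_nm)` (function returning per-beam
#'   precession-averaged intensities, 000 first) and `beams`.
#' @export
dyn_frame_solver <- function(structure, models, beams, dir, kv,
                             phi_deg = 0, n_azimuth = 64) {
  lambda <- electron_wavelength(kv)
  K <- 1 / lambda
  gamma <- relativistic_gamma(kv)
  U <- .structure_matrix_U(structure, models, beams, gamma)
  H <- as.matrix(beams[, c("h", "k", "l")])
  dirs <- if (phi_deg > 0) {
    lapply((seq_len(n_azimuth) - 1) * 360 / n_azimuth,
           function(az) tilt_orientation(dir, phi_deg, az))
  } else list(dir)
  eigs <- lapply(dirs, function(nd) {
    S <- excitation_error(structure$cell, nd, lambda, H)
    S[1] <- 0
    A <- U / (2 * K)
    diag(A) <- S
    eg <- eigen(A, symmetric = TRUE)
    list(C = eg$vectors, g = eg$values, eps = Conj(eg$vectors[1, ]))
  })
  intensity <- function(t_nm) {
    tA <- t_nm * 10
    acc <- numeric(nrow(H))
    for (e in eigs) {
      psi <- e$C %*% (exp(2i * pi * e$g * tA) * e$eps)
      acc <- acc + as.numeric(Mod(psi)^2)
    }
    acc / length(eigs)
  }
  list(intensity = intensity, beams = beams, lambda = lambda, K = K)
}

#' Precession-averaged dynamical intensities
#'
#' @inheritParams dyn_frame_solver
#' @param t_nm Crystal thickness (nm).
#' @return Data frame: beams columns plus `I` (averaged intensities).
#' @export
precession_average <- function(structure, models, beams, dir, kv, t_nm,
                               phi_deg = 0, n_azimuth = 64) {
  if (phi_deg > 0 && n_azimuth < 4) stop("need at least 4 azimuth samples")
  sol <- dyn_frame_solver(structure, models, beams, dir, kv, phi_deg, n_azimuth)
  out <- beams
  out$I <- sol$intensity(t_nm)
  out
}

#' Refine crystal thickness and per-frame scales
#'
#' Least-squares fit of one thickness per crystal and one scale per
#' frame against frame amplitude data (sqrt of intensities). Scales have
#' a closed-form optimum for a given thickness; the thickness is found
#' by golden-section search per crystal.
#'
#' @param frames List of frames, each a list with `beam_dir`, `hkl`
#'   (matrix of non-000 beams), `Iobs`, `sigma`, `crystal` (tag),
#'   `phi_deg`, optional `n_azimuth`.
#' @param structure A `crystal_structure`.
#' @param models Scattering model set.
#' @param kv Voltage (kilovolts).
#' @param t_range Search interval for the thickness (nm).
#' @param d_min,S_max,RS_max Beam-selection settings used to rebuild each
#'   frame's beam set.
#' @return List: `thickness` (named by crystal), `scales` (per frame),
#'   `R_obs`, `R_all`, `per_frame` (data frame with per-frame R).
#' @export
refine_thickness_scale <- function(frames, structure, models, kv,
                                   t_range = c(20, 300), d_min = 0.56,
                                   S_max = 0.02, RS_max = 0.75) {
  lambda <- electron_wavelength(kv)
  solvers <- lapply(frames, function(fr) {
    beams <- data.frame(h = fr$hkl[, 1], k = fr$hkl[, 2], l = fr$hkl[, 3])
    d <- d_spacing(structure$cell, fr$hkl)
    S <- excitation_error(structure$cell, fr$beam_dir, lambda, fr$hkl)
    bs <- data.frame(h = c(0, beams$h), k = c(0, beams$k), l = c(0, beams$l),
                     d = c(Inf, d), S_g = c(0, S), RS_g = NA)
    class(bs) <- c("beam_set", "data.frame")
    dyn_frame_solver(structure, models, bs, fr$beam_dir, kv,
                     phi_deg = fr$phi_deg,
                     n_azimuth = if (is.null(fr$n_azimuth)) 64 else fr$n_azimuth)
  })
  crystals <- unique(vapply(frames, `[[`, "", "crystal"))
  thickness <- numeric(0)
  scales <- rep(NA_real_, length(frames))
  frame_cost <- function(fi, t_nm) {
    Ic <- solvers[[fi]]$intensity(t_nm)[-1]
    Ao <- sqrt(pmax(0, frames[[fi]]$Iobs))
    Ac <- sqrt(pmax(0, Ic))
    sc <- sum(Ao * Ac) / max(sum(Ac^2), 1e-300)
    list(ss = sum((Ao - sc * Ac)^2), scale = sc, Ac = Ac, Ao = Ao)
  }
  for (cr in crystals) {
    idx <- which(vapply(frames, `[[`, "", "crystal") == cr)
    obj <- function(t_nm) sum(vapply(idx, function(fi) frame_cost(fi, t_nm)$ss, 0))
    opt <- stats::optimize(obj, t_range, tol = 1e-3)
    if (opt$minimum < t_range[1] + 1 || opt$minimum > t_range[2] - 1) {
      warning("thickness for crystal ", cr, " at the search boundary")
    }
    thickness[cr] <- opt$minimum
    for (fi in idx) scales[fi] <- frame_cost(fi, opt$minimum)$scale
  }
  # assemble amplitude residual statistics
  Ao_all <- c(); Ac_all <- c(); obs_all <- c(); fr_R <- numeric(length(frames))
  for (fi in seq_along(frames)) {
    fc <- frame_cost(fi, thickness[[frames[[fi]]$crystal]])
    Ao_all <- c(Ao_all, fc$Ao)
    Ac_all <- c(Ac_all, fc$scale * fc$Ac)
    obs_all <- c(obs_all, frames[[fi]]$Iobs > 3 * frames[[fi]]$sigma)
    fr_R[fi] <- 100 * sum(abs(fc$Ao - fc$scale * fc$Ac)) / sum(fc$Ao)
  }
  list(thickness = thickness, scales = scales,
       R_obs = if (any(obs_all)) r_factor(Ao_all, Ac_all, 1, obs_all, "obs") else NA,
       R_all = r_factor(Ao_all, Ac_all, 1),
       per_frame = data.frame(frame = seq_along(frames),
                              crystal = vapply(frames, `[[`, "", "crystal"),
                              scale = scales, R = fr_R))
}

#' Write dynamical frames to a documented text format
#'
#' One file per call; frames separated by `frame` header lines:
#' `frame <crystal> <phi_deg> <lambda> <bx> <by> <bz>` followed by
#' `h k l I sigma` rows.
#'
#' @param frames Frame list (see [refine_thickness_scale()]).
#' @param lambda Wavelength (A), stored in headers.
#' @param path Output path.
#' @export
write_frames <- function(frames, lambda, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# aspherED dynamical frame file", con)
  for (fr in frames) {
    writeLines(sprintf("frame %s %.4f %.8f %.8f %.8f %.8f", fr$crystal,
                       fr$phi_deg, lambda, fr$beam_dir[1], fr$beam_dir[2],
                       fr$beam_dir[3]), con)
    writeLines(sprintf("%5d %5d %5d %14.8g %12.6g", fr$hkl[, 1], fr$hkl[, 2],
                       fr$hkl[, 3], fr$Iobs, fr$sigma), con)
  }
  invisible(path)
}

#' Read a dynamical frame file written by [write_frames()]
#' @param path File path.
#' @return List with `frames` and `lambda`.
#' @export
read_frames <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  frames <- list()
  lambda <- NA_real_
  cur <- NULL
  flush_cur <- function(cur, frames) {
    if (!is.null(cur)) frames[[length(frames) + 1]] <- cur
    frames
  }
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "frame") {
      frames <- flush_cur(cur, frames)
      lambda <- as.numeric(tok[4])
      cur <- list(crystal = tok[2], phi_deg = as.numeric(tok[3]),
                  beam_dir = as.numeric(tok[5:7]),
                  hkl = matrix(0, 0, 3), Iobs = numeric(0), sigma = numeric(0))
    } else {
      v <- as.numeric(tok)
      cur$hkl <- rbind(cur$hkl, v[1:3])
      cur$Iobs <- c(cur$Iobs, v[4])
      cur$sigma <- c(cur$sigma, v[5])
    }
  }
  frames <- flush_cur(cur, frames)
  list(frames = frames, lambda = lambda)
}
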