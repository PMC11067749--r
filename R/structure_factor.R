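# Kinematical crystal structure factors for IAM / multipole models, for
# X-ray or electron radiation, including symmetry and Debye-Waller factors.

#' Laue-group equivalents of a reflection
#'
#' Applies the rotation parts of all space-group operators plus the
#' Friedel inversion.
#'
#' @param sg A `space_group`.
#' @param hkl Integer triple.
#' @return Matrix of distinct equivalent index triples (rows).
#' @export
laue_equivalents <- function(sg, hkl) {
  h <- as.numeric(hkl)
  eq <- t(vapply(sg$ops, function(op) as.numeric(h %*% op$R), numeric(3)))
  eq <- rbind(eq, -eq)
  unique(round(eq))
}

#' Systematic absence test
#'
#' A reflection is systematically absent when some operator fixes its
#' index (h R = h) but carries an incompatible translation
#' (exp(2 pi i h.t) != 1).
#'
#' @param sg A `space_group`.
#' @param hkl n x 3 index matrix.
#' @return Logical vector.
#' @export
systematic_absent <- function(sg, hkl) {
  H <- rbind_hkl(hkl)
  out <- rep(FALSE, nrow(H))
  for (op in sg$ops) {
    fixes <- rowSums(abs(H %*% op$R - H)) < 1e-9
    if (any(fixes)) {
      ph <- (H[fixes, , drop = FALSE] %*% op$t) %% 1
      out[fixes] <- out[fixes] | (pmin(ph, 1 - ph) > 1e-9)
    }
  }
  out
}

#' Symmetry-unique reflection list to a resolution limit
#'
#' Enumerates all integer triples with d >= d_min, drops 000 and
#' systematic absences, and keeps one lexicographically maximal
#' representative per Laue-equivalence class.
#'
#' @param cell A `unit_cell`.
#' @param sg A `space_group`.
#' @param d_min Resolution limit (Angstrom).
#' @return Data frame with columns `h`, `k`, `l`, `d`, `mult`
#'   (Laue multiplicity), sorted by descending d.
#' @export
unique_reflections <- function(cell, sg, d_min) {
  stopifnot(d_min > 0)
  lim <- ceiling(cell$abc / d_min) + 1
  grid <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2], l = -lim[3]:lim[3])
  H <- as.matrix(grid)
  H <- H[rowSums(H != 0) > 0, , drop = FALSE]
  d <- d_spacing(cell, H)
  H <- H[d >= d_min, , drop = FALSE]
  d <- d[d >= d_min]
  keep <- !systematic_absent(sg, H)
  H <- H[keep, , drop = FALSE]; d <- d[keep]
  key <- apply(H, 1, paste, collapse = ",")
  seen <- new.env(parent = emptyenv())
  rows <- integer(0); mult <- integer(0)
  for (i in seq_len(nrow(H))) {
    if (!is.null(seen[[key[i]]])) next
    eq <- laue_equivalents(sg, H[i, ])
    ek <- apply(eq, 1, paste, collapse = ",")
    for (k in ek) seen[[k]] <- TRUE
    # lexicographically maximal representative (h, then k, then l)
    ord <- order(eq[, 1], eq[, 2], eq[, 3], decreasing = TRUE)
    rep_h <- eq[ord[1], ]
    rows <- c(rows, i); mult <- c(mult, nrow(eq))
    H[i, ] <- rep_h
  }
  out <- data.frame(h = H[rows, 1], k = H[rows, 2], l = H[rows, 3],
                    d = d[rows], mult = mult)
  out[order(-out$d, out$h, out$k, out$l), , drop = FALSE]
}

#' Per-atom structure-factor contributions
#'
#' Computes the complex contribution of every asymmetric-unit site to
#' every reflection:
#' `F(h) = sum_a w_a sum_ops f_a(h R) T_a(h R) exp(2 pi i (h.t + (h R).x_a))`
#' with `w_a = occupancy * multiplicity / |ops|` (exact on special
#' positions), the form factor evaluated with the scattering direction
#' rotated into the atom's local frame, and, for electron radiation,
#' the Mott-Bethe conversion applied per atom.
#'
#' @param structure A `crystal_structure`.
#' @param models Named list of `multipole_model`, one per site label.
#' @param hkl n x 3 integer index matrix.
#' @param radiation "xray" or "electron".
#' @param sites Optional character vector of site labels: compute only
#'   those columns (local frames still see the full structure).
#' @param check_psd Passed to [debye_waller()].
#' @return Complex matrix (n_reflections x n_sites); row sums are the
#'   crystal structure factors.
#' @export
structure_factor_matrix <- function(structure, models, hkl,
                                    radiation = c("xray", "electron"),
                                    sites = NULL, check_psd = TRUE) {
  radiation <- match.arg(radiation)
  H <- rbind_hkl(hkl)
  cell <- structure$cell
  nref <- nrow(H)
  labs <- vapply(structure$sites, `[[`, "", "label")
  if (is.null(sites)) sites <- labs
  if (!all(sites %in% labs)) stop("unknown site label(s) requested")
  if (!all(sites %in% names(models))) {
    stop("missing form-factor model for site(s): ",
         paste(setdiff(sites, names(models)), collapse = ", "))
  }
  s <- 1 / (2 * d_spacing(cell, H))
  nops <- length(structure$sg$ops)
  Fmat <- matrix(0i, nref, length(sites), dimnames = list(NULL, sites))
  Rloc <- lapply(sites, function(lb) build_local_frame(structure, lb, models[[lb]]$frame))
  names(Rloc) <- sites
  for (ai in seq_along(sites)) {
    site <- structure$sites[[match(sites[ai], labs)]]
    model <- models[[site$label]]
    w <- site$occupancy * site$multiplicity / nops
    acc <- complex(real = numeric(nref))
    for (op in structure$sg$ops) {
      Heff <- H %*% op$R
      dir_cart <- recip_cartesian(cell, Heff)
      dir_cart <- dir_cart / sqrt(rowSums(dir_cart^2))
      f <- aspherical_form_factor(model, s, dir_cart %*% Rloc[[site$label]])
      if (radiation == "electron") {
        f <- mott_bethe(element_shells()[[site$element]]$Z, f, s)
      }
      Tdw <- debye_waller(cell, site, Heff, check_psd)
      phase <- exp(2i * pi * (H %*% op$t + Heff %*% site$xyz))
      acc <- acc + f * Tdw * as.complex(phase)
    }
    Fmat[, ai] <- w * acc
  }
  Fmat
}

#' Crystal structure factors
#'
#' @inheritParams structure_factor_matrix
#' @return Complex vector of structure factors F(h).
#' @export
structure_factor <- function(structure, models, hkl,
                             radiation = c("xray", "electron")) {
  rowSums(structure_factor_matrix(structure, models, hkl, radiation))
}

#' Per-reflection amplitude differences between two model sets
#'
#' Ranks reflections by |F_A| - |F_B| (the "worst-matching reflections"
#' machinery); either side may be a precomputed amplitude vector.
#'
#' @param hkl n x 3 index matrix.
#' @param d Resolutions (Angstrom).
#' @param F_A,F_B Amplitude vectors (numeric) or complex structure
#'   factors (modulus taken).
#' @return Data frame (h, k, l, d, F_A, F_B, dF) sorted by decreasing
#'   |dF|.
#' @export
delta_F_table <- function(hkl, d, F_A, F_B) {
  H <- rbind_hkl(hkl)
  if (length(F_A) != nrow(H) || length(F_B) != nrow(H)) {
    stop("index set and structure-factor lengths differ")
  }
  tab <- data.frame(h = H[, 1], k = H[, 2], l = H[, 3], d = d,
                    F_A = Mod(F_A), F_B = Mod(F_B))
  tab$dF <- tab$F_A - tab$F_B
  tab[order(-abs(tab$dF)), , drop = FALSE]
}
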