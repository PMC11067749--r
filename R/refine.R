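# Weighted least-squares refinement against |F| or |F|^2 data, with
# Levenberg-Marquardt damping, numerical central-difference derivatives,
# symmetry-derived special-position constraints, and the usual
# crystallographic fit statistics.

#' Reflection weight
#'
#' `w = 1 / (sigma^2(Fo^2) + (a P)^2 + b P)` with
#' `P = max(0, Fo^2)/3 + 2 Fc^2 / 3`. With a = b = 0 this reduces to
#' sigma weighting; sigma = 1, a = b = 0 gives unit weights.
#'
#' @param Fobs2 Observed squared amplitudes (may be negative).
#' @param Fcalc2 Calculated squared amplitudes.
#' @param sigma sigma(Fo^2) >= 0.
#' @param a,b Weighting parameters.
#' @return Weights.
#' @export
weight_shelx <- function(Fobs2, Fcalc2, sigma, a = 0, b = 0) {
  P <- pmax(0, Fobs2) / 3 + 2 * Fcalc2 / 3
  1 / (sigma^2 + (a * P)^2 + b * P)
}

#' Automatic weighting-parameter selection
#'
#' Coarse grid search over (a, b) minimizing the spread of the mean
#' weighted squared residual across intensity bins (a flat profile means
#' the weights describe the actual error distribution).
#'
#' @param Fobs2,Fcalc2,sigma As in [weight_shelx()].
#' @param n_bins Number of intensity bins.
#' @return List with `a`, `b` and the achieved `flatness` (max/min bin
#'   ratio).
#' @export
select_weight_ab <- function(Fobs2, Fcalc2, sigma, n_bins = 10) {
  bins <- cut(rank(Fcalc2, ties.method = "first"), n_bins, labels = FALSE)
  flat <- function(a, b) {
    w <- weight_shelx(Fobs2, Fcalc2, sigma, a, b)
    m <- tapply(w * (Fobs2 - Fcalc2)^2, bins, mean)
    if (any(!is.finite(m)) || any(m <= 0)) return(Inf)
    max(m) / min(m)
  }
  best <- list(a = 0, b = 0, flatness = flat(0, 0))
  for (a in c(0, 0.01, 0.02, 0.03, 0.05, 0.075, 0.1, 0.15)) {
    for (b in c(0, 0.1, 0.3, 1, 3, 10)) {
      fl <- flat(a, b)
      if (fl < best$flatness) best <- list(a = a, b = b, flatness = fl)
    }
  }
  best
}

#' Crystallographic R factor (percent)
#'
#' `R = 100 * sum| |Fo| - k |Fc| | / sum |Fo|` over the chosen subset.
#'
#' @param Fobs,Fcalc Amplitude vectors.
#' @param scale Scale k applied to Fcalc.
#' @param observed Logical vector (I > 3 sigma flag) for subset "obs".
#' @param subset "all" or "obs".
#' @return R in percent.
#' @export
r_factor <- function(Fobs, Fcalc, scale = 1, observed = NULL,
                     subset = c("all", "obs")) {
  subset <- match.arg(subset)
  keep <- if (subset == "obs") {
    if (is.null(observed)) stop("observed flags required for subset='obs'")
    observed
  } else rep(TRUE, length(Fobs))
  if (!any(keep)) stop("empty reflection subset for R factor")
  100 * sum(abs(abs(Fobs[keep]) - scale * abs(Fcalc[keep]))) / sum(abs(Fobs[keep]))
}

#' Per-shell R factors
#'
#' Splits reflections into `n_shells` equal-count resolution shells
#' (sorted by d) and reports R per shell.
#'
#' @param d Resolutions (A).
#' @param Fobs,Fcalc Amplitudes.
#' @param scale Scale on Fcalc.
#' @param n_shells Number of shells.
#' @return Data frame: shell, d_max, d_min, n, R.
#' @export
shell_statistics <- function(d, Fobs, Fcalc, scale = 1, n_shells = 8) {
  n <- length(d)
  if (n < n_shells) stop("fewer reflections than shells")
  ord <- order(-d)
  shell <- ceiling(seq_len(n) / (n / n_shells))
  shell[shell > n_shells] <- n_shells
  out <- data.frame(shell = seq_len(n_shells), d_max = NA_real_,
                    d_min = NA_real_, n = 0L, R = NA_real_)
  for (si in seq_len(n_shells)) {
    idx <- ord[shell == si]
    out$d_max[si] <- max(d[idx]); out$d_min[si] <- min(d[idx])
    out$n[si] <- length(idx)
    out$R[si] <- r_factor(Fobs[idx], Fcalc[idx], scale)
  }
  out
}

#' Mean error and root-mean-square deviation
#'
#' `ME = mean(x - ref)`; `RMSD = sqrt(mean((x - ref)^2))`.
#'
#' @param x Refined values.
#' @param ref Reference values.
#' @return List with `ME` and `RMSD`.
#' @export
me_rmsd <- function(x, ref) {
  if (length(x) != length(ref)) stop("length mismatch between refined and reference values")
  d <- x - ref
  list(ME = mean(d), RMSD = sqrt(mean(d^2)))
}

# ---- parameterization ------------------------------------------------------

# Builds the free-parameter table for a structural refinement. Each row
# describes one scalar parameter: a scale factor, or a shift of one atom
# along a symmetry-allowed basis direction in coordinate or U space.
build_structure_params <- function(structure, refine = c("xyz", "adp", "scale"),
                                   h_aniso = FALSE) {
  pars <- list()
  if ("scale" %in% refine) {
    pars[[length(pars) + 1]] <- list(kind = "scale", label = NA, dir = NA,
                                     step = 1e-5, name = "scale")
  }
  for (s in structure$sites) {
    con <- site_constraints(structure$sg, s$xyz, structure$tol)
    if ("xyz" %in% refine) {
      B <- con$xyz_basis
      for (j in seq_len(ncol(B))) {
        pars[[length(pars) + 1]] <- list(kind = "xyz", label = s$label,
                                         dir = B[, j], step = 1e-5,
                                         name = sprintf("%s.x%d", s$label, j))
      }
    }
    if ("adp" %in% refine) {
      if (is.null(s$uaniso)) {
        pars[[length(pars) + 1]] <- list(kind = "uiso", label = s$label,
                                         dir = NA, step = 1e-5,
                                         name = sprintf("%s.Uiso", s$label))
      } else {
        B <- con$u_basis
        for (j in seq_len(ncol(B))) {
          pars[[length(pars) + 1]] <- list(kind = "uaniso", label = s$label,
                                           dir = B[, j], step = 1e-5,
                                           name = sprintf("%s.U%d", s$label, j))
        }
      }
    }
  }
  pars
}

# apply a parameter delta vector to (structure, scale)
apply_structure_params <- function(structure, scale, pars, delta) {
  labs <- vapply(structure$sites, `[[`, "", "label")
  for (i in seq_along(pars)) {
    p <- pars[[i]]; dv <- delta[i]
    if (dv == 0) next
    if (p$kind == "scale") {
      scale <- scale + dv
    } else {
      j <- match(p$label, labs)
      s <- structure$sites[[j]]
      if (p$kind == "xyz") s$xyz <- s$xyz + dv * p$dir
      if (p$kind == "uiso") s$uiso <- s$uiso + dv
      if (p$kind == "uaniso") s$uaniso <- s$uaniso + dv * p$dir
      structure$sites[[j]] <- s
    }
  }
  list(structure = structure, scale = scale)
}

#' Refinement specification
#'
#' @param refine Character vector from "xyz", "adp", "scale".
#' @param target "F" (amplitudes) or "F2" (intensities).
#' @param weights "unit", "sigma", "shelx" (with `a`, `b`) or
#'   "shelx_auto" (grid-selected a, b).
#' @param a,b ShelX-style weighting parameters.
#' @param max_cycles Cycle cap.
#' @param shift_esd_tol Convergence threshold on max |shift|/esd.
#' @param gof_normalized Scale esds by goodness of fit if TRUE.
#' @return List of class `refinement_spec`.
#' @export
refinement_spec <- function(refine = c("xyz", "adp", "scale"),
                            target = c("F2", "F"),
                            weights = c("sigma", "unit", "shelx", "shelx_auto"),
                            a = 0, b = 0, max_cycles = 100,
                            shift_esd_tol = 0.01, gof_normalized = FALSE) {
  target <- match.arg(target)
  weights <- match.arg(weights)
  stopifnot(max_cycles > 0, shift_esd_tol > 0)
  structure(list(refine = refine, target = target, weights = weights,
                 a = a, b = b, max_cycles = max_cycles,
                 shift_esd_tol = shift_esd_tol,
                 gof_normalized = gof_normalized),
            class = "refinement_spec")
}

# ---- core engine -----------------------------------------------------------

# Generic damped Gauss-Newton driver. calc(delta_pars) must return the
# calculated target vector after applying the scalar deltas; the driver
# owns numerical differentiation with per-parameter steps and per-atom
# column caching through the `recalc` closure interface.
.lm_engine <- function(y_obs, w, pars, calc_full, calc_perturb,
                       max_cycles, shift_esd_tol, gof_normalized,
                       snapshot, restore) {
  npar <- length(pars)
  sw <- sqrt(w)
  lambda <- 1e-4
  y <- calc_full()
  ssr <- sum((sw * (y_obs - y))^2)
  history <- ssr
  esd <- rep(NA_real_, npar)
  shift_esd <- Inf
  cov <- NULL
  for (cyc in seq_len(max_cycles)) {
    J <- matrix(0, length(y_obs), npar)
    for (i in seq_len(npar)) {
      st <- pars[[i]]$step
      yp <- calc_perturb(i, st)
      ym <- calc_perturb(i, -st)
      J[, i] <- sw * (yp - ym) / (2 * st)
    }
    r <- sw * (y_obs - y)
    A <- crossprod(J)
    g <- crossprod(J, r)
    dA <- diag(A)
    # parameters with no leverage this cycle (e.g. kappa' while all
    # deformation populations are zero) are frozen for the cycle
    active <- dA > max(dA) * 1e-18
    if (!any(active)) {
      stop("singular normal matrix; null-space parameters: ",
           paste(vapply(pars, `[[`, "", "name"), collapse = ", "))
    }
    Aa <- A[active, active, drop = FALSE]
    ga <- g[active]
    da <- dA[active]
    accepted <- FALSE
    snap <- snapshot()
    for (try in 1:12) {
      Ad <- Aa + lambda * diag(da, sum(active))
      da_sol <- tryCatch(solve(Ad, ga), error = function(e) NULL)
      if (is.null(da_sol)) { lambda <- lambda * 10; next }
      delta <- numeric(npar)
      delta[active] <- da_sol
      y_new <- calc_full(delta)
      ssr_new <- sum((sw * (y_obs - y_new))^2)
      if (is.finite(ssr_new) && ssr_new <= ssr * (1 + 1e-12)) {
        accepted <- TRUE
        break
      }
      restore(snap)
      lambda <- lambda * 10
    }
    if (!accepted) break
    lambda <- max(lambda / 10, 1e-12)
    y <- y_new
    ssr <- ssr_new
    history <- c(history, ssr)
    cova <- tryCatch(solve(Aa), error = function(e) NULL)
    if (is.null(cova)) {
      ev <- eigen(Aa, symmetric = TRUE)
      worst <- which.max(abs(ev$vectors[, sum(active)]))
      bad <- vapply(pars[which(active)[worst]], `[[`, "", "name")
      stop("singular normal matrix near solution; parameters: ", bad)
    }
    cov <- matrix(0, npar, npar)
    cov[active, active] <- cova
    gof2 <- ssr / max(1, length(y_obs) - sum(active))
    esd <- rep(NA_real_, npar)
    esd[active] <- sqrt(pmax(0, diag(cova))) * if (gof_normalized) sqrt(gof2) else 1
    shift_esd <- max(abs(delta[active]) / pmax(esd[active], 1e-300))
    if (shift_esd < shift_esd_tol) break
  }
  list(esd = esd, cov = cov, history = history, shift_esd = shift_esd,
       y = y, n_cycles = length(history) - 1)
}

#' Refine structural parameters against reflection data
#'
#' Damped Gauss-Newton minimization of
#' `sum w (y_obs - y_calc)^2` with `y = |F|` or `|F|^2`, honoring
#' special-position constraints derived from the site symmetry. Central
#' finite differences with per-atom structure-factor column caching.
#'
#' @param refl A `reflection_set` (with `Iobs` for target "F2", `Fobs`
#'   for "F").
#' @param structure Starting `crystal_structure`.
#' @param models Form-factor model set (IAM or multipole).
#' @param spec A `refinement_spec`.
#' @param radiation "electron" or "xray".
#' @param scale Starting scale on amplitudes.
#' @return List of class `refinement_result`: `structure`, `scale`,
#'   `esd` (named), `cov`, `pars`, `R_obs`, `R_all`, `wR2`, `history`,
#'   `shift_esd`, `n_cycles`, `Fcalc`.
#' @export
refine <- function(refl, structure, models, spec = refinement_spec(),
                   radiation = "electron", scale = 1) {
  H <- as.matrix(refl[, c("h", "k", "l")])
  y_obs <- if (spec$target == "F2") {
    if (!"Iobs" %in% names(refl)) stop("target F2 needs intensity data")
    refl$Iobs
  } else {
    if (!"Fobs" %in% names(refl)) stop("target F needs amplitude data")
    refl$Fobs
  }
  pars <- build_structure_params(structure, spec$refine)
  if (!length(pars)) stop("no free parameters selected")
  if (length(pars) >= nrow(H)) stop("more parameters than reflections")
  labs <- vapply(structure$sites, `[[`, "", "label")

  state <- new.env(parent = emptyenv())
  state$structure <- structure
  state$scale <- scale
  state$Fmat <- structure_factor_matrix(structure, models, H, radiation)

  # moving an atom also reorients the local frames that reference it
  dep_map <- lapply(labs, function(lb) {
    deps <- vapply(labs, function(a) {
      fr <- models[[a]]$frame
      !is.null(fr) && lb %in% c(fr$ref1, fr$ref2)
    }, TRUE)
    unique(c(lb, labs[deps]))
  })
  names(dep_map) <- labs

  y_from <- function(Fmat, k) {
    Fa <- Mod(rowSums(Fmat))
    if (spec$target == "F2") (k * Fa)^2 else k * Fa
  }
  calc_full <- function(delta = NULL) {
    if (!is.null(delta)) {
      upd <- apply_structure_params(state$structure, state$scale, pars, delta)
      moved <- unique(stats::na.omit(vapply(which(delta != 0), function(i) {
        p <- pars[[i]]; if (p$kind == "scale") NA_character_ else p$label
      }, "")))
      Fmat <- state$Fmat
      if (length(moved)) {
        affected <- unique(unlist(dep_map[moved]))
        Fmat[, affected] <- structure_factor_matrix(upd$structure, models, H,
                                                    radiation, sites = affected,
                                                    check_psd = FALSE)
      }
      state$structure <- upd$structure
      state$scale <- upd$scale
      state$Fmat <- Fmat
    }
    y_from(state$Fmat, state$scale)
  }
  calc_perturb <- function(i, step) {
    p <- pars[[i]]
    if (p$kind == "scale") return(y_from(state$Fmat, state$scale + step))
    delta <- numeric(length(pars)); delta[i] <- step
    upd <- apply_structure_params(state$structure, state$scale, pars, delta)
    affected <- if (p$kind == "xyz") dep_map[[p$label]] else p$label
    Fmat <- state$Fmat
    Fmat[, affected] <- structure_factor_matrix(upd$structure, models, H,
                                                radiation, sites = affected,
                                                check_psd = FALSE)
    y_from(Fmat, state$scale)
  }

  w <- switch(spec$weights,
    unit = rep(1, nrow(H)),
    sigma = {
      if (any(refl$sigma <= 0)) stop("sigma weighting needs positive sigmas")
      1 / refl$sigma^2
    },
    shelx = weight_shelx(y_obs, calc_full(), refl$sigma, spec$a, spec$b),
    shelx_auto = {
      ab <- select_weight_ab(y_obs, calc_full(), refl$sigma)
      weight_shelx(y_obs, calc_full(), refl$sigma, ab$a, ab$b)
    })

  snapshot <- function() list(structure = state$structure, scale = state$scale,
                              Fmat = state$Fmat)
  restore <- function(sn) {
    state$structure <- sn$structure; state$scale <- sn$scale; state$Fmat <- sn$Fmat
  }
  fit <- .lm_engine(y_obs, w, pars, calc_full, calc_perturb,
                    spec$max_cycles, spec$shift_esd_tol, spec$gof_normalized,
                    snapshot, restore)

  Fc <- Mod(rowSums(state$Fmat))
  Fo <- if (spec$target == "F2") sqrt(pmax(0, y_obs)) else y_obs
  observed <- if ("observed" %in% names(refl)) refl$observed else rep(TRUE, nrow(H))
  names(fit$esd) <- vapply(pars, `[[`, "", "name")
  res <- list(structure = state$structure, scale = state$scale,
              esd = fit$esd, cov = fit$cov, pars = pars,
              R_obs = if (any(observed)) r_factor(Fo, Fc, state$scale, observed, "obs") else NA,
              R_all = r_factor(Fo, Fc, state$scale),
              wR2 = 100 * sqrt(sum(w * (y_obs - fit$y)^2) / sum(w * y_obs^2)),
              history = fit$history, shift_esd = fit$shift_esd,
              n_cycles = fit$n_cycles, Fcalc = Fc, weights = w)
  class(res) <- "refinement_result"
  res
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement: %d cycles, R_all = %.3f%%, wR2 = %.3f%%, max shift/esd = %.3g\n",
              x$n_cycles, x$R_all, x$wR2, x$shift_esd))
  invisible(x)
}

# ---- multipole-parameter refinement ---------------------------------------

build_multipole_params <- function(models, freeze_kappa_prime = FALSE) {
  pars <- list()
  for (m in models) {
    pars[[length(pars) + 1]] <- list(kind = "pval", label = m$label, idx = NA,
                                     step = 1e-4, name = paste0(m$label, ".Pval"))
    for (i in seq_len(nrow(m$plm))) {
      pars[[length(pars) + 1]] <- list(kind = "plm", label = m$label, idx = i,
                                       step = 1e-4,
                                       name = sprintf("%s.P%d%+d", m$label,
                                                      m$plm$l[i], m$plm$m[i]))
    }
    pars[[length(pars) + 1]] <- list(kind = "kappa", label = m$label, idx = NA,
                                     step = 1e-4, name = paste0(m$label, ".kappa"))
    if (!freeze_kappa_prime) {
      pars[[length(pars) + 1]] <- list(kind = "kappap", label = m$label, idx = NA,
                                       step = 1e-4, name = paste0(m$label, ".kappap"))
    }
  }
  pars
}

apply_multipole_params <- function(models, pars, delta) {
  for (i in seq_along(pars)) {
    if (delta[i] == 0) next
    p <- pars[[i]]
    m <- models[[p$label]]
    switch(p$kind,
      pval = { m$P_val <- m$P_val + delta[i] },
      plm = { m$plm$P[p$idx] <- m$plm$P[p$idx] + delta[i] },
      kappa = { m$kappa <- max(1e-3, m$kappa + delta[i]) },
      kappap = { m$kappa_prime <- max(1e-3, m$kappa_prime + delta[i]) })
    models[[p$label]] <- m
  }
  models
}

#' Fit multipole parameters to phased amplitudes
#'
#' Mirrors a databank-construction refinement: coordinates, ADPs and
#' scale are frozen, phases are constrained to the supplied values, and
#' P_val, P_lm, kappa (and optionally kappa') are fitted with unit
#' weights against |F|. Site-symmetry-forbidden populations are not
#' parameters and remain exactly zero.
#'
#' @param refl `reflection_set` with `Fobs` and `phase` columns.
#' @param structure `crystal_structure` (held fixed).
#' @param models Starting model set (e.g. spherical).
#' @param radiation "xray" or "electron".
#' @param freeze_kappa_prime Keep kappa' at input values.
#' @param max_cycles,shift_esd_tol Convergence controls.
#' @return List: `models` (fitted), `esd`, `R_all`, `history`,
#'   `n_cycles`.
#' @export
refine_multipoles <- function(refl, structure, models, radiation = "xray",
                              freeze_kappa_prime = FALSE,
                              max_cycles = 60, shift_esd_tol = 0.01) {
  if (!"phase" %in% names(refl)) stop("phase-constrained fit needs a phase column")
  H <- as.matrix(refl[, c("h", "k", "l")])
  phase <- refl$phase
  y_obs <- refl$Fobs
  pars <- build_multipole_params(models, freeze_kappa_prime)
  labs <- names(models)

  state <- new.env(parent = emptyenv())
  state$models <- models
  state$Fmat <- structure_factor_matrix(structure, models, H, radiation)
  y_from <- function(Fmat) Re(rowSums(Fmat) * exp(-1i * phase))
  calc_full <- function(delta = NULL) {
    if (!is.null(delta)) {
      newm <- apply_multipole_params(state$models, pars, delta)
      moved <- unique(vapply(which(delta != 0), function(i) pars[[i]]$label, ""))
      Fmat <- state$Fmat
      if (length(moved)) {
        Fmat[, moved] <- structure_factor_matrix(structure, newm, H,
                                                 radiation, sites = moved)
      }
      state$models <- newm
      state$Fmat <- Fmat
    }
    y_from(state$Fmat)
  }
  calc_perturb <- function(i, step) {
    p <- pars[[i]]
    delta <- numeric(length(pars)); delta[i] <- step
    newm <- apply_multipole_params(state$models, pars, delta)
    Fmat <- state$Fmat
    Fmat[, p$label] <- structure_factor_matrix(structure, newm, H,
                                               radiation, sites = p$label)[, 1]
    y_from(Fmat)
  }
  w <- rep(1, nrow(H))
  snapshot <- function() list(models = state$models, Fmat = state$Fmat)
  restore <- function(sn) {
    state$models <- sn$models; state$Fmat <- sn$Fmat
  }
  fit <- .lm_engine(y_obs, w, pars, calc_full, calc_perturb,
                    max_cycles, shift_esd_tol, gof_normalized = FALSE,
                    snapshot, restore)
  names(fit$esd) <- vapply(pars, `[[`, "", "name")
  list(models = state$models, esd = fit$esd,
       R_all = r_factor(y_obs, Mod(rowSums(state$Fmat))),
       history = fit$history, n_cycles = fit$n_cycles)
}

# ---- comparison statistics -------------------------------------------------

#' Bond-length comparison statistics
#'
#' Computes refined bond lengths (with esds propagated from the
#' coordinate covariance when a `refinement_result` is given), compares
#' them with a reference table and reports ME and RMSD.
#'
#' @param result A `refinement_result`, or a `crystal_structure` (no
#'   esds then).
#' @param bonds Data frame with columns `atom1`, `atom2`, `ref`
#'   (reference lengths, A).
#' @return List: `table` (bond, length, esd, ref, diff), `ME`, `RMSD`.
#' @export
bond_length_stats <- function(result, bonds) {
  structure <- if (inherits(result, "refinement_result")) result$structure else result
  labs <- vapply(structure$sites, `[[`, "", "label")
  if (!all(c(bonds$atom1, bonds$atom2) %in% labs)) {
    stop("bond table references unknown atom labels")
  }
  n <- nrow(bonds)
  len <- numeric(n); esd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    len[i] <- bond_length(structure, bonds$atom1[i], bonds$atom2[i])
    if (inherits(result, "refinement_result") && !is.null(result$cov)) {
      esd[i] <- .bond_esd(result, bonds$atom1[i], bonds$atom2[i])
    }
  }
  st <- me_rmsd(len, bonds$ref)
  list(table = data.frame(bond = paste(bonds$atom1, bonds$atom2, sep = "-"),
                          length = len, esd = esd, ref = bonds$ref,
                          diff = len - bonds$ref),
       ME = st$ME, RMSD = st$RMSD)
}

# esd of a bond length from the parameter covariance: gradient of the
# distance wrt each free coordinate parameter of the two atoms
.bond_esd <- function(result, lab1, lab2) {
  structure <- result$structure
  cell <- structure$cell
  labs <- vapply(structure$sites, `[[`, "", "label")
  x1 <- structure$sites[[match(lab1, labs)]]$xyz
  x2 <- structure$sites[[match(lab2, labs)]]$xyz
  dcart <- as.numeric(cell$ortho %*% (x1 - x2))
  L <- sqrt(sum(dcart^2))
  grad <- numeric(length(result$pars))
  for (i in seq_along(result$pars)) {
    p <- result$pars[[i]]
    if (p$kind != "xyz") next
    sgn <- if (p$label == lab1) 1 else if (p$label == lab2) -1 else 0
    if (sgn == 0) next
    grad[i] <- sgn * sum(dcart * as.numeric(cell$ortho %*% p$dir)) / L
  }
  sqrt(max(0, t(grad) %*% result$cov %*% grad))
}

#' ADP comparison statistics (U_eq)
#'
#' U_eq of each matched atom in the refined and reference structures,
#' with ME and RMSD reported separately for non-hydrogen and hydrogen
#' atoms.
#'
#' @param refined,reference `crystal_structure` objects with matching
#'   labels.
#' @return List: `table` (label, element, U_eq, U_ref, diff), `nonH`
#'   (ME, RMSD), `H` (ME, RMSD).
#' @export
adp_stats <- function(refined, reference) {
  labs <- vapply(refined$sites, `[[`, "", "label")
  rlabs <- vapply(reference$sites, `[[`, "", "label")
  common <- intersect(labs, rlabs)
  el <- vapply(common, function(lb)
    refined$sites[[match(lb, labs)]]$element, "")
  ue <- vapply(common, function(lb) u_equiv(refined, lb), 0)
  ur <- vapply(common, function(lb) u_equiv(reference, lb), 0)
  tab <- data.frame(label = common, element = el, U_eq = ue, U_ref = ur,
                    diff = ue - ur)
  hsel <- el == "H"
  list(table = tab,
       nonH = me_rmsd(ue[!hsel], ur[!hsel]),
       H = if (any(hsel)) me_rmsd(ue[hsel], ur[hsel]) else NULL)
}

#' X-H bond table of the fixture structure
#'
#' Pairs each hydrogen with its covalently bonded heavy atom (nearest
#' non-H neighbour) and attaches reference lengths.
#'
#' @param structure A `crystal_structure`.
#' @param ref Named numeric vector of reference lengths keyed by
#'   hydrogen label (optional; defaults to current lengths).
#' @return Data frame with `atom1` (heavy), `atom2` (H), `ref`.
#' @export
xh_bond_table <- function(structure, ref = NULL) {
  labs <- vapply(structure$sites, `[[`, "", "label")
  els <- vapply(structure$sites, `[[`, "", "element")
  XC <- site_cartesian(structure)
  hs <- which(els == "H")
  heavy <- which(els != "H")
  out <- data.frame(atom1 = character(0), atom2 = character(0), ref = numeric(0))
  for (i in hs) {
    dd <- sqrt(rowSums((XC[heavy, , drop = FALSE] -
                          matrix(XC[i, ], length(heavy), 3, byrow = TRUE))^2))
    j <- heavy[which.min(dd)]
    r <- if (!is.null(ref)) unname(ref[labs[i]]) else min(dd)
    out <- rbind(out, data.frame(atom1 = labs[j], atom2 = labs[i], ref = r))
  }
  out
}
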