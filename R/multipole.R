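# Hansen-Coppens pseudoatom models: element shell tables, local frames,
# and the analytic aspherical X-ray form factor
#   f_x(h) = P_c f_core(s) + P_val f_val(s/kappa)
#          + sum_l 4 pi i^l <j_l>(s/kappa') sum_m P_lm d_lm(h_local)

.aspher_env <- new.env(parent = emptyenv())

#' Packaged element shell table (H, C, N, O)
#'
#' Loads the single-zeta Slater shell description shipped with the
#' package (synthetic stand-in values, documented in the data file) and
#' converts exponents from bohr^-1 to A^-1.
#'
#' @param path Optional alternative table path (same format).
#' @return Named list per element with `Z`, `P_c`, `P_val`, `core`
#'   (`slater_radial` or NULL), `val`, `def_n` (powers n_1..n_4),
#'   `def_zeta` (A^-1).
#' @export
element_shells <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.aspher_env$shells)) return(.aspher_env$shells)
    path <- system.file("extdata", "hcno_slater.txt", package = "aspherED")
  }
  tab <- utils::read.table(path, comment.char = "#", header = FALSE,
    col.names = c("element", "Z", "P_c", "P_val", "n_core", "zeta_core",
                  "n_val", "zeta_val", "zeta_def", "n1", "n2", "n3", "n4"))
  a0 <- .const$a0
  out <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    out[[r$element]] <- list(
      Z = r$Z, P_c = r$P_c, P_val = r$P_val,
      core = if (r$P_c > 0) slater_radial(r$n_core, r$zeta_core / a0) else NULL,
      val = slater_radial(r$n_val, r$zeta_val / a0),
      def_n = c(r$n1, r$n2, r$n3, r$n4),
      def_zeta = r$zeta_def / a0)
  }
  .aspher_env$shells <- out
  out
}

#' Multipole pseudoatom model
#'
#' @param label Atom-site label the model attaches to.
#' @param element Element symbol (must exist in [element_shells()]).
#' @param P_val Valence monopole population (electrons).
#' @param plm Data frame with columns `l`, `m`, `P` (deformation
#'   populations); rows violating `site_symmetry` must be absent or zero.
#' @param kappa Valence contraction-expansion (> 0).
#' @param kappa_prime Deformation contraction-expansion (> 0, one value
#'   shared across l).
#' @param site_symmetry "1", "m", "3m" or "cyl".
#' @param frame Local frame spec: list(ref1=, ref2=, axis1=, axis2=) with
#'   axis names from "x","y","z"; axis1 points from the atom to `ref1`,
#'   axis2 is the Gram-Schmidt complement toward `ref2`.
#' @param l_max Maximum l (<= 4; <= 2 enforced for hydrogen).
#' @param P_c Core population override (defaults to the element value).
#' @return Object of class `multipole_model`.
#' @export
multipole_model <- function(label, element, P_val,
                            plm = data.frame(l = integer(), m = integer(), P = numeric()),
                            kappa = 1, kappa_prime = 1,
                            site_symmetry = "1",
                            frame = NULL, l_max = if (element == "H") 2 else 4,
                            P_c = NULL) {
  stopifnot(kappa > 0, kappa_prime > 0)
  sh <- element_shells()[[element]]
  if (is.null(sh)) stop("no shell table for element ", element)
  if (element == "H" && l_max > 2) stop("hydrogen models limited to l_max = 2")
  if (l_max > 4) stop("l_max must be <= 4")
  if (nrow(plm)) {
    allowed <- allowed_multipoles(site_symmetry, l_max)
    bad <- !paste(plm$l, plm$m) %in% paste(allowed$l, allowed$m)
    if (any(bad & abs(plm$P) > 0)) {
      stop("populations present for multipoles forbidden by site symmetry '",
           site_symmetry, "': ", paste(paste(plm$l[bad], plm$m[bad]), collapse = "; "))
    }
    plm <- plm[!bad, , drop = FALSE]
    if (any(plm$l > l_max)) stop("plm rows exceed l_max")
  }
  structure(list(label = label, element = element,
                 P_c = if (is.null(P_c)) sh$P_c else P_c, P_val = P_val,
                 plm = plm, kappa = kappa, kappa_prime = kappa_prime,
                 site_symmetry = site_symmetry, frame = frame, l_max = l_max),
            class = "multipole_model")
}

#' Local-frame rotation matrix for a pseudoatom
#'
#' Builds the orthonormal right-handed rotation whose columns are the
#' local x, y, z axes expressed in the crystal Cartesian frame. The
#' first named axis points from the atom towards `ref1`; the second is
#' the Gram-Schmidt orthogonalized direction towards `ref2`; the third
#' completes a right-handed set.
#'
#' @param structure A `crystal_structure`.
#' @param origin Label of the atom owning the frame.
#' @param frame Frame spec (see [multipole_model()]); `NULL` gives the
#'   identity.
#' @return 3x3 rotation matrix R (local -> Cartesian), det = +1.
#' @export
build_local_frame <- function(structure, origin, frame) {
  if (is.null(frame)) return(diag(3))
  XC <- site_cartesian(structure)
  v1 <- XC[frame$ref1, ] - XC[origin, ]
  v2 <- XC[frame$ref2, ] - XC[origin, ]
  n1 <- sqrt(sum(v1^2))
  if (n1 < 1e-8) stop("frame reference ", frame$ref1, " coincides with ", origin)
  e1 <- v1 / n1
  v2p <- v2 - sum(v2 * e1) * e1
  n2 <- sqrt(sum(v2p^2))
  if (n2 < 1e-8) stop("frame references are collinear for atom ", origin)
  e2 <- v2p / n2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  ax <- c(frame$axis1, frame$axis2)
  third <- setdiff(c("x", "y", "z"), ax)
  R <- matrix(0, 3, 3, dimnames = list(NULL, c("x", "y", "z")))
  R[, ax[1]] <- e1
  R[, ax[2]] <- e2
  R[, third] <- e3
  if (det(R) < 0) R[, third] <- -e3
  R
}

#' Aspherical X-ray form factor of a multipole pseudoatom
#'
#' Evaluates the analytic Hansen-Coppens form factor at scattering
#' vectors given in the *local* frame of the atom (rotate beforehand
#' with the transpose of [build_local_frame()]).
#'
#' @param model A `multipole_model`.
#' @param s sin(theta)/lambda values (A^-1), vectorized.
#' @param dir_local Unit scattering directions in the local frame
#'   (n x 3); may be `NULL` when the model has no deformation terms.
#' @return Complex form factor values (electrons); at s = 0 equals
#'   P_c + P_val.
#' @export
aspherical_form_factor <- function(model, s, dir_local = NULL) {
  sh <- element_shells()[[model$element]]
  f <- complex(real = numeric(length(s)))
  if (model$P_c > 0) {
    f <- f + model$P_c * slater_fourier_bessel(0, sh$core$n, sh$core$zeta, s)
  }
  f <- f + model$P_val * slater_fourier_bessel(0, sh$val$n, sh$val$zeta, s / model$kappa)
  if (nrow(model$plm)) {
    if (is.null(dir_local)) stop("dir_local required for a model with deformation terms")
    D <- if (is.matrix(dir_local)) dir_local else matrix(dir_local, ncol = 3)
    for (l in unique(model$plm$l)) {
      nl <- sh$def_n[l]
      jl <- slater_fourier_bessel(l, nl, sh$def_zeta, s / model$kappa_prime)
      ang <- numeric(nrow(D))
      rows <- model$plm[model$plm$l == l, , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        ang <- ang + rows$P[i] * density_normalized_harmonic(l, rows$m[i], D)
      }
      f <- f + 4 * pi * (1i)^l * jl * ang
    }
  }
  f
}

#' Direct-space pseudoatom density (oracle helper)
#'
#' Evaluates the Hansen-Coppens density at Cartesian points in the local
#' frame; the Fourier transform of this density is
#' [aspherical_form_factor()]. Used by tests as the brute-force route.
#'
#' @param model A `multipole_model`.
#' @param xyz n x 3 Cartesian points (A) in the local frame.
#' @return Density values (e A^-3).
#' @export
pseudoatom_density <- function(model, xyz) {
  sh <- element_shells()[[model$element]]
  P <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3)
  r <- sqrt(rowSums(P^2))
  rho <- numeric(length(r))
  if (model$P_c > 0) rho <- rho + model$P_c * slater_eval(sh$core, r) / (4 * pi)
  k <- model$kappa
  rho <- rho + model$P_val * k^3 * slater_eval(sh$val, k * r) / (4 * pi)
  if (nrow(model$plm)) {
    dirs <- P / pmax(r, 1e-300)
    kp <- model$kappa_prime
    for (i in seq_len(nrow(model$plm))) {
      l <- model$plm$l[i]
      rad <- slater_radial(sh$def_n[l], sh$def_zeta)
      rho <- rho + model$plm$P[i] * kp^3 * slater_eval(rad, kp * r) *
        density_normalized_harmonic(l, model$plm$m[i], dirs)
    }
  }
  rho
}

#' Total electron count of a model set
#' @param models List of `multipole_model`.
#' @return Sum of P_c + P_val.
#' @export
model_electron_count <- function(models) {
  sum(vapply(models, function(m) m$P_c + m$P_val, 0))
}

#' Write multipole models to a plain-text parameter file
#'
#' One block per atom:
#' ```
#' atom <label> <element>
#' monopole <P_c> <P_val> <kappa> <kappa_prime>
#' symmetry <site_symmetry> <l_max>
#' frame <ref1> <ref2> <axis1> <axis2>      (absent for identity frame)
#' plm <l> <m> <P>                          (repeated)
#' end
#' ```
#'
#' @param models List of `multipole_model`.
#' @param path Output file.
#' @export
write_multipole_file <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# aspherED multipole parameter file", con)
  for (m in models) {
    writeLines(sprintf("atom %s %s", m$label, m$element), con)
    writeLines(sprintf("monopole %.10g %.10g %.10g %.10g",
                       m$P_c, m$P_val, m$kappa, m$kappa_prime), con)
    writeLines(sprintf("symmetry %s %d", m$site_symmetry, m$l_max), con)
    if (!is.null(m$frame)) {
      writeLines(sprintf("frame %s %s %s %s", m$frame$ref1, m$frame$ref2,
                         m$frame$axis1, m$frame$axis2), con)
    }
    if (nrow(m$plm)) {
      for (i in seq_len(nrow(m$plm))) {
        writeLines(sprintf("plm %d %d %.10g", m$plm$l[i], m$plm$m[i], m$plm$P[i]), con)
      }
    }
    writeLines("end", con)
  }
  invisible(path)
}

#' Read a multipole parameter file written by [write_multipole_file()]
#' @param path File path.
#' @return List of `multipole_model`.
#' @export
read_multipole_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  models <- list()
  i <- 1
  while (i <= length(lines)) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (tok[1] != "atom") stop("expected 'atom' at line: ", lines[i])
    label <- tok[2]; element <- tok[3]
    mono <- NULL; sym <- "1"; lmax <- 4; frame <- NULL
    plm <- data.frame(l = integer(), m = integer(), P = numeric())
    i <- i + 1
    while (lines[i] != "end") {
      t2 <- strsplit(lines[i], "[[:space:]]+")[[1]]
      switch(t2[1],
        monopole = { mono <- as.numeric(t2[2:5]) },
        symmetry = { sym <- t2[2]; lmax <- as.integer(t2[3]) },
        frame = { frame <- list(ref1 = t2[2], ref2 = t2[3], axis1 = t2[4], axis2 = t2[5]) },
        plm = { plm <- rbind(plm, data.frame(l = as.integer(t2[2]),
                                             m = as.integer(t2[3]),
                                             P = as.numeric(t2[4]))) },
        stop("unknown record '", t2[1], "' in multipole file"))
      i <- i + 1
    }
    i <- i + 1
    models[[label]] <- multipole_model(label, element, P_val = mono[2], plm = plm,
                                       kappa = mono[3], kappa_prime = mono[4],
                                       site_symmetry = sym, frame = frame,
                                       l_max = lmax, P_c = mono[1])
  }
  models
}
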