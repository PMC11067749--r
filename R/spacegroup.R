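#' Parse a symmetry operator from an xyz triplet string
#'
#' Accepts strings like `"x,y,z"`, `"-x,y+1/2,-z"`, `"1/2+x,1/2-y,z"`.
#'
#' @param s Triplet string.
#' @return List with integer `R` (3x3 rotation part) and numeric `t`
#'   (translation, reduced mod 1).
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("symmetry operator must have three components: ", s)
  R <- matrix(0L, 3, 3)
  tr <- numeric(3)
  for (i in 1:3) {
    p <- parts[i]
    # tokenize into signed terms
    p <- gsub("-", "+-", p)
    terms <- strsplit(p, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      sign <- 1
      if (startsWith(tm, "-")) { sign <- -1; tm <- substring(tm, 2) }
      if (tm %in% c("x", "y", "z")) {
        R[i, match(tm, c("x", "y", "z"))] <- as.integer(sign)
      } else if (grepl("^[0-9]+/[0-9]+$", tm)) {
        f <- as.numeric(strsplit(tm, "/")[[1]])
        tr[i] <- tr[i] + sign * f[1] / f[2]
      } else if (grepl("^[0-9.]+$", tm)) {
        tr[i] <- tr[i] + sign * as.numeric(tm)
      } else {
        stop("cannot parse symmetry term '", tm, "' in ", s)
      }
    }
  }
  d <- round(det(R))
  if (abs(d) != 1) stop("rotation part of '", s, "' has |det| != 1")
  list(R = R, t = tr %% 1)
}

#' Format a symmetry operator as an xyz triplet
#' @param op List with `R` and `t` as from [parse_symop()].
#' @return Triplet string.
#' @export
format_symop <- function(op) {
  ax <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      if (op$R[i, j] == 1) s <- paste0(s, "+", ax[j])
      if (op$R[i, j] == -1) s <- paste0(s, "-", ax[j])
    }
    tfrac <- op$t[i] %% 1
    if (abs(tfrac) > 1e-9) {
      fr <- c("1/2" = 0.5, "1/4" = 0.25, "3/4" = 0.75, "1/3" = 1 / 3, "2/3" = 2 / 3,
              "1/6" = 1 / 6, "5/6" = 5 / 6)
      k <- which(abs(fr - tfrac) < 1e-9)
      s <- paste0(s, "+", if (length(k)) names(fr)[k[1]] else format(tfrac))
    }
    comp[i] <- sub("^\\+", "", s)
  }
  paste(comp, collapse = ",")
}

#' Build a space group from explicit operator strings
#'
#' The operator list must contain every operation including centering
#' translations (no symbol lookup is performed). Closure modulo lattice
#' translations and the presence of the identity are verified.
#'
#' @param symbol Free-text label (e.g. "Ibam", "P1").
#' @param ops Character vector of xyz triplets.
#' @return Object of class `space_group` with `symbol` and `ops`
#'   (list of `R`/`t` pairs).
#' @export
space_group <- function(symbol, ops) {
  parsed <- lapply(ops, parse_symop)
  key <- function(R, t) paste(c(R, round(t %% 1, 6)), collapse = ",")
  keys <- vapply(parsed, function(o) key(o$R, o$t), "")
  if (anyDuplicated(keys)) stop("duplicate symmetry operators supplied")
  if (!any(vapply(parsed, function(o) all(o$R == diag(3)) && all(abs(o$t %% 1) < 1e-9), TRUE))) {
    stop("identity operator missing")
  }
  # closure check
  for (a in parsed) for (b in parsed) {
    Rc <- a$R %*% b$R
    tc <- (a$R %*% b$t + a$t) %% 1
    if (!key(Rc, tc) %in% keys) {
      stop("operator list not closed under composition: missing ",
           format_symop(list(R = Rc, t = as.numeric(tc))))
    }
  }
  structure(list(symbol = symbol, ops = parsed), class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s (%d operators)\n", x$symbol, length(x$ops)))
  invisible(x)
}

#' Packaged operator lists
#'
#' Explicit operator lists for the two settings used by the synthetic
#' fixtures: P1 and the body-centred orthorhombic group Ibam in the
#' standard origin-at-centre setting (mirror plane at z = 0).
#'
#' @param symbol "P1", "P-1" or "Ibam".
#' @return A `space_group`.
#' @export
packaged_space_group <- function(symbol = c("Ibam", "P1", "P-1")) {
  symbol <- match.arg(symbol)
  ops <- switch(symbol,
    "P1" = "x,y,z",
    "P-1" = c("x,y,z", "-x,-y,-z"),
    "Ibam" = c(
      "x,y,z", "-x,-y,z", "x,-y,-z+1/2", "-x,y,-z+1/2",
      "-x,-y,-z", "x,y,-z", "-x,y,z+1/2", "x,-y,z+1/2",
      "x+1/2,y+1/2,z+1/2", "-x+1/2,-y+1/2,z+1/2",
      "x+1/2,-y+1/2,-z", "-x+1/2,y+1/2,-z",
      "-x+1/2,-y+1/2,-z+1/2", "x+1/2,y+1/2,-z+1/2",
      "-x+1/2,y+1/2,z", "x+1/2,-y+1/2,z"))
  space_group(symbol, ops)
}

#' Apply a symmetry operator to fractional coordinates
#' @param op Operator (list `R`, `t`).
#' @param xyz Numeric triple.
#' @return Transformed fractional coordinates (not reduced mod 1).
#' @export
apply_symop <- function(op, xyz) {
  as.numeric(op$R %*% xyz + op$t)
}

frac_wrap <- function(x) {
  y <- x %% 1
  y[abs(y - 1) < 1e-9] <- 0
  y
}

# minimum-image fractional distance (in fractional units, per component)
frac_close <- function(a, b, tol) {
  d <- (a - b) %% 1
  all(pmin(d, 1 - d) < tol)
}

#' Stabilizer (site-symmetry group) of a position
#'
#' Operators that map `xyz` onto itself modulo lattice translations.
#'
#' @param sg A `space_group`.
#' @param xyz Fractional coordinates.
#' @param tol Matching tolerance in fractional units.
#' @return Integer indices into `sg$ops`.
#' @export
site_stabilizer <- function(sg, xyz, tol = 1e-4) {
  which(vapply(sg$ops, function(op) frac_close(apply_symop(op, xyz), xyz, tol), TRUE))
}

#' Orbit of a position under the space group
#'
#' @inheritParams site_stabilizer
#' @return Matrix of distinct images (rows, wrapped to [0,1)).
#' @export
site_orbit <- function(sg, xyz, tol = 1e-4) {
  imgs <- t(vapply(sg$ops, function(op) frac_wrap(apply_symop(op, xyz)), numeric(3)))
  keep <- rep(TRUE, nrow(imgs))
  for (i in seq_len(nrow(imgs))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1)) {
      if (keep[j] && frac_close(imgs[i, ], imgs[j, ], tol)) { keep[i] <- FALSE; break }
    }
  }
  imgs[keep, , drop = FALSE]
}

#' Special-position parameter constraints
#'
#' Derives, from the site-symmetry (stabilizer) of a position, the linear
#' subspaces of free coordinate shifts and free anisotropic-U components.
#' A shift delta is free iff it equals its average over the stabilizer
#' rotations; the same projector logic applies to the U tensor
#' (U -> R U R' averaged).
#'
#' @param sg A `space_group`.
#' @param xyz Fractional coordinates of the site.
#' @param tol Site-matching tolerance.
#' @return List with `xyz_basis` (3 x k matrix whose columns span the free
#'   coordinate shifts), `u_basis` (6 x m matrix for free Voigt-ordered
#'   U11,U22,U33,U12,U13,U23 shifts) and `stabilizer` indices.
#' @export
site_constraints <- function(sg, xyz, tol = 1e-4) {
  stab <- site_stabilizer(sg, xyz, tol)
  Rs <- lapply(sg$ops[stab], `[[`, "R")
  # coordinate projector
  P <- Reduce(`+`, Rs) / length(Rs)
  xyz_basis <- eigen_basis_one(P)
  # U projector in Voigt space
  voigt <- function(U) c(U[1, 1], U[2, 2], U[3, 3], U[1, 2], U[1, 3], U[2, 3])
  unvoigt <- function(v) matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3, 3)
  PU <- matrix(0, 6, 6)
  for (k in 1:6) {
    e <- numeric(6); e[k] <- 1
    U <- unvoigt(e)
    acc <- matrix(0, 3, 3)
    for (R in Rs) acc <- acc + R %*% U %*% t(R)
    PU[, k] <- voigt(acc / length(Rs))
  }
  list(xyz_basis = xyz_basis, u_basis = eigen_basis_one(PU), stabilizer = stab)
}

# orthonormal basis of the eigenvalue-1 subspace of an averaging projector
eigen_basis_one <- function(P) {
  eg <- eigen((P + t(P)) / 2, symmetric = TRUE)
  idx <- which(abs(eg$values - 1) < 1e-8)
  if (!length(idx)) return(matrix(0, nrow(P), 0))
  B <- eg$vectors[, idx, drop = FALSE]
  qr.Q(qr(B))
}
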