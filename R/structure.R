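#' Atom site
#'
#' @param label Site label (e.g. "O4").
#' @param element Element symbol ("H", "C", "N", "O").
#' @param xyz Fractional coordinates.
#' @param uiso Isotropic displacement parameter (A^2), used when `uaniso`
#'   is `NULL`.
#' @param uaniso Optional length-6 vector (U11, U22, U33, U12, U13, U23)
#'   in the standard U^ij convention (A^2).
#' @param occupancy Site occupancy in (0, 1].
#' @return List of class `atom_site`.
#' @export
atom_site <- function(label, element, xyz, uiso = 0, uaniso = NULL, occupancy = 1) {
  stopifnot(length(xyz) == 3, occupancy > 0, occupancy <= 1)
  if (is.null(uaniso)) {
    if (uiso < 0) stop("U_iso must be >= 0 for ", label)
  } else {
    stopifnot(length(uaniso) == 6)
    U <- u6_to_mat(uaniso)
    if (min(eigen(U, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      stop("anisotropic U tensor not positive semidefinite for ", label)
    }
  }
  structure(list(label = label, element = element, xyz = as.numeric(xyz),
                 uiso = uiso, uaniso = if (is.null(uaniso)) NULL else as.numeric(uaniso),
                 occupancy = occupancy),
            class = "atom_site")
}

u6_to_mat <- function(u) {
  matrix(c(u[1], u[4], u[5], u[4], u[2], u[6], u[5], u[6], u[3]), 3, 3)
}
mat_to_u6 <- function(U) {
  c(U[1, 1], U[2, 2], U[3, 3], U[1, 2], U[1, 3], U[2, 3])
}

#' Crystal structure (cell + symmetry + asymmetric unit)
#'
#' @param cell A `unit_cell`.
#' @param sg A `space_group`.
#' @param sites List of `atom_site` objects (one asymmetric unit).
#' @param tol Site-matching tolerance in fractional units.
#' @return Object of class `crystal_structure`; each site gains a
#'   `multiplicity` field (orbit size under `sg`).
#' @export
crystal_structure <- function(cell, sg, sites, tol = 1e-4) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "space_group"))
  sites <- lapply(sites, function(s) {
    s$multiplicity <- nrow(site_orbit(sg, s$xyz, tol))
    s
  })
  labs <- vapply(sites, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("duplicate atom labels")
  structure(list(cell = cell, sg = sg, sites = sites, tol = tol),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal structure: %d sites in %s, V=%.1f A^3\n",
              length(x$sites), x$sg$symbol, x$cell$volume))
  invisible(x)
}

#' Expand the asymmetric unit to the full unit cell
#'
#' Generates the symmetry orbit of every site, merging duplicate images
#' closer than `tol` (fractional). Images of *different* labels that
#' collide raise an error. The result is a P1 structure.
#'
#' @param structure A `crystal_structure`.
#' @param tol Merge tolerance (fractional units).
#' @return A `crystal_structure` in P1 containing every image; labels are
#'   suffixed with the image number.
#' @export
expand_to_unit_cell <- function(structure, tol = structure$tol) {
  out <- list()
  pos <- NULL
  owner <- character(0)
  for (s in structure$sites) {
    orb <- site_orbit(structure$sg, s$xyz, tol)
    # anisotropic U must follow the generating rotation of each image
    for (i in seq_len(nrow(orb))) {
      p <- orb[i, ]
      if (!is.null(pos)) {
        for (j in seq_len(nrow(pos))) {
          if (frac_close(p, pos[j, ], tol) && owner[j] != s$label) {
            stop("sites ", s$label, " and ", owner[j],
                 " produce overlapping images but have distinct labels")
          }
        }
      }
      op <- find_generating_op(structure$sg, s$xyz, p, tol)
      ua <- if (is.null(s$uaniso)) NULL else
        mat_to_u6(op$R %*% u6_to_mat(s$uaniso) %*% t(op$R))
      out[[length(out) + 1]] <- atom_site(
        label = paste0(s$label, "_", i), element = s$element, xyz = p,
        uiso = s$uiso, uaniso = ua, occupancy = s$occupancy)
      pos <- rbind(pos, p)
      owner <- c(owner, s$label)
    }
  }
  crystal_structure(structure$cell, packaged_space_group("P1"), out, tol)
}

find_generating_op <- function(sg, xyz, image, tol) {
  for (op in sg$ops) {
    if (frac_close(apply_symop(op, xyz), image, tol)) return(op)
  }
  stop("no generating operator found")
}

#' Transform a structure to a new basis
#'
#' Applies an integer basis transformation with |det| = 1 (cell-preserving
#' reindexing, e.g. swapping the a and b axes). New cell vectors are
#' `a'_i = sum_j M[i,j] a_j`; fractional coordinates transform with the
#' inverse transpose, Miller indices with M itself.
#'
#' @param structure A `crystal_structure`.
#' @param M 3x3 integer matrix, |det(M)| = 1.
#' @return Transformed `crystal_structure`.
#' @export
transform_structure <- function(structure, M) {
  M <- matrix(as.numeric(M), 3, 3)
  d <- det(M)
  if (abs(abs(d) - 1) > 1e-9) stop("basis transform must have |det| = 1")
  G2 <- M %*% structure$cell$G %*% t(M)
  len <- sqrt(diag(G2))
  ang <- c(acos(G2[2, 3] / (len[2] * len[3])),
           acos(G2[1, 3] / (len[1] * len[3])),
           acos(G2[1, 2] / (len[1] * len[2]))) * 180 / pi
  cell2 <- build_cell(len[1], len[2], len[3], ang[1], ang[2], ang[3])
  Minv <- solve(M)
  # x' = (M^-T) x ; symop rotations R' = M^-T R M^T ; U' = (M^-T) U (M^-1)
  MT <- t(M); MinvT <- t(Minv)
  ops2 <- lapply(structure$sg$ops, function(op) {
    Rn <- MinvT %*% op$R %*% MT
    if (max(abs(Rn - round(Rn))) > 1e-9) {
      stop("symmetry operators are not integral in the transformed basis")
    }
    format_symop(list(R = round(Rn), t = as.numeric(MinvT %*% op$t) %% 1))
  })
  sg2 <- space_group(paste0(structure$sg$symbol, "'"), unlist(ops2))
  sites2 <- lapply(structure$sites, function(s) {
    ua <- if (is.null(s$uaniso)) NULL else
      mat_to_u6(MinvT %*% u6_to_mat(s$uaniso) %*% Minv)
    atom_site(s$label, s$element, as.numeric(MinvT %*% s$xyz),
              uiso = s$uiso, uaniso = ua, occupancy = s$occupancy)
  })
  crystal_structure(cell2, sg2, sites2, structure$tol)
}

#' Cartesian coordinates of the asymmetric-unit sites
#' @param structure A `crystal_structure`.
#' @return n x 3 matrix (Angstrom), rownames = labels.
#' @export
site_cartesian <- function(structure) {
  X <- t(vapply(structure$sites, `[[`, numeric(3), "xyz"))
  XC <- X %*% t(structure$cell$ortho)
  rownames(XC) <- vapply(structure$sites, `[[`, "", "label")
  XC
}

#' Interatomic distance between two labelled sites
#' @param structure A `crystal_structure`.
#' @param label1,label2 Site labels.
#' @return Distance in Angstrom (direct, no symmetry search).
#' @export
bond_length <- function(structure, label1, label2) {
  XC <- site_cartesian(structure)
  sqrt(sum((XC[label1, ] - XC[label2, ])^2))
}

#' Isotropic-equivalent displacement parameter U_eq
#'
#' U_eq is one third of the trace of the Cartesianized U tensor. For an
#' isotropic site it equals U_iso exactly.
#'
#' @param structure A `crystal_structure`.
#' @param label Site label.
#' @return U_eq in A^2.
#' @export
u_equiv <- function(structure, label) {
  s <- structure$sites[[match(label, vapply(structure$sites, `[[`, "", "label"))]]
  if (is.null(s$uaniso)) return(s$uiso)
  sum(diag(u_cartesian(structure$cell, s$uaniso))) / 3
}

# Cartesianized U tensor: U_cart = A U A' with A = ortho %*% diag(a*_i)
u_cartesian <- function(cell, u6) {
  astar <- sqrt(diag(cell$Gstar))
  A <- cell$ortho %*% diag(astar)
  A %*% u6_to_mat(u6) %*% t(A)
}
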