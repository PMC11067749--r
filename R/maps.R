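# Fourier difference electrostatic-potential maps, residual extrema,
# reflection-omission experiments, and fractal-dimension curves.

fft_friendly <- function(n) {
  ok <- function(m) {
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    m == 1
  }
  while (!ok(n)) n <- n + 1
  n
}

#' Default map grid dimensions
#'
#' Smallest FFT-friendly (2,3,5-smooth) integers giving a grid spacing
#' of at most d_min/3 along each cell axis.
#'
#' @param cell A `unit_cell`.
#' @param d_min Resolution of the coefficient set (A).
#' @return Integer vector (n1, n2, n3).
#' @export
map_grid <- function(cell, d_min) {
  as.integer(vapply(cell$abc, function(a) fft_friendly(ceiling(3 * a / d_min)), 0))
}

#' Fourier synthesis of a potential map
#'
#' `map(r) = (2 pi a0 / V) sum_h c_h exp(-2 pi i h.r)` on a regular
#' grid, with Hermitian completion (the Friedel mate `conj(c_h)` at -h
#' is added automatically; supply each reflection once). With electron
#' structure-factor coefficients in Angstrom the factor `2 pi a0`
#' converts to electrostatic potential in e A^-1. The 000 term is
#' excluded, so the map mean is zero.
#'
#' @param cell A `unit_cell`.
#' @param hkl n x 3 index matrix (no 000).
#' @param coef Complex coefficients (A).
#' @param grid Grid dimensions (default from [map_grid()] using the
#'   coefficient resolution).
#' @return Object of class `potential_map`: list with `values` (3D
#'   array, e A^-1), `grid`, `cell`.
#' @export
difference_map <- function(cell, hkl, coef, grid = NULL) {
  H <- rbind_hkl(hkl)
  if (any(rowSums(H != 0) == 0)) stop("000 term must be excluded from map synthesis")
  if (is.null(grid)) grid <- map_grid(cell, min(d_spacing(cell, H)))
  G <- array(0i, dim = grid)
  idx <- function(h) cbind(h[, 1] %% grid[1] + 1, h[, 2] %% grid[2] + 1,
                           h[, 3] %% grid[3] + 1)
  # deduplicate (keep first occurrence of an index)
  key <- apply(H, 1, paste, collapse = ",")
  keep <- !duplicated(key)
  H <- H[keep, , drop = FALSE]; coef <- coef[keep]
  G[idx(H)] <- G[idx(H)] + coef
  G[idx(-H)] <- G[idx(-H)] + Conj(coef)
  vals <- Re(stats::fft(G)) * 2 * pi * .const$a0 / cell$volume
  structure(list(values = vals, grid = grid, cell = cell),
            class = "potential_map")
}

#' Residual potential map from observed amplitudes and a model
#'
#' Difference Fourier synthesis with coefficients
#' `(|F_o|/k - |F_c|) exp(i phase_c)` over the supplied (symmetry-
#' unique) reflection set, expanded to all space-group equivalents with
#' phases transformed as `F(hR) = F(h) exp(-2 pi i h.t)`.
#'
#' @param structure A `crystal_structure` (model geometry).
#' @param models Scattering model set (electron radiation).
#' @param refl `reflection_set` with `Fobs` (amplitudes).
#' @param scale Scale k such that F_o/k matches F_c.
#' @param grid Optional grid dimensions.
#' @return A `potential_map`.
#' @export
residual_map <- function(structure, models, refl, scale = 1, grid = NULL) {
  H <- as.matrix(refl[, c("h", "k", "l")])
  Fc <- structure_factor(structure, models, H, "electron")
  dF <- (refl$Fobs / scale - Mod(Fc)) * exp(1i * Arg(Fc))
  # expand to all equivalents
  Hx <- NULL; cx <- NULL
  seen <- new.env(parent = emptyenv())
  for (op in structure$sg$ops) {
    Hp <- H %*% op$R
    ph <- exp(-2i * pi * as.numeric(H %*% op$t))
    for (i in seq_len(nrow(Hp))) {
      kk <- paste(Hp[i, ], collapse = ",")
      if (is.null(seen[[kk]])) {
        seen[[kk]] <- TRUE
        Hx <- rbind(Hx, Hp[i, ])
        cx <- c(cx, dF[i] * ph[i])
      }
    }
  }
  # drop one of each Friedel pair (difference_map adds the conjugate)
  keys <- paste(Hx[, 1], Hx[, 2], Hx[, 3])
  negk <- paste(-Hx[, 1], -Hx[, 2], -Hx[, 3])
  j <- match(negk, keys)
  keepF <- is.na(j) | j >= seq_along(j)
  if (is.null(grid)) grid <- map_grid(structure$cell, min(refl$d))
  difference_map(structure$cell, Hx[keepF, , drop = FALSE], cx[keepF], grid)
}

#' Map extrema with sub-voxel interpolation
#'
#' Global minimum and maximum of a potential map, refined by a 1D
#' parabolic fit along each axis, with optional nearest-atom labels.
#'
#' @param map A `potential_map`.
#' @param structure Optional `crystal_structure` for nearest-atom
#'   annotation.
#' @return List: `min`, `max` (values), `min_frac`, `max_frac`
#'   (fractional positions), `min_atom`, `max_atom` (labels or NA).
#' @export
map_extrema <- function(map, structure = NULL) {
  v <- map$values
  refine_peak <- function(flat_idx) {
    ijk <- arrayInd(flat_idx, dim(v))
    pos <- numeric(3)
    val <- v[flat_idx]
    peak <- val
    for (ax in 1:3) {
      n <- dim(v)[ax]
      im <- ijk; ip <- ijk
      im[ax] <- (ijk[ax] - 2) %% n + 1
      ip[ax] <- ijk[ax] %% n + 1
      y1 <- v[im]; y2 <- val; y3 <- v[ip]
      den <- y1 - 2 * y2 + y3
      dd <- if (abs(den) > 1e-300) 0.5 * (y1 - y3) / den else 0
      dd <- max(-0.5, min(0.5, dd))
      pos[ax] <- (ijk[ax] - 1 + dd) / n
      # vertex value of the per-axis parabola (separable approximation)
      if (abs(den) > 1e-300) peak <- peak - (y1 - y3)^2 / (8 * den)
    }
    list(pos = pos, val = peak)
  }
  mn <- refine_peak(which.min(v))
  mx <- refine_peak(which.max(v))
  nearest <- function(p) {
    if (is.null(structure)) return(NA_character_)
    labs <- vapply(structure$sites, `[[`, "", "label")
    best <- Inf; who <- NA_character_
    for (s in structure$sites) {
      orb <- site_orbit(structure$sg, s$xyz, structure$tol)
      for (i in seq_len(nrow(orb))) {
        d <- (orb[i, ] - p) %% 1
        d <- pmin(d, 1 - d)
        dc <- sqrt(sum((structure$cell$ortho %*% d)^2))
        if (dc < best) { best <- dc; who <- s$label }
      }
    }
    who
  }
  list(min = mn$val, max = mx$val, min_frac = mn$pos, max_frac = mx$pos,
       min_atom = nearest(mn$pos), max_atom = nearest(mx$pos))
}

#' Remove symmetry-equivalent reflection groups from a set
#'
#' Each group (e.g. c(1,1,0)) is expanded to all Laue-group equivalents
#' and every matching reflection is dropped. Groups absent from the set
#' give a warning, not an error.
#'
#' @param sg A `space_group`.
#' @param refl A `reflection_set` (or data frame with h, k, l).
#' @param groups List of index triples.
#' @return The filtered set, with attribute `n_removed`.
#' @export
omit_reflections <- function(sg, refl, groups) {
  drop <- rep(FALSE, nrow(refl))
  key <- paste(refl$h, refl$k, refl$l)
  for (g in groups) {
    eq <- laue_equivalents(sg, g)
    hit <- key %in% paste(eq[, 1], eq[, 2], eq[, 3])
    if (!any(hit)) {
      warning("no reflections match omission group (",
              paste(g, collapse = " "), ")")
    }
    drop <- drop | hit
  }
  out <- refl[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Fractal-dimension curve of a map
#'
#' `d_f(rho0) = ln N(rho0) / ln(N_total^(1/3))` where `N(rho0)` counts
#' grid voxels whose value lies within a window centred at rho0. The
#' window width is fixed at 1/100 of the map's value range so that
#' `n_bins` only controls how densely the curve is sampled (a denser
#' sampling resamples, it does not rescale, the curve). At the default
#' 100 sample points the windows tile the range and the counts sum to
#' the voxel total, so the bin covering the whole map gives d_f = 3
#' exactly. Featureless Gaussian residual maps give a parabola-like
#' curve.
#'
#' @param map A `potential_map`.
#' @param n_bins Number of curve sample points (>= 20).
#' @return Data frame: `rho` (window centre, e A^-1), `count`, `d_f`
#'   (NA where the window is empty).
#' @export
fractal_dimension_curve <- function(map, n_bins = 100) {
  if (n_bins < 20) stop("use at least 20 bins")
  v <- as.numeric(map$values)
  if (any(!is.finite(v))) stop("map contains non-finite values")
  rng <- range(v)
  w <- diff(rng) / 100
  rho <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_bins)
  vs <- sort(v)
  lo <- findInterval(rho - w / 2, vs)
  hi <- findInterval(rho + w / 2, vs)
  cnt <- hi - lo
  # the first window is closed on the left so every voxel is counted once
  cnt[1] <- cnt[1] + sum(vs <= rho[1] - w / 2)
  df <- ifelse(cnt > 0, 3 * log(cnt) / log(length(v)), NA_real_)
  data.frame(rho = rho, count = cnt, d_f = df)
}

#' Write a map in X-PLOR ASCII format
#'
#' @param map A `potential_map`.
#' @param path Output path.
#' @export
write_xplor <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  g <- map$grid
  writeLines("", con)
  writeLines("       1", con)
  writeLines("REMARKS residual potential map (e/A)", con)
  writeLines(sprintf("%8d%8d%8d%8d%8d%8d%8d%8d%8d",
                     g[1], 0, g[1] - 1, g[2], 0, g[2] - 1, g[3], 0, g[3] - 1), con)
  cellp <- c(map$cell$abc, map$cell$angles)
  writeLines(paste(sprintf("%12.5E", cellp), collapse = ""), con)
  writeLines("ZYX", con)
  for (k in seq_len(g[3])) {
    writeLines(sprintf("%8d", k - 1), con)
    vals <- as.numeric(map$values[, , k])
    lines <- split(vals, ceiling(seq_along(vals) / 6))
    for (ln in lines) writeLines(paste(sprintf("%12.5E", ln), collapse = ""), con)
  }
  writeLines(sprintf("%8d", -9999), con)
  writeLines(sprintf("%12.4E%12.4E", mean(map$values), stats::sd(map$values)), con)
  invisible(path)
}
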