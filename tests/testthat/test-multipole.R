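test_that("density-normalized harmonics integrate to the HC convention", {
  # quadrature oracle: integral |d_lm| dOmega = 2 for l > 0, and the
  # monopole integrates to 1. The harmonics separate into a polar
  # amplitude times cos/sin(m phi), so the azimuthal |.| integral is
  # analytic (2 pi for m = 0, 4 otherwise) and the polar factor is
  # integrated on a dense composite Gauss-Legendre grid that resolves
  # the |.| kinks.
  q <- gauss_legendre(8)
  panels <- 600
  edges <- seq(-1, 1, length.out = panels + 1)
  ctv <- as.numeric(outer(q$x, diff(edges) / 2) +
                      matrix((edges[-1] + edges[-length(edges)]) / 2,
                             length(q$x), panels, byrow = TRUE))
  wv <- as.numeric(outer(q$w, diff(edges) / 2))
  for (l in 0:4) {
    for (m in seq(-l, l)) {
      # phi where the azimuthal factor is 1
      ph <- if (m >= 0) 0 else pi / (2 * abs(m))
      stv <- sqrt(pmax(0, 1 - ctv^2))
      dirs <- cbind(stv * cos(ph), stv * sin(ph), ctv)
      polar <- sum(wv * abs(density_normalized_harmonic(l, m, dirs)))
      acc <- polar * if (m == 0) 2 * pi else 4
      expect_equal(acc, if (l == 0) 1 else 2, tolerance = 1e-6,
                   label = sprintf("integral |d_%d%+d|", l, m))
    }
  }
  # monopole is constant, dipole peaks along z
  dirs <- matrix(rnorm(30), 10, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_equal(density_normalized_harmonic(0, 0, dirs), rep(1 / (4 * pi), 10))
  zmax <- density_normalized_harmonic(1, 0, c(0, 0, 1))
  expect_true(all(density_normalized_harmonic(1, 0, dirs) <= zmax + 1e-12))
  expect_error(density_normalized_harmonic(5, 0, c(0, 0, 1)))
})

test_that("dipole density-normalization constant matches the analytic value", {
  # integral |cos| over the sphere = 2 pi, so C_10 = 2 / (2 pi sqrt(3/4pi))
  got <- density_normalized_harmonic(1, 0, c(0, 0, 1))
  expect_equal(got, 2 / (2 * pi), tolerance = 1e-9)
})

test_that("closed-form Slater Fourier-Bessel transforms match quadrature", {
  # limits: normalization at s = 0, small-argument Bessel behaviour
  expect_equal(slater_fourier_bessel(0, 2, 5, 0), 1)
  for (l in 1:4) expect_equal(slater_fourier_bessel(l, l, 5, 0), 0)
  # oracle = adaptive quadrature of the defining integral, with the
  # spherical Bessel function taken from base R: j_l = sqrt(pi/2x) J_{l+1/2}
  jl_num <- function(l, x) ifelse(x < 1e-8, if (l == 0) 1 else 0,
                                  sqrt(pi / (2 * x)) * besselJ(x, l + 0.5))
  worst <- 0
  for (l in 0:4) for (n in c(l, l + 2)) for (zeta in c(4, 9)) {
    for (s in c(0.02, 0.08, 0.3, 0.7, 1.2)) {
      K <- 4 * pi * s
      f <- function(r) zeta^(n + 3) / factorial(n + 2) * r^(n + 2) *
        exp(-zeta * r) * jl_num(l, K * r)
      oracle <- stats::integrate(f, 0, 80 / zeta, rel.tol = 1e-12,
                                 subdivisions = 4000)$value
      got <- slater_fourier_bessel(l, n, zeta, s)
      worst <- max(worst, abs(got - oracle) / max(abs(oracle), 1e-10))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("kappa scaling acts as a pure dilation of the valence transform", {
  sh <- element_shells()[["O"]]
  s <- seq(0.05, 1, 0.05)
  for (kap in c(0.8, 1.2)) {
    a <- slater_fourier_bessel(0, sh$val$n, sh$val$zeta, s / kap)
    b <- slater_fourier_bessel(0, sh$val$n, sh$val$zeta * kap, s)
    # scaling zeta by kappa equals evaluating at s/kappa (dilation theorem)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("allowed multipoles equal the brute-force symmetry filter", {
  set.seed(7)
  dirs <- matrix(rnorm(1500), 500, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  lm_all <- do.call(rbind, lapply(1:4, function(l) cbind(l = l, m = seq(-l, l))))
  for (sym in c("m", "3m")) {
    gens <- site_symmetry_generators(sym)
    brute <- apply(lm_all, 1, function(r) {
      all(vapply(gens, function(G) {
        max(abs(density_normalized_harmonic(r[1], r[2], dirs) -
                  density_normalized_harmonic(r[1], r[2], dirs %*% t(G)))) < 1e-10
      }, TRUE))
    })
    got <- allowed_multipoles(sym, 4)
    expect_setequal(paste(got$l, got$m),
                    paste(lm_all[brute, 1], lm_all[brute, 2]))
  }
  expect_equal(nrow(allowed_multipoles("1", 4)), 24)
  cyl <- allowed_multipoles("cyl", 4)
  expect_true(all(cyl$m == 0))
  expect_error(allowed_multipoles("6mm"))
})

test_that("aspherical form factor reduces, counts electrons and obeys symmetry", {
  m0 <- multipole_model("O1", "O", P_val = 6, kappa = 1)
  s <- seq(0, 1, 0.1)
  sh <- element_shells()[["O"]]
  spherical <- sh$P_c * slater_fourier_bessel(0, sh$core$n, sh$core$zeta, s) +
    6 * slater_fourier_bessel(0, sh$val$n, sh$val$zeta, s)
  expect_equal(Re(aspherical_form_factor(m0, s)), spherical, tolerance = 1e-14)
  expect_equal(Re(aspherical_form_factor(m0, 0)), 8)
  # declared site symmetry is inherited by the form factor
  mm <- multipole_model("O1", "O", P_val = 6.2,
                        plm = data.frame(l = c(1, 2), m = c(1, 0), P = c(0.08, -0.1)),
                        site_symmetry = "m")
  set.seed(3)
  dirs <- matrix(rnorm(60), 20, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  mir <- dirs %*% diag(c(1, 1, -1))
  sv <- runif(20, 0.1, 0.8)
  expect_equal(aspherical_form_factor(mm, sv, dirs),
               aspherical_form_factor(mm, sv, mir), tolerance = 1e-10)
  # forbidden populations are rejected
  expect_error(multipole_model("O1", "O", P_val = 6,
                               plm = data.frame(l = 1, m = 0, P = 0.1),
                               site_symmetry = "m"), "forbidden")
})

test_that("form factor equals the direct-space Fourier transform oracle", {
  m <- multipole_model("X", "N", P_val = 5.1,
                       plm = data.frame(l = c(1, 2, 3, 4), m = c(1, 0, -2, 3),
                                        P = c(0.06, -0.08, 0.04, 0.02)),
                       kappa = 0.97, kappa_prime = 1.08)
  qt <- gauss_legendre(40)
  nphi <- 80
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  qr <- gauss_legendre(110)
  rmax <- 6
  rr <- (qr$x + 1) / 2 * rmax
  wr <- qr$w / 2 * rmax
  set.seed(8)
  for (trial in 1:3) {
    hv <- rnorm(3)
    hdir <- hv / sqrt(sum(hv^2))
    s <- runif(1, 0.1, 0.7)
    got <- aspherical_form_factor(m, s, matrix(hdir, 1))
    acc <- 0 + 0i
    for (k in seq_along(qt$x)) {
      ct <- qt$x[k]; stq <- sqrt(1 - ct^2)
      dirs <- cbind(stq * cos(phi), stq * sin(phi), ct)
      for (ir in seq_along(rr)) {
        pts <- dirs * rr[ir]
        rho <- pseudoatom_density(m, pts)
        ph <- exp(2i * pi * 2 * s * (pts %*% hdir))
        acc <- acc + qt$w[k] * (2 * pi / nphi) * wr[ir] * rr[ir]^2 * sum(rho * ph)
      }
    }
    expect_lt(Mod(got - acc), 1e-4)
  }
})

test_that("local frames are orthonormal and rotate with the structure", {
  st <- fixture_structure()
  fr <- list(ref1 = "C2", ref2 = "C6", axis1 = "x", axis2 = "y")
  R <- build_local_frame(st, "N1", fr)
  expect_equal(unname(t(R) %*% R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_error(build_local_frame(st, "N1",
    list(ref1 = "N1", ref2 = "C2", axis1 = "x", axis2 = "y")))
  # frame-aware form factors are invariant under rigid rotation of both
  # the structure (via a cubic P1 copy) and the scattering vector
  cell <- build_cell(20, 20, 20)
  p1 <- packaged_space_group("P1")
  xyz <- list(A = c(0.50, 0.50, 0.50), B = c(0.57, 0.50, 0.50), C = c(0.50, 0.56, 0.50))
  mk <- function(rot) {
    pts <- lapply(xyz, function(x) {
      v <- rot %*% (x - 0.5) + 0.5
      as.numeric(v)
    })
    crystal_structure(cell, p1, list(
      atom_site("A", "O", pts$A, uiso = 0),
      atom_site("B", "C", pts$B, uiso = 0),
      atom_site("C", "N", pts$C, uiso = 0)))
  }
  models <- list(
    A = multipole_model("A", "O", 6.2,
                        plm = data.frame(l = c(1, 2), m = c(1, 0), P = c(0.1, -0.08)),
                        frame = list(ref1 = "B", ref2 = "C", axis1 = "x", axis2 = "y")),
    B = iam_model("B", "C"), C = iam_model("C", "N"))
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  H <- matrix(c(3, 1, 2, -2, 4, 1, 5, 0, -3), 3, 3, byrow = TRUE)
  F0 <- structure_factor(mk(diag(3)), models, H)
  # rotating the structure about the cell centre maps reciprocal vectors
  # with the same rotation: h' = h R^T (cubic cell, fractional = Cartesian/20)
  Hrot <- H %*% t(rot)
  F1 <- structure_factor(mk(rot), models, Hrot)
  expect_equal(F1 / F0, exp(2i * pi * ((Hrot - H) %*% rep(0.5, 3)))[, 1],
               tolerance = 1e-10)
})

test_that("multipole parameter files round-trip exactly", {
  models <- fixture_multipoles("databank")
  path <- tempfile(fileext = ".txt")
  write_multipole_file(models, path)
  back <- read_multipole_file(path)
  expect_equal(names(back), names(models))
  for (lb in names(models)) {
    expect_equal(back[[lb]]$P_val, models[[lb]]$P_val)
    expect_equal(back[[lb]]$kappa, models[[lb]]$kappa)
    expect_equal(back[[lb]]$kappa_prime, models[[lb]]$kappa_prime)
    expect_equal(back[[lb]]$plm$P, models[[lb]]$plm$P)
    expect_equal(back[[lb]]$site_symmetry, models[[lb]]$site_symmetry)
  }
})
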