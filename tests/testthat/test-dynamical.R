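test_that("excitation errors follow Ewald-sphere geometry", {
  st <- fixture_structure()
  lam <- electron_wavelength(200)
  zone <- zone_axis_orientation(st$cell, c(0, 0, 1))
  H <- matrix(c(2, 2, 0, 1, 3, 0, 4, 0, 0), 3, 3, byrow = TRUE)
  S <- excitation_error(st$cell, zone, lam, H)
  g2 <- 1 / d_spacing(st$cell, H)^2
  expect_equal(S, -g2 * lam / 2, tolerance = 1e-10)
  # tilting toward g reduces |S_g| before crossing the sphere
  g <- c(2, 2, 0)
  s0 <- abs(excitation_error(st$cell, zone, lam, g))
  gdir <- recip_cartesian(st$cell, g)
  gdir <- gdir / sqrt(sum(gdir^2))
  # Bragg needs k.g = -g^2/2: tilt the beam away from +g (by less than
  # the Bragg tilt g*lambda/2 so the sphere is not crossed)
  tilted <- zone - 0.001 * as.numeric(gdir)
  s1 <- abs(excitation_error(st$cell, tilted / sqrt(sum(tilted^2)), lam, g))
  expect_lt(s1, s0)
})

test_that("relative excitation errors are bounded and grid-stable", {
  st <- fixture_structure()
  lam <- electron_wavelength(200)
  zone <- zone_axis_orientation(st$cell, c(0, 0, 1))
  H <- as.matrix(all_reflections(st$cell, st$sg, 2.5)[, c("h", "k", "l")])
  expect_error(relative_excitation_error(st$cell, zone, lam, 0, H))
  rs1 <- relative_excitation_error(st$cell, zone, lam, 0.7, H, n_azimuth = 360)
  rs2 <- relative_excitation_error(st$cell, zone, lam, 0.7, H, n_azimuth = 720)
  expect_equal(rs1, rs2, tolerance = 1e-4)
  # beams crossing the sphere during precession have RS <= 1; a beam at
  # exact Bragg has RS = 0
  dirb <- tilt_orientation(zone, 0.35, 10)
  Sb <- excitation_error(st$cell, dirb, lam, H)
  near <- which.min(abs(Sb))
  rsb <- relative_excitation_error(st$cell, dirb, lam, 0.7,
                                   H[near, , drop = FALSE])
  expect_lte(rsb, 1 + 1e-9)
})

test_that("beam selection applies every cut and equals a brute-force filter", {
  st <- fixture_structure()
  lam <- electron_wavelength(200)
  zone <- zone_axis_orientation(st$cell, c(0, 0, 1))
  cand <- all_reflections(st$cell, st$sg, 1.4)
  bs <- select_beams(st$cell, cand, zone, lam, phi_deg = 0.7,
                     d_min = 1.4, S_max = 0.01, RS_max = 0.75)
  expect_equal(as.numeric(bs[1, c("h", "k", "l")]), c(0, 0, 0))
  H <- as.matrix(cand[, c("h", "k", "l")])
  S <- excitation_error(st$cell, zone, lam, H)
  keep <- abs(S) <= 0.01
  RS <- relative_excitation_error(st$cell, zone, lam, 0.7, H[keep, , drop = FALSE])
  n_expected <- sum(RS <= 0.75)
  expect_equal(nrow(bs) - 1, n_expected)
  expect_true(all(abs(bs$S_g[-1]) <= 0.01))
  expect_true(all(bs$RS_g[-1] <= 0.75))
  # loose thresholds pass everything
  bs_all <- select_beams(st$cell, cand, zone, lam, phi_deg = 0,
                         d_min = 1.4, S_max = 1e9, RS_max = 1e9,
                         max_beams = 2000)
  expect_equal(nrow(bs_all) - 1, nrow(cand))
  expect_error(select_beams(st$cell, cand, zone, lam, d_min = 1.4,
                            S_max = 1e-12))
})

test_that("Bloch intensities: identity at t=0, unitarity, two-beam oracle", {
  lam <- electron_wavelength(200)
  K <- 1 / lam
  n <- 6
  set.seed(31)
  S <- c(0, rnorm(n - 1, 0, 0.01))
  U <- matrix(0i, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    u <- complex(real = rnorm(1, 0, 2e-3), imaginary = rnorm(1, 0, 2e-3))
    U[i, j] <- u
    U[j, i] <- Conj(u)
  }
  I0 <- bloch_intensities(S, U, K, 0)
  expect_equal(as.numeric(I0), c(1, rep(0, n - 1)), tolerance = 1e-12)
  for (t in c(30, 90, 250)) {
    It <- bloch_intensities(S, U, K, t)
    expect_equal(sum(It), 1, tolerance = 1e-10)
  }
  # two-beam pendelloesung closed form over an (S, U, t) grid
  worst <- 0
  for (Sg in c(0, 0.004, -0.012)) for (Ug in c(5e-4, 2e-3, 6e-3)) {
    for (t in c(40, 120, 260)) {
      U2 <- matrix(c(0, Ug, Ug, 0), 2, 2) + 0i
      got <- bloch_intensities(c(0, Sg), U2, K, t)[1, 2]
      seff <- sqrt(Sg^2 + (Ug / K)^2)
      closed <- (Ug / (K * seff))^2 * sin(pi * t * 10 * seff)^2
      worst <- max(worst, abs(got - closed))
    }
  }
  expect_lt(worst, 1e-8)
  # non-Hermitian input is rejected (no absorption supported)
  Ubad <- U
  Ubad[1, 2] <- Ubad[1, 2] + 0.1
  expect_error(bloch_intensities(S, Ubad, K, 50), "Hermitian")
})

test_that("precession averaging degenerates and converges properly", {
  st <- fixture_structure()
  mods <- iam_models(st)
  lam <- electron_wavelength(200)
  dir <- tilt_orientation(zone_axis_orientation(st$cell, c(0, 0, 1)), 4, 30)
  cand <- all_reflections(st$cell, st$sg, 1.3)
  beams <- select_beams(st$cell, cand, dir, lam, phi_deg = 0.7,
                        d_min = 1.3, S_max = 0.012)
  static <- precession_average(st, mods, beams, dir, 200, 90, phi_deg = 0)
  solver <- dyn_frame_solver(st, mods, beams, dir, 200, phi_deg = 0)
  expect_equal(static$I, as.numeric(solver$intensity(90)), tolerance = 1e-14)
  a64 <- precession_average(st, mods, beams, dir, 200, 90, 0.7, n_azimuth = 64)
  a128 <- precession_average(st, mods, beams, dir, 200, 90, 0.7, n_azimuth = 128)
  expect_lt(max(abs(a128$I - a64$I)) / max(a64$I), 1e-4)
  expect_equal(sum(a64$I), 1, tolerance = 1e-10)
  # thin-crystal limit: averaged dynamical intensities correlate with
  # kinematical |F_e|^2 (rank correlation on the strong beams)
  thin <- precession_average(st, mods, beams, dir, 200, 4, 0.7, n_azimuth = 16)
  Fe2 <- Mod(structure_factor(st, mods,
                              as.matrix(thin[-1, c("h", "k", "l")]), "electron"))^2
  sel <- thin$I[-1] > max(thin$I[-1]) * 1e-4
  expect_gt(cor(thin$I[-1][sel], Fe2[sel], method = "spearman"), 0.9)
})

test_that("thickness and scales are recovered from frames", {
  st <- fixture_structure()
  mods <- iam_models(st)
  # noise-free closed loop: exact recovery, R ~ 0
  sim0 <- simulate_frames(st, mods, t_nm = 95, n_frames = 2, noise_frac = 0,
                          d_min = 1.3, S_max = 0.008, n_azimuth = 8, seed = 41)
  fit0 <- refine_thickness_scale(sim0$frames, st, mods, 200,
                                 t_range = c(40, 200))
  expect_equal(unname(fit0$thickness), 95, tolerance = 0.05)
  expect_lt(fit0$R_all, 0.1)
  # amplitude scales equal the square root of the intensity scales
  expect_equal(unname(fit0$scales), sqrt(sim0$truth$scales), tolerance = 1e-3)
  # frame order invariance
  fit0r <- refine_thickness_scale(rev(sim0$frames), st, mods, 200,
                                  t_range = c(40, 200))
  expect_equal(unname(fit0r$thickness), unname(fit0$thickness), tolerance = 1e-6)
})

test_that("frame files round-trip", {
  st <- fixture_structure()
  mods <- iam_models(st)
  sim <- simulate_frames(st, mods, t_nm = 80, n_frames = 2, noise_frac = 0.02,
                         d_min = 1.4, S_max = 0.008, n_azimuth = 4, seed = 8)
  path <- tempfile(fileext = ".frames")
  write_frames(sim$frames, electron_wavelength(200), path)
  back <- read_frames(path)
  expect_equal(length(back$frames), 2)
  expect_equal(back$lambda, electron_wavelength(200), tolerance = 1e-6)
  for (i in 1:2) {
    expect_equal(unname(back$frames[[i]]$hkl), unname(sim$frames[[i]]$hkl))
    expect_equal(back$frames[[i]]$Iobs, sim$frames[[i]]$Iobs, tolerance = 1e-6)
    expect_equal(back$frames[[i]]$crystal, sim$frames[[i]]$crystal)
  }
})
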