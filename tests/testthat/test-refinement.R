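test_that("weighting scheme formula and clamping", {
  expect_equal(weight_shelx(4, 4, 1, 0, 0), 1)
  # negative measured intensity clamps to zero in P
  P <- pmax(0, -3) / 3 + 2 * 6 / 3
  expect_equal(P, 4)
  w <- weight_shelx(-3, 6, 2, 0.1, 0.5)
  expect_equal(w, 1 / (4 + (0.1 * 4)^2 + 0.5 * 4))
})

test_that("automatic (a,b) selection flattens binned weighted residuals", {
  set.seed(21)
  n <- 1200
  Fc2 <- exp(runif(n, 0, 8))
  sig <- 1
  a_true <- 0.05
  noise <- sqrt(sig^2 + (a_true * Fc2)^2)
  Fo2 <- Fc2 + rnorm(n) * noise
  ab <- select_weight_ab(Fo2, Fc2, rep(sig, n))
  w <- weight_shelx(Fo2, Fc2, rep(sig, n), ab$a, ab$b)
  bins <- cut(rank(Fc2, ties.method = "first"), 10, labels = FALSE)
  m <- tapply(w * (Fo2 - Fc2)^2, bins, mean)
  expect_lt(max(m) / min(m), 2)
})

test_that("R factors and shell statistics match hand arithmetic", {
  expect_equal(r_factor(c(10, 20), c(10, 20)), 0)
  expect_equal(r_factor(c(10, 20), c(8, 22)), 100 * 4 / 30, tolerance = 1e-12)
  expect_error(r_factor(c(10), c(8), observed = FALSE, subset = "obs"))
  set.seed(5)
  Fo <- runif(100, 1, 50); Fc <- Fo * (1 + rnorm(100, 0, 0.05))
  expect_equal(r_factor(Fo, Fc), 100 * sum(abs(Fo - Fc)) / sum(Fo))
  d <- runif(100, 0.8, 8)
  sh <- shell_statistics(d, Fo, Fc, 1, 8)
  expect_true(all(abs(sh$n - 100 / 8) <= 1))
  # corrupting one low-angle reflection only changes the first shell
  Fo2 <- Fo
  Fo2[which.max(d)] <- Fo2[which.max(d)] + 30
  sh2 <- shell_statistics(d, Fo2, Fc, 1, 8)
  expect_true(sh2$R[1] != sh$R[1])
  expect_equal(sh2$R[-1], sh$R[-1])
  expect_error(shell_statistics(d[1:5], Fo[1:5], Fc[1:5], 1, 8))
})

test_that("me_rmsd matches its definition", {
  expect_equal(me_rmsd(c(1, 2), c(1, 2)), list(ME = 0, RMSD = 0))
  st <- me_rmsd(c(1.1, 0.9), c(1, 1))
  expect_equal(st$ME, 0)
  expect_equal(st$RMSD, 0.1)
  expect_error(me_rmsd(1:3, 1:2))
})

test_that("structural refinement recovers a perturbed structure exactly", {
  exp1 <- recovery_experiment()
  st <- exp1$truth
  mods <- exp1$models
  refl <- exp1$refl
  spec <- exp1$spec
  # start at truth: immediate convergence with zero R
  r0 <- refine(refl, st, mods, spec, "electron")
  expect_lt(r0$R_all, 1e-8)
  expect_lte(r0$n_cycles, 2)
  # perturbed start (~0.02 A coordinate shifts, 8% ADP scaling)
  r1 <- exp1$result
  for (i in seq_along(st$sites)) {
    expect_lt(max(abs(r1$structure$sites[[i]]$xyz - st$sites[[i]]$xyz)), 5e-4)
    if (!is.null(st$sites[[i]]$uaniso)) {
      expect_lt(max(abs(r1$structure$sites[[i]]$uaniso - st$sites[[i]]$uaniso)) /
                  max(abs(st$sites[[i]]$uaniso)), 0.01)
    } else {
      expect_lt(abs(r1$structure$sites[[i]]$uiso - st$sites[[i]]$uiso) /
                  st$sites[[i]]$uiso, 0.01)
    }
  }
  expect_equal(r1$scale, 1, tolerance = 1e-6)
  # residual history non-increasing over accepted steps
  expect_true(all(diff(r1$history) <= 1e-9 * r1$history[1]))
  # special positions honoured: mirror atoms stay at z = 0
  for (s in r1$structure$sites) {
    if (s$label != "H7b") expect_equal(s$xyz[3], 0)
  }
})

test_that("sigma rescaling doubles esds but leaves estimates unchanged", {
  st <- fixture_structure()
  mods <- iam_models(st)
  sim <- simulate_reflections(st, mods, d_min = 1.2, radiation = "electron",
                              noise = "gaussianF2", sigma_floor = 0.5,
                              c_frac = 0.01, seed = 23)
  refl <- sim$refl
  spec <- refinement_spec(refine = c("xyz", "scale"), target = "F2",
                          weights = "sigma", max_cycles = 40,
                          shift_esd_tol = 1e-5)
  r1 <- refine(refl, st, mods, spec, "electron")
  refl2 <- refl
  refl2$sigma <- refl2$sigma * 2
  r2 <- refine(refl2, st, mods, spec, "electron")
  x1 <- unlist(lapply(r1$structure$sites, `[[`, "xyz"))
  x2 <- unlist(lapply(r2$structure$sites, `[[`, "xyz"))
  expect_equal(x2, x1, tolerance = 1e-7)
  ok <- is.finite(r1$esd) & r1$esd > 0
  expect_equal(unname(r2$esd[ok] / r1$esd[ok]), rep(2, sum(ok)), tolerance = 1e-5)
})

test_that("multipole fitting honours constraints and frozen kappa-prime", {
  st <- fixture_structure()
  for (i in seq_along(st$sites)) { st$sites[[i]]$uaniso <- NULL; st$sites[[i]]$uiso <- 0 }
  truth <- fixture_multipoles("databank")
  sim <- simulate_reflections(st, truth, d_min = 1.1, radiation = "xray",
                              noise = "none", seed = 3)
  expect_error(refine_multipoles(within(sim$refl, rm(phase)), st, truth),
               "phase")
  # start at truth: zero shifts, kappa' frozen bit-exact
  fit <- refine_multipoles(sim$refl, st, truth, radiation = "xray",
                           freeze_kappa_prime = TRUE, max_cycles = 3)
  for (lb in names(truth)) {
    expect_equal(fit$models[[lb]]$kappa_prime, truth[[lb]]$kappa_prime)
    expect_equal(fit$models[[lb]]$P_val, truth[[lb]]$P_val, tolerance = 1e-6)
    # cylindrical hydrogens keep only m = 0 terms (never parameters)
    if (truth[[lb]]$site_symmetry == "cyl") {
      expect_true(all(fit$models[[lb]]$plm$m == 0))
    }
  }
  expect_lt(fit$R_all, 1e-6)
})

test_that("bond and ADP statistics are computed with esd propagation", {
  st <- fixture_structure()
  bonds <- xh_bond_table(st, fixture_xh_ref)
  expect_setequal(bonds$atom2, names(fixture_xh_ref))
  expect_equal(bonds$atom1[bonds$atom2 == "H3"], "N3")
  # refined = reference gives zero statistics
  cur <- xh_bond_table(st)
  bs0 <- bond_length_stats(st, cur)
  expect_equal(bs0$ME, 0, tolerance = 1e-12)
  expect_equal(bs0$RMSD, 0, tolerance = 1e-12)
  # U_eq of an isotropic site equals U_iso; aniso equals the eigenvalue mean
  expect_equal(u_equiv(st, "H3"), st$sites[[5]]$uiso)
  U <- aspherED:::u_cartesian(st$cell, st$sites[[1]]$uaniso)
  expect_equal(u_equiv(st, "N1"), mean(eigen(U)$values), tolerance = 1e-12)
  as0 <- adp_stats(st, st)
  expect_equal(as0$nonH$ME, 0)
  expect_equal(as0$H$RMSD, 0)
})
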