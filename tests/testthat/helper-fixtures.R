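# Shared fixtures and memoised expensive computations. Everything is a
# pure function of fixed seeds so reruns are reproducible.

.memo <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

fixture_xh_ref <- c(H3 = 1.0425, H5 = 1.0812, H6 = 1.0877,
                    H7a = 1.0826, H7b = 1.0878)

# Gauss-Legendre nodes/weights on [-1, 1] (oracle-side quadrature)
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# noise-free perturbed-start structural recovery (IAM data, IAM model)
recovery_experiment <- function() {
  memo("recovery", {
    st <- fixture_structure()
    mods <- iam_models(st)
    sim <- simulate_reflections(st, mods, d_min = 1.05, radiation = "electron",
                                noise = "none", seed = 7)
    refl <- sim$refl
    refl$Iobs <- refl$Fobs^2
    refl$sigma <- rep(1, nrow(refl))
    refl$observed <- TRUE
    spec <- refinement_spec(target = "F2", weights = "unit", max_cycles = 30)
    set.seed(11)
    st2 <- st
    for (i in seq_along(st2$sites)) {
      s <- st2$sites[[i]]
      B <- site_constraints(st2$sg, s$xyz)$xyz_basis
      s$xyz <- s$xyz + as.numeric(B %*% rnorm(ncol(B), 0, 0.0012))
      if (!is.null(s$uaniso)) s$uaniso <- s$uaniso * 1.08 else s$uiso <- s$uiso * 1.1
      st2$sites[[i]] <- s
    }
    res <- refine(refl, st2, mods, spec, "electron", scale = 1.05)
    list(truth = st, start = st2, refl = refl, result = res, spec = spec,
         models = mods)
  })
}

# electron-data structural refinement of the fixture with IAM against
# multipole-generated noise-free data (the refinement-bias experiment);
# shared between trend tests
trend_refinement <- function() {
  memo("trend", {
    st <- fixture_structure()
    tm <- fixture_multipoles("databank")
    sim <- simulate_reflections(st, tm, d_min = 0.8, radiation = "electron",
                                noise = "none", seed = 17)
    refl <- sim$refl
    refl$Iobs <- refl$Fobs^2
    refl$sigma <- rep(1, nrow(refl))
    refl$observed <- TRUE
    spec <- refinement_spec(target = "F2", weights = "shelx_auto",
                            max_cycles = 40)
    res <- refine(refl, st, iam_models(st), spec, "electron")
    list(truth = st, sim = sim, result = res)
  })
}
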