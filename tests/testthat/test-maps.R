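test_that("map synthesis: single wave, zero map, zero mean, linearity", {
  cell <- build_cell(13.3, 13.7, 6.2)
  grid <- c(30, 30, 30)
  m <- difference_map(cell, rbind(c(2, 0, 0)), complex(real = 0.5), grid)
  x <- (0:29) / 30
  amp <- 2 * pi * 0.529177210903 / cell$volume
  expect_equal(m$values[, 1, 1], amp * 2 * 0.5 * cos(2 * pi * 2 * x),
               tolerance = 1e-14)
  expect_equal(mean(m$values), 0, tolerance = 1e-15)
  expect_error(difference_map(cell, rbind(c(0, 0, 0)), complex(real = 1)))
  # linearity and sign flip
  H2 <- rbind(c(2, 0, 0), c(1, 1, 1))
  c1 <- complex(real = c(0.5, -0.2), imaginary = c(0, 0.3))
  c2 <- complex(real = c(-0.1, 0.4), imaginary = c(0.2, 0))
  mm <- function(co) difference_map(cell, H2, co, grid)$values
  expect_equal(mm(2 * c1 + 3 * c2), 2 * mm(c1) + 3 * mm(c2), tolerance = 1e-13)
  ex1 <- map_extrema(difference_map(cell, H2, c1, grid))
  ex2 <- map_extrema(difference_map(cell, H2, -c1, grid))
  expect_equal(ex2$min, -ex1$max, tolerance = 1e-12)
  expect_equal(ex2$max, -ex1$min, tolerance = 1e-12)
})

test_that("synthesis/analysis round trip recovers the coefficients", {
  cell <- build_cell(10, 11, 12)
  grid <- c(16, 16, 16)
  H <- rbind(c(1, 0, 0), c(2, 3, -1), c(0, -2, 4))
  co <- complex(real = c(1.5, -0.7, 0.3), imaginary = c(0, 0.4, -0.2))
  m <- difference_map(cell, H, co, grid)
  # analysis: the forward FFT of the map returns each coefficient at -h
  G <- fft(m$values) / prod(grid) / (2 * pi * 0.529177210903 / cell$volume)
  idx <- cbind((-H[, 1]) %% 16 + 1, (-H[, 2]) %% 16 + 1, (-H[, 3]) %% 16 + 1)
  expect_equal(G[idx], co, tolerance = 1e-10)
})

test_that("residual maps vanish for a perfect model and find planted peaks", {
  st <- fixture_structure()
  mods <- iam_models(st)
  sim <- simulate_reflections(st, mods, d_min = 1.2, radiation = "electron",
                              noise = "none", seed = 1)
  m0 <- residual_map(st, mods, sim$refl)
  expect_equal(max(abs(m0$values)), 0, tolerance = 1e-12)
  # a planted band-limited Gaussian peak is located and measured
  cell <- st$cell
  grid <- map_grid(cell, 1.0)
  uni <- unique_reflections(cell, packaged_space_group("P1"), 1.0)
  H <- as.matrix(uni[, c("h", "k", "l")])
  x0 <- c(0.31, 0.62, 0.25)
  sig <- 0.6    # Angstrom
  height <- 0.30
  # Fourier coefficients of a periodic Gaussian of peak height 0.30 e/A;
  # the synthesis convention exp(-2 pi i h.x) needs a +h.x0 shift phase
  q2 <- 1 / d_spacing(cell, H)^2
  vol_factor <- height * (2 * pi * sig^2)^(3 / 2)
  co <- vol_factor * exp(-2 * pi^2 * sig^2 * q2) * exp(+2i * pi * (H %*% x0)) /
    (2 * pi * 0.529177210903)
  mp <- difference_map(cell, H, co, grid)
  ex <- map_extrema(mp, st)
  # generator truth: the band-limited peak value at x0
  peak_true <- 2 * pi * 0.529177210903 / cell$volume *
    sum(Re(co * exp(-2i * pi * (H %*% x0))) * 2)
  expect_equal(ex$max, peak_true, tolerance = 0.01)
  expect_equal(peak_true, height, tolerance = 0.05)
  dd <- (ex$max_frac - x0) %% 1
  dd <- pmin(dd, 1 - dd)
  expect_lt(sqrt(sum((cell$ortho %*% dd)^2)), 0.3)
})

test_that("reflection omission expands symmetry groups", {
  st <- fixture_structure()
  sim <- simulate_reflections(st, iam_models(st), d_min = 1.5,
                              radiation = "electron", noise = "none", seed = 2)
  refl <- sim$refl
  out <- omit_reflections(st$sg, refl, list())
  expect_equal(nrow(out), nrow(refl))
  out1 <- omit_reflections(st$sg, refl, list(c(1, 1, 0)))
  # brute-force: every equivalent of {110} gone
  eq <- laue_equivalents(st$sg, c(1, 1, 0))
  keys <- paste(out1$h, out1$k, out1$l)
  expect_false(any(keys %in% paste(eq[, 1], eq[, 2], eq[, 3])))
  expect_equal(attr(out1, "n_removed"), nrow(refl) - nrow(out1))
  expect_warning(omit_reflections(st$sg, refl, list(c(25, 0, 1))), "no reflections")
})

test_that("omitting a planted worst reflection shrinks the residual extrema", {
  st <- fixture_structure()
  mods <- iam_models(st)
  sim <- simulate_reflections(st, mods, d_min = 1.2, radiation = "electron",
                              noise = "none", seed = 3)
  refl <- sim$refl
  # corrupt the 110 amplitude
  i110 <- which(abs(refl$h) == 1 & abs(refl$k) == 1 & refl$l == 0)[1]
  refl$Fobs[i110] <- refl$Fobs[i110] * 1.6 + 2
  m_bad <- residual_map(st, mods, refl)
  m_fix <- residual_map(st, mods,
                        omit_reflections(st$sg, refl, list(c(1, 1, 0))))
  expect_lt(max(abs(m_fix$values)), max(abs(m_bad$values)))
})

test_that("fractal curves: full-map value, noise parabola, bin stability", {
  cell <- build_cell(10, 10, 10)
  set.seed(19)
  m <- structure(list(values = array(rnorm(32^3), c(32, 32, 32)),
                      grid = c(32, 32, 32), cell = cell),
                 class = "potential_map")
  fc <- fractal_dimension_curve(m, 100)
  # a single bin covering everything gives exactly 3
  expect_equal(3 * log(sum(fc$count)) / log(length(m$values)), 3)
  expect_true(all(fc$d_f <= 3 + 1e-12, na.rm = TRUE))
  # unimodal parabola-like shape: peak near zero, small at the extremes
  pk <- which.max(fc$d_f)
  expect_lt(abs(fc$rho[pk]), 0.5)
  expect_gt(fc$d_f[pk], 2)
  ends <- c(head(stats::na.omit(fc$d_f), 1), tail(stats::na.omit(fc$d_f), 1))
  expect_true(all(ends < 1))
  # halving the bin width leaves the curve shape stable
  fc2 <- fractal_dimension_curve(m, 200)
  sel <- fc2$count > 100
  approx1 <- stats::approx(fc$rho, fc$d_f, xout = fc2$rho[sel])$y
  dif <- abs(approx1 - fc2$d_f[sel])
  expect_lt(max(dif, na.rm = TRUE), 0.1)
  expect_error(fractal_dimension_curve(m, 10), "20")
})

test_that("X-PLOR export writes a parseable grid", {
  cell <- build_cell(5, 6, 7)
  m <- difference_map(cell, rbind(c(1, 0, 0)), complex(real = 1), c(6, 6, 6))
  path <- tempfile(fileext = ".xplor")
  write_xplor(m, path)
  lines <- readLines(path)
  expect_true(any(grepl("ZYX", lines)))
  hdr <- as.numeric(strsplit(trimws(lines[4]), "[[:space:]]+")[[1]])
  expect_equal(hdr[c(1, 4, 7)], c(6, 6, 6))
})
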