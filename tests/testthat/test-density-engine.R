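test_that("Gaussian-atom density integrates to the electron count and is linear", {
  cell <- tiny_cubic(12)
  grid <- grid_spec(cell, c(48, 48, 48))
  one_c <- atomic_model(
    tibble::tibble(element = "C", x = 0.31, y = 0.62, z = 0.18, u_iso = 0.25),
    cell
  )
  rho <- model_density(one_c, grid)
  voxvol <- cell$volume / prod(grid$n)
  expect_equal(sum(rho$data) * voxvol, 6, tolerance = 1e-3)

  two_c <- atomic_model(rbind(one_c, one_c), cell)
  rho2 <- model_density(two_c, grid)
  expect_equal(rho2$data, 2 * rho$data, tolerance = 1e-12)

  # closed-form profile along a line through the centre
  line_x <- seq(0.31 - 0.1, 0.31 + 0.1, length.out = 9)
  on_grid <- abs(line_x * 48 - round(line_x * 48)) < 1e-9
  vals <- trilinear_interpolate(rho, cbind(line_x, 0.62, 0.18))
  r <- abs(line_x - 0.31) * 12
  analytic <- 6 * (2 * pi * 0.25)^(-1.5) * exp(-r^2 / (2 * 0.25))
  expect_equal(vals[on_grid], analytic[on_grid], tolerance = 1e-6)
})

test_that("direct-summation structure factors behave analytically", {
  cell <- tiny_cubic(12)
  one_c <- atomic_model(
    tibble::tibble(element = "C", x = 0, y = 0, z = 0, u_iso = 0.2),
    cell
  )
  hkl <- hkl_list(cell, 3.0, include_f000 = TRUE)
  f <- sf_direct(one_c, hkl)$f
  f000 <- f[hkl$h == 0 & hkl$k == 0 & hkl$l == 0]
  expect_equal(f000, 6 + 0i)
  # atom at the origin: all coefficients real and positive
  expect_lt(max(abs(Im(f))), 1e-10)
  expect_true(all(Re(f) > 0))
})

test_that("FFT and direct summation agree on random models", {
  sys <- small_system(n_atoms = 10, edge = 14, d_min = 2.5, seed = 9)
  grid <- build_grid(sys$cell, 2.5, 2.0)
  rho <- suppressWarnings(model_density(sys$model, grid))
  sf_fft <- map_to_sf(rho, 2.5, include_f000 = TRUE)
  sf_dir <- sf_direct(sys$model, sf_fft)
  rel <- sqrt(mean(Mod(sf_fft$f - sf_dir$f)^2)) / sqrt(mean(Mod(sf_dir$f)^2))
  expect_lt(rel, 1e-3)
})

test_that("scaling fit recovers scale and overall-U attenuation", {
  sys <- small_system(seed = 3)
  fc <- sys$fc
  fobs_eq <- sf_set(fc, sys$cell, sys$d_min, fobs = Mod(fc$f))
  s <- fit_scale(fobs_eq, fc)
  expect_equal(s$k, 1, tolerance = 1e-9)
  expect_equal(s$u_overall, 0, tolerance = 1e-9)

  s3 <- fit_scale(sf_set(fc, sys$cell, sys$d_min, fobs = 3 * Mod(fc$f)), fc)
  expect_equal(s3$k, 3, tolerance = 1e-9)
  expect_equal(s3$u_overall, 0, tolerance = 1e-9)

  s2v <- shiftfieldr:::s_squared(sys$cell, fc)
  att <- sf_set(fc, sys$cell, sys$d_min,
    fobs = Mod(fc$f) * exp(-2 * pi^2 * 0.1 * s2v))
  sa <- fit_scale(att, fc)
  expect_equal(sa$u_overall, 0.1, tolerance = 1e-6)

  expect_error(
    fit_scale(fobs_eq[1:5, ], fc[1:5, ]),
    class = "shiftfieldr_fit_degenerate"
  )
})

test_that("R factor matches hand arithmetic and limiting cases", {
  cell <- tiny_cubic(10)
  hkl <- data.frame(h = 1:5, k = 0L, l = 0L)
  fobs <- sf_set(hkl, cell, 2.0, fobs = c(10, 8, 6, 4, 2))
  fcalc <- sf_set(hkl, cell, 2.0, fobs = c(9, 9, 5, 4, 1))
  r <- r_factor(fobs, fcalc, manual_scale(1), subset = "all")
  # independent summation
  expect_equal(r, sum(abs(c(10, 8, 6, 4, 2) - c(9, 9, 5, 4, 1))) / sum(c(10, 8, 6, 4, 2)))
  expect_equal(r, 4 / 30)

  expect_equal(r_factor(fobs, fobs, manual_scale(1), subset = "all"), 0)
  # scaled fcalc driven to zero -> R = 1
  expect_equal(r_factor(fobs, fcalc, manual_scale(1e-300), subset = "all"), 1)
  expect_error(
    r_factor(fobs, fcalc, manual_scale(1), subset = "free"),
    class = "shiftfieldr_invalid_argument"
  )
})

test_that("a model scores R ~ 0 against its own noise-free amplitudes", {
  sys <- small_system(seed = 5)
  fobs <- sf_set(sys$fc, sys$cell, sys$d_min, fobs = Mod(sys$fc$f))
  s <- fit_scale(fobs, sys$fc)
  expect_lt(r_factor(fobs, sys$fc, s, subset = "all"), 1e-6)
})

test_that("a uniform U inflation is absorbed by the overall-U scale term", {
  sys <- small_system(seed = 6)
  inflated <- sys$model
  inflated$u_iso <- inflated$u_iso + 0.05
  fc_inf <- sf_direct(inflated, sys$fc)
  fobs <- sf_set(sys$fc, sys$cell, sys$d_min, fobs = Mod(sys$fc$f))
  s <- fit_scale(fobs, fc_inf)
  expect_equal(abs(s$u_overall), 0.05, tolerance = 1e-6)
  expect_lt(r_factor(fobs, fc_inf, s, subset = "all"), 1e-6)
})

test_that("difference coefficients vanish for a perfect model and are linear", {
  sys <- small_system(seed = 8)
  fobs <- sf_set(sys$fc, sys$cell, sys$d_min,
    fobs = Mod(sys$fc$f), free = rep(FALSE, nrow(sys$fc)))
  dc <- difference_coefficients(fobs, sys$fc, manual_scale(1))
  expect_lt(max(Mod(dc$f)), 1e-10 * max(Mod(sys$fc$f)))

  # doubling the amplitude differences doubles D everywhere
  fobs2 <- fobs
  fobs2$fobs <- Mod(sys$fc$f) * 1.1
  dc1 <- difference_coefficients(fobs2, sys$fc, manual_scale(1))
  fobs3 <- fobs
  fobs3$fobs <- Mod(sys$fc$f) * 1.2
  dc2 <- difference_coefficients(fobs3, sys$fc, manual_scale(1))
  d1 <- sf_to_map(dc1, sys$grid)
  d2 <- sf_to_map(dc2, sys$grid)
  expect_equal(d2$data, 2 * d1$data, tolerance = 1e-9)
})

test_that("coefficient-route and map-subtraction difference maps agree", {
  # single atom: model phases equal true phases, so the two routes coincide
  cell <- tiny_cubic(12)
  truth <- atomic_model(
    tibble::tibble(element = "O", x = 0.4, y = 0.55, z = 0.21, u_iso = 0.2), cell
  )
  wrong <- truth
  wrong$u_iso <- 0.35
  grid <- build_grid(cell, 2.0, 1.5)
  hkl <- hkl_list(cell, 2.0)
  ft <- sf_direct(truth, hkl)
  fw <- sf_direct(wrong, hkl)
  fobs <- sf_set(hkl, cell, 2.0, fobs = Mod(ft$f), free = rep(FALSE, nrow(hkl)))
  d_coef <- sf_to_map(difference_coefficients(fobs, fw, manual_scale(1)), grid)
  d_sub <- density_map(grid, sf_to_map(ft, grid)$data - sf_to_map(fw, grid)$data)
  expect_lt(sqrt(mean((d_coef$data - d_sub$data)^2)), 1e-6)
})

test_that("free-set flags are deterministic with binomially plausible counts", {
  hkl <- data.frame(h = 1:1000, k = 0L, l = 0L)
  f1 <- assign_free_set(hkl, 0.05, seed = 42)
  expect_true(sum(f1) >= 30 && sum(f1) <= 70)
  expect_identical(f1, assign_free_set(hkl, 0.05, seed = 42))
  f2 <- assign_free_set(hkl, 0.05, seed = 43)
  expect_false(identical(f1, f2))
  # overlap of independent 5% draws ~ Binomial(1000, 0.0025)
  expect_lte(sum(f1 & f2), 12)
  expect_error(assign_free_set(hkl, 0.7), class = "shiftfieldr_invalid_argument")
})
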