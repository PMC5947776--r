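test_that("radial kernels sample g(r) correctly and enforce bounds", {
  cell <- tiny_cubic(12)
  grid <- grid_spec(cell, c(24, 24, 24)) # spacing 0.5
  for (form in c("step", "linear", "quadratic")) {
    k <- make_kernel(grid, 2.0, form)
    expect_equal(k$data[1, 1, 1], 1) # r = 0
    expect_true(all(k$data >= 0))
    expect_gt(sum(k$data), 0)
  }
  # quadratic at r = r0/2 (voxel 2 steps away, r0 = 4 steps)
  kq <- make_kernel(grid, 4 * 0.5, "quadratic")
  expect_equal(kq$data[3, 1, 1], 0.75)

  # step kernel approximates the sphere volume
  ks <- make_kernel(grid, 3.0, "step") # 6 voxels radius
  voxvol <- cell$volume / prod(grid$n)
  expect_equal(sum(ks$data) * voxvol, 4 / 3 * pi * 3^3, tolerance = 0.02)

  expect_error(make_kernel(grid, 0.4, "step"), class = "shiftfieldr_invalid_argument")
  expect_error(make_kernel(grid, 6.5, "step"), class = "shiftfieldr_invalid_argument")
})

test_that("the solvent mask is a union of minimum-image spheres", {
  cell <- tiny_cubic(12)
  grid <- grid_spec(cell, c(24, 24, 24))
  m <- atomic_model(
    tibble::tibble(element = "C", x = 0, y = 0, z = 0, u_iso = 0.2), cell
  )
  w <- solvent_mask(m, grid, 2.5)
  expect_equal(w$data[1, 1, 1], 1) # at the centre
  expect_equal(w$data[5, 1, 1], 1) # 2.0 A away
  expect_equal(w$data[7, 1, 1], 0) # 3.0 A away: outside
  # wraps: voxel just below the far edge is 0.5 A away
  expect_equal(w$data[24, 1, 1], 1)
  voxvol <- cell$volume / prod(grid$n)
  expect_equal(sum(w$data) * voxvol, 4 / 3 * pi * 2.5^3, tolerance = 0.05)
})

make_solve_system <- function(seed = 7, n_grid = 12, d_min = 2.5, edge = 12) {
  sys <- small_system(
    n_atoms = 5, edge = edge, d_min = d_min, seed = seed,
    grid_n = rep(n_grid, 3)
  )
  grads <- gradient_maps(sys$fc, sys$grid)
  # a difference map with structure everywhere: truth minus jittered model
  jit <- perturb_model(sys$model, "jitter_xyz", 0.25, seed = seed + 1)
  jit$u_iso <- jit$u_iso * 1.3
  dmap <- density_map(
    sys$grid,
    sf_to_map(sys$fc, sys$grid)$data - sf_to_map(sf_direct(jit, sys$fc), sys$grid)$data,
    role = "difference"
  )
  list(sys = sys, grads = grads, dmap = dmap)
}

test_that("a zero difference map yields a zero shift field", {
  s <- make_solve_system()
  kern <- make_kernel(s$sys$grid, 3, "quadratic")
  fld <- shift_field_solve(s$grads, density_map(s$sys$grid, 0, role = "difference"),
    NULL, kern)
  for (m in fld$maps) expect_true(all(m$data == 0))
})

test_that("an exact linear combination of gradient columns is recovered", {
  s <- make_solve_system()
  D <- density_map(
    s$sys$grid,
    0.2 * s$grads$maps$du$data - 0.1 * s$grads$maps$dx$data,
    role = "difference"
  )
  kern <- make_kernel(s$sys$grid, 3, "quadratic")
  fld <- shift_field_solve(s$grads, D, NULL, kern, ridge = 0)
  ok <- !fld$singular
  expect_gt(mean(ok), 0.99)
  expect_lt(max(abs(fld$maps$du$data[ok] - 0.2)), 1e-6)
  expect_lt(max(abs(fld$maps$dx$data[ok] + 0.1)), 1e-6)
  for (nm in c("dy", "dz")) expect_lt(max(abs(fld$maps[[nm]]$data[ok])), 1e-6)
})

test_that("convolution solver matches the sphere-enumeration oracle", {
  s <- make_solve_system()
  wm <- solvent_mask(s$sys$model, s$sys$grid, 2.5)
  masks <- list(uniform = NULL, model = wm)
  # sample voxels where the regression is well posed; deep-solvent voxels
  # under the binary mask are near-singular by design and get flagged/zeroed
  vox_for <- function(mask) {
    pool <- if (is.null(mask)) seq_len(prod(s$sys$grid$n)) else which(mask$data > 0)
    idx <- with_seed_test(5, sample(pool, 20))
    arrayInd(idx, s$sys$grid$n)
  }
  for (form in c("step", "linear", "quadratic")) {
    for (mk in names(masks)) {
      kern <- make_kernel(s$sys$grid, 3, form)
      fld <- shift_field_solve(s$grads, s$dmap, masks[[mk]], kern)
      vox <- vox_for(masks[[mk]])
      oracle <- shift_field_direct(s$grads, s$dmap, masks[[mk]], 3, form, vox)
      keep <- !oracle$singular & !fld$singular[vox]
      expect_gte(sum(keep), 18)
      for (nm in names(fld$maps)) {
        conv_at <- fld$maps[[nm]]$data[vox]
        denom <- max(abs(oracle[[nm]][keep]))
        expect_lt(max(abs(conv_at[keep] - oracle[[nm]][keep])) / denom, 1e-8,
          label = sprintf("form %s mask %s component %s", form, mk, nm))
      }
    }
  }
})

test_that("convolution pass counts follow n(n+1)/2 + n", {
  s <- make_solve_system()
  kern <- make_kernel(s$sys$grid, 3, "quadratic")
  fld5 <- shift_field_solve(s$grads, s$dmap, NULL, kern)
  expect_identical(fld5$n_convolutions, 20L)
  g2 <- gradient_maps(s$sys$fc, s$sys$grid, active_mask(positions = FALSE))
  fld2 <- shift_field_solve(g2, s$dmap, NULL, kern)
  expect_identical(fld2$n_convolutions, 5L)
  g4 <- gradient_maps(s$sys$fc, s$sys$grid, active_mask(u = FALSE))
  expect_identical(shift_field_solve(g4, s$dmap, NULL, kern)$n_convolutions, 14L)
})

test_that("scaling the kernel leaves the solution unchanged", {
  s <- make_solve_system()
  kern <- make_kernel(s$sys$grid, 3, "linear")
  fld1 <- shift_field_solve(s$grads, s$dmap, NULL, kern)
  kern2 <- kern
  kern2$data <- 7.3 * kern$data
  fld2 <- shift_field_solve(s$grads, s$dmap, NULL, kern2)
  ok <- !fld1$singular & !fld2$singular
  for (nm in names(fld1$maps)) {
    expect_equal(fld1$maps[[nm]]$data[ok], fld2$maps[[nm]]$data[ok], tolerance = 1e-9)
  }
})

test_that("the field is linear in the difference map at fixed normal matrix", {
  s <- make_solve_system()
  kern <- make_kernel(s$sys$grid, 3, "quadratic")
  D1 <- s$dmap
  D2 <- density_map(s$sys$grid, s$grads$maps$du$data * 0.1, role = "difference")
  alpha <- 0.7
  beta <- -1.3
  Dmix <- density_map(s$sys$grid, alpha * D1$data + beta * D2$data, role = "difference")
  f1 <- shift_field_solve(s$grads, D1, NULL, kern)
  f2 <- shift_field_solve(s$grads, D2, NULL, kern)
  fm <- shift_field_solve(s$grads, Dmix, NULL, kern)
  ok <- !f1$singular & !f2$singular & !fm$singular
  for (nm in names(f1$maps)) {
    expect_equal(
      fm$maps[[nm]]$data[ok],
      alpha * f1$maps[[nm]]$data[ok] + beta * f2$maps[[nm]]$data[ok],
      tolerance = 1e-8
    )
  }
})

test_that("degenerate regressions are flagged singular, not solved", {
  s <- make_solve_system()
  zero_w <- density_map(s$sys$grid, 0, role = "weight")
  oracle <- shift_field_direct(s$grads, s$dmap, zero_w, 3, "quadratic",
    matrix(c(1, 1, 1, 5, 5, 5), ncol = 3, byrow = TRUE))
  expect_true(all(oracle$singular))
  expect_true(all(oracle$du == 0))
  # grid mismatch and zero kernel raise
  kern <- make_kernel(s$sys$grid, 3, "quadratic")
  other <- grid_spec(s$sys$cell, c(10, 10, 10))
  expect_error(
    shift_field_solve(s$grads, density_map(other, 0), NULL, kern),
    class = "shiftfieldr_invalid_argument"
  )
  kz <- kern
  kz$data <- array(0, dim = s$sys$grid$n)
  expect_error(
    shift_field_solve(s$grads, s$dmap, NULL, kz),
    class = "shiftfieldr_invalid_argument"
  )
})

test_that("shift components respect the symmetry of a centred atom", {
  cell <- tiny_cubic(12)
  grid <- grid_spec(cell, c(16, 16, 16))
  m <- atomic_model(
    tibble::tibble(element = "C", x = 0.5, y = 0.5, z = 0.5, u_iso = 0.25), cell
  )
  fc <- sf_direct(m, hkl_list(cell, 2.5, include_f000 = TRUE))
  grads <- gradient_maps(fc, grid)
  # centrosymmetric D: the atom with a larger U, same centre
  m2 <- m
  m2$u_iso <- 0.35
  D <- density_map(grid,
    sf_to_map(sf_direct(m2, fc), grid)$data - sf_to_map(fc, grid)$data,
    role = "difference")
  fld <- shift_field_solve(grads, D, NULL, make_kernel(grid, 2.5, "quadratic"))
  # indices mirrored about the centre voxel (9,9,9): 9+v <-> 9-v
  v <- 3
  ctr <- 9
  expect_equal(
    fld$maps$dx$data[ctr + v, ctr, ctr], -fld$maps$dx$data[ctr - v, ctr, ctr],
    tolerance = 1e-8
  )
  expect_equal(
    fld$maps$du$data[ctr + v, ctr, ctr], fld$maps$du$data[ctr - v, ctr, ctr],
    tolerance = 1e-8
  )
})

test_that("larger kernel radii give smoother shift fields", {
  s <- make_solve_system(n_grid = 16)
  g2 <- gradient_maps(s$sys$fc, s$sys$grid, active_mask(positions = FALSE))
  variances <- vapply(c(2, 3, 4, 5), function(r0) {
    fld <- shift_field_solve(g2, s$dmap, NULL, make_kernel(s$sys$grid, r0, "quadratic"))
    stats::var(as.vector(fld$maps$du$data[!fld$singular]))
  }, numeric(1))
  expect_true(all(diff(variances) <= 1e-12))
})
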