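# Shared small fixtures, built in code (no files).

tiny_cubic <- function(edge = 12) unit_cell(edge, edge, edge)

# a small random model + grid + exact structure factors, reproducible
small_system <- function(n_atoms = 5, edge = 12, d_min = 2.5, seed = 7,
                         u_range = c(0.15, 0.35), grid_n = NULL) {
  cell <- tiny_cubic(edge)
  model <- make_toy_structure(n_atoms, cell, u_range = u_range, seed = seed)
  grid <- if (is.null(grid_n)) build_grid(cell, d_min, 1.5) else grid_spec(cell, grid_n)
  fc <- sf_direct(model, hkl_list(cell, d_min, include_f000 = TRUE))
  list(cell = cell, model = model, grid = grid, fc = fc, d_min = d_min)
}

# mean minimum-image coordinate error (angstrom) between two models
coord_error <- function(model, truth, remove_translation = FALSE) {
  cell <- model_cell(truth)
  df <- cbind(model$x - truth$x, model$y - truth$y, model$z - truth$z)
  df <- df - round(df)
  if (remove_translation) df <- sweep(df, 2, colMeans(df))
  mean(sqrt(rowSums(frac_to_orth(cell, df)^2)))
}

# a band-limited random real map: random Friedel-unique coefficients
random_bandlimited_map <- function(grid, d_min, seed = 1) {
  cell <- grid$cell
  hkl <- hkl_list(cell, d_min, include_f000 = FALSE)
  f <- with_seed_test(seed, complex(
    real = rnorm(nrow(hkl)), imaginary = rnorm(nrow(hkl))
  ))
  sf_to_map(sf_set(hkl, cell, d_min, f = f), grid)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

manual_scale <- function(k, u_overall = 0) {
  structure(list(k = k, u_overall = u_overall), class = "scale_params")
}
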