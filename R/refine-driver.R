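#' Refinement configuration
#'
#' Bundles every tunable of the iterative shift-field protocol.
#'
#' @param d_min Resolution limit in angstrom.
#' @param n_cycles Number of refinement cycles (default 5).
#' @param mode Parameter mode: `"u_only"` (U_iso + constant, n = 2),
#'   `"positions_only"` (x, y, z + constant, n = 4) or `"full"` (n = 5).
#' @param kernel Radial kernel form, default `"quadratic"` (the form that
#'   performs best in practice).
#' @param radius_a Kernel radius r0 in angstrom, or `"auto"` to use
#'   [r0_from_resolution()] with `auto_slope`/`auto_intercept`.
#' @param auto_slope,auto_intercept Coefficients of the linear
#'   r0-vs-resolution heuristic (angstrom per angstrom, angstrom).  The
#'   defaults (1, 1) give `r0 = d_min + 1`, passing through 3 angstrom at
#'   2 angstrom resolution; they are a placeholder to be refit with
#'   [radius_sweep()] on data like yours.
#' @param mask `"model"` (binary 2.5-angstrom solvent mask) or `"uniform"`.
#' @param mask_radius Mask radius in angstrom (default 2.5).
#' @param ridge Relative ridge regularization for the per-voxel solves.
#' @param damping Shift step-size factor in (0, 1].
#' @param free_fraction,seed Free-set fraction and seed, used when the
#'   observations carry no free flags.
#' @param oversample Grid oversampling factor (default 1.5).
#' @param diff_factor Multiplier on difference coefficients (default 1).
#' @param weighting Difference-map weighting, `"none"` or `"sigma"`.
#' @return A list of class `refine_config`.
#' @export
refine_config <- function(d_min,
                          n_cycles = 5,
                          mode = c("u_only", "positions_only", "full"),
                          kernel = c("quadratic", "step", "linear"),
                          radius_a = "auto",
                          auto_slope = 1.0,
                          auto_intercept = 1.0,
                          mask = c("model", "uniform"),
                          mask_radius = 2.5,
                          ridge = 1e-6,
                          damping = 1.0,
                          free_fraction = 0.05,
                          seed = 1,
                          oversample = 1.5,
                          diff_factor = 1,
                          weighting = c("none", "sigma")) {
  stopifnot(d_min > 0, n_cycles >= 1)
  structure(
    list(
      d_min = d_min, n_cycles = as.integer(n_cycles),
      mode = match.arg(mode), kernel = match.arg(kernel),
      radius_a = radius_a,
      auto_slope = auto_slope, auto_intercept = auto_intercept,
      mask = match.arg(mask), mask_radius = mask_radius,
      ridge = ridge, damping = damping,
      free_fraction = free_fraction, seed = seed,
      oversample = oversample, diff_factor = diff_factor,
      weighting = match.arg(weighting)
    ),
    class = "refine_config"
  )
}

#' Kernel radius from resolution
#'
#' Linear heuristic `r0 = slope * d_min + intercept`, clipped into the
#' \[1.5, 8\] angstrom range over which the radius behaves well: larger
#' spheres mean fewer effective independent parameters, suiting lower
#' resolution.  The coefficients are configuration, to be calibrated with
#' [radius_sweep()].
#'
#' @param d_min Resolution limit in angstrom (> 0).
#' @param slope,intercept Heuristic coefficients.
#' @return r0 in angstrom.
#' @export
r0_from_resolution <- function(d_min, slope, intercept) {
  if (!is.finite(d_min) || d_min <= 0) {
    abort("d_min must be positive", class = "shiftfieldr_invalid_config")
  }
  r0 <- slope * d_min + intercept
  if (r0 <= 0) {
    abort("auto radius resolved to a non-positive value",
      class = "shiftfieldr_invalid_config")
  }
  min(max(r0, 1.5), 8)
}

config_active <- function(mode) {
  switch(mode,
    u_only = active_mask(positions = FALSE, u = TRUE),
    positions_only = active_mask(positions = TRUE, u = FALSE),
    full = active_mask()
  )
}

#' Run iterative shift-field refinement
#'
#' The two-step protocol, iterated `n_cycles` times: (i) model density
#' and calculated structure factors are computed from the current model,
#' the overall scale is fitted on the work set, R and free R are
#' recorded, and a difference map is synthesized from work reflections;
#' (ii) gradient fields of the (scaled) model map are built for the
#' active parameter mode, the shift field is solved by FFT convolution,
#' and the shifts are applied to the model.  Gradients and the difference
#' map share the observed amplitude scale, so solved shifts are directly
#' in model-parameter units.
#'
#' @param model Starting [atomic_model()].
#' @param fobs [sf_set()] of observed amplitudes (`fobs`, optional
#'   `sigma`, optional logical `free`; flags are assigned from the config
#'   when absent).
#' @param config A [refine_config()].
#' @return Object of class `shift_refinement`: list with the final
#'   `model`, `start_model`, a `stats` tibble of `n_cycles + 1` rows
#'   (row 0 = the starting state), the resolved `r0`, the last
#'   `shift_field`, and the `config`.
#' @export
run_refinement <- function(model, fobs, config) {
  start_model <- model
  cell <- model_cell(model)
  grid <- build_grid(cell, config$d_min, config$oversample)
  r0 <- if (identical(config$radius_a, "auto")) {
    r0_from_resolution(config$d_min, config$auto_slope, config$auto_intercept)
  } else {
    as.numeric(config$radius_a)
  }
  if (is.null(fobs[["free"]])) {
    fobs$free <- assign_free_set(fobs, config$free_fraction, config$seed)
  }
  kern <- make_kernel(grid, r0, config$kernel)
  active <- config_active(config$mode)
  work <- fobs[!fobs$free & !(fobs$h == 0 & fobs$k == 0 & fobs$l == 0), ]
  attr(work, "cell") <- cell

  stats <- vector("list", config$n_cycles + 1)
  rms <- c(dx = 0, dy = 0, dz = 0, du = 0)
  field <- NULL
  for (cyc in 0:config$n_cycles) {
    fc <- sf_direct(model, fobs)
    scale <- fit_scale(work, fc)
    r_work <- r_factor(fobs, fc, scale, subset = "work")
    r_free <- r_factor(fobs, fc, scale, subset = "free")
    if (!is.finite(r_work)) {
      abort(sprintf("R_work became non-finite at cycle %d", cyc),
        class = "shiftfieldr_diverged")
    }
    n_sing <- if (is.null(field)) 0L else sum(field$singular)
    stats[[cyc + 1]] <- tibble(
      cycle = cyc, r_work = r_work, r_free = r_free,
      k = scale$k, u_overall = scale$u_overall,
      rms_dx = rms[["dx"]], rms_dy = rms[["dy"]], rms_dz = rms[["dz"]],
      rms_du = rms[["du"]], n_singular = n_sing
    )
    if (cyc == config$n_cycles) break
    # difference map from work reflections, on the observed scale
    dcoef <- difference_coefficients(fobs, fc, scale,
      weighting = config$weighting, factor = config$diff_factor)
    dmap <- sf_to_map(dcoef, grid, role = "difference")
    # scaled model coefficients so gradients share the observed scale
    s2 <- s_squared(cell, fc)
    fs <- sf_set(fc, cell, config$d_min, f = fc$f * applied_scale(scale, s2))
    grads <- gradient_maps(fs, grid, active)
    wmask <- switch(config$mask,
      model = solvent_mask(model, grid, config$mask_radius),
      uniform = NULL
    )
    field <- shift_field_solve(grads, dmap, wmask, kern, ridge = config$ridge)
    model <- apply_to_model(model, field, damping = config$damping)
    rms <- attr(model, "applied_rms")
  }
  structure(
    list(
      model = model,
      start_model = start_model,
      stats = dplyr::bind_rows(stats),
      r0 = r0,
      field = field,
      config = config
    ),
    class = "shift_refinement"
  )
}

#' @export
print.shift_refinement <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<shift_refinement> %s, %d cycles, r0 = %.2f A\n  R_work %.4f -> %.4f   R_free %.4f -> %.4f\n",
    x$config$mode, x$config$n_cycles, x$r0,
    s$r_work[1], s$r_work[nrow(s)], s$r_free[1], s$r_free[nrow(s)]
  ))
  invisible(x)
}

#' Sweep the kernel radius
#'
#' One full [run_refinement()] per radius, from the same starting model,
#' collecting the final R and free R.  This is how the r0-vs-resolution
#' heuristic coefficients are calibrated for a data set.
#'
#' @inheritParams run_refinement
#' @param radii Numeric vector of r0 values in angstrom.
#' @return Tibble of class `radius_sweep` with columns `r0`,
#'   `r_work_final`, `r_free_final`, plus attributes `best_r0_work` and
#'   `best_r0_free`.
#' @export
radius_sweep <- function(model, fobs, config, radii) {
  if (is.null(fobs[["free"]])) {
    fobs$free <- assign_free_set(fobs, config$free_fraction, config$seed)
  }
  rows <- purrr::map(radii, function(r0) {
    cfg <- config
    cfg$radius_a <- r0
    res <- run_refinement(model, fobs, cfg)
    s <- res$stats
    tibble(
      r0 = r0,
      r_work_final = s$r_work[nrow(s)],
      r_free_final = s$r_free[nrow(s)]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "best_r0_work") <- out$r0[which.min(out$r_work_final)]
  attr(out, "best_r0_free") <- out$r0[which.min(out$r_free_final)]
  class(out) <- c("radius_sweep", class(out))
  out
}
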