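#' Generate a toy crystal structure with known ground truth
#'
#' Places atoms in a P1 cell with a minimum pairwise minimum-image
#' separation of 1.5 angstrom.  Arrangements: `"random"` packing,
#' `"helix"` (a regular helical path with 1.5 angstrom rise and 100
#' degree twist per atom, giving the ~3.8 angstrom consecutive spacing of
#' a C-alpha trace), or `"two_domain"` (two separated clusters, for
#' domain-shift tests; atoms carry a `domain` label).  Per-atom U_iso is
#' drawn uniformly from `u_range`.  Deterministic given the seed.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param cell A [unit_cell()] (default 30 angstrom cube).
#' @param arrangement "random", "helix" or "two_domain".
#' @param u_range Range of U_iso in square angstrom, within (0.01, 2).
#' @param seed Integer seed.
#' @return An [atomic_model()].
#' @export
make_toy_structure <- function(n_atoms,
                               cell = unit_cell(30, 30, 30),
                               arrangement = c("random", "helix", "two_domain"),
                               u_range = c(0.1, 0.4),
                               seed = 1) {
  arrangement <- match.arg(arrangement)
  stopifnot(n_atoms >= 1, u_range[1] > 0.01, u_range[2] < 2.0)
  min_sep <- 1.5
  with_seed(seed, {
    pos <- switch(arrangement,
      random = pack_random(n_atoms, cell, min_sep, lo = c(0, 0, 0), hi = c(1, 1, 1)),
      helix = place_helix(n_atoms, cell),
      two_domain = {
        n1 <- ceiling(n_atoms / 2)
        p1 <- pack_random(n1, cell, min_sep, lo = c(0.05, 0.05, 0.05), hi = c(0.45, 0.45, 0.45))
        p2 <- pack_random(n_atoms - n1, cell, min_sep, lo = c(0.55, 0.55, 0.55), hi = c(0.95, 0.95, 0.95))
        rbind(p1, p2)
      }
    )
    domain <- if (arrangement == "two_domain") {
      rep(c(1L, 2L), c(ceiling(n_atoms / 2), n_atoms - ceiling(n_atoms / 2)))
    } else {
      rep(1L, n_atoms)
    }
    elements <- sample(c("C", "N", "O", "S"), n_atoms,
      replace = TRUE, prob = c(0.62, 0.17, 0.17, 0.04))
    atomic_model(
      tibble(
        element = elements,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        occ = 1,
        u_iso = runif(n_atoms, u_range[1], u_range[2]),
        domain = domain
      ),
      cell
    )
  })
}

# rejection-sample fractional positions in a box with a minimum-image
# orthogonal separation floor
pack_random <- function(n, cell, min_sep, lo, hi) {
  pos <- matrix(0, 0, 3)
  tries <- 0L
  max_tries <- 5000L * n
  while (nrow(pos) < n) {
    cand <- lo + runif(3) * (hi - lo)
    ok <- TRUE
    if (nrow(pos) > 0) {
      d <- min_image_dist(cell, pos, cand)
      ok <- all(d >= min_sep)
    }
    if (ok) pos <- rbind(pos, cand)
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("cell too small to pack atoms at the separation floor",
        class = "shiftfieldr_packing_error")
    }
  }
  dimnames(pos) <- NULL
  pos
}

# minimum-image distances (angstrom) from each row of `pos` to point `p`
min_image_dist <- function(cell, pos, p) {
  df <- sweep(pos, 2, p)
  df <- df - round(df)
  sqrt(rowSums(frac_to_orth(cell, df)^2))
}

place_helix <- function(n, cell) {
  rise <- 1.5
  twist <- 100 * pi / 180
  radius <- 2.3
  if ((n - 1) * rise >= cell$c - 2) {
    abort("helix does not fit along the c axis",
      class = "shiftfieldr_packing_error")
  }
  i <- seq_len(n) - 1
  ctr <- frac_to_orth(cell, c(0.5, 0.5, 0))
  xyz <- cbind(
    ctr[1] + radius * cos(i * twist),
    ctr[2] + radius * sin(i * twist),
    1 + i * rise
  )
  orth_to_frac(cell, xyz)
}

#' Simulate observed amplitudes from a ground-truth model
#'
#' `|Fobs| = |F_true| * (1 + eps)`, `eps ~ Normal(0, noise_frac)` clamped
#' at +/- 3 sigma, with the multiplier floored at 0.01 so amplitudes stay
#' positive; `sigma = noise_frac * |F_true|`.  Free flags are assigned;
#' F(000) is excluded.  Deterministic given the seed.
#'
#' @param truth An [atomic_model()].
#' @param d_min Resolution limit in angstrom.
#' @param noise_frac Relative amplitude noise (>= 0).
#' @param free_fraction Free-set fraction.
#' @param seed Integer seed.
#' @return [sf_set()] with columns `fobs`, `sigma`, `free`.
#' @export
simulate_observations <- function(truth, d_min, noise_frac = 0.02,
                                  free_fraction = 0.05, seed = 1) {
  stopifnot(noise_frac >= 0)
  cell <- model_cell(truth)
  hkl <- hkl_list(cell, d_min, include_f000 = FALSE)
  ftrue <- Mod(sf_direct(truth, hkl)$f)
  with_seed(seed, {
    eps <- pmin(pmax(rnorm(length(ftrue), 0, noise_frac), -3 * noise_frac), 3 * noise_frac)
    fobs <- ftrue * pmax(1 + eps, 0.01)
    free <- runif(length(ftrue)) < free_fraction
    sf_set(hkl, cell, d_min, fobs = fobs, sigma = noise_frac * ftrue, free = free)
  })
}

#' Perturb a model in a controlled way
#'
#' Modes: `"reset_u"` sets every U_iso to `magnitude` (0.5 square
#' angstrom being the classic constant-B starting point for displacement
#' refinement tests); `"jitter_xyz"` adds isotropic Gaussian positional
#' noise of RMS `magnitude` angstrom; `"rigid_shift_domain"` translates
#' the second domain of a two-domain model by `magnitude` angstrom along
#' a random direction.
#'
#' @param model An [atomic_model()].
#' @param mode Perturbation mode.
#' @param magnitude Mode-dependent magnitude (>= 0); see above.
#' @param seed Integer seed (used by the stochastic modes).
#' @return The perturbed [atomic_model()].
#' @export
perturb_model <- function(model, mode = c("reset_u", "jitter_xyz", "rigid_shift_domain"),
                          magnitude = 0.5, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(magnitude >= 0)
  cell <- model_cell(model)
  if (mode == "reset_u") {
    model$u_iso <- rep(magnitude, nrow(model))
    return(model)
  }
  if (mode == "jitter_xyz") {
    with_seed(seed, {
      # isotropic displacement with total RMS = magnitude
      d_orth <- matrix(rnorm(3 * nrow(model), 0, magnitude / sqrt(3)), ncol = 3)
      d_frac <- orth_to_frac(cell, d_orth)
      model$x <- (model$x + d_frac[, 1]) %% 1
      model$y <- (model$y + d_frac[, 2]) %% 1
      model$z <- (model$z + d_frac[, 3]) %% 1
    })
    return(model)
  }
  # rigid_shift_domain
  if (!any(model$domain == 2L)) {
    abort("rigid_shift_domain needs a two_domain model",
      class = "shiftfieldr_invalid_argument")
  }
  with_seed(seed, {
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    d_frac <- orth_to_frac(cell, magnitude * dir)
    sel <- model$domain == 2L
    model$x[sel] <- (model$x[sel] + d_frac[1]) %% 1
    model$y[sel] <- (model$y[sel] + d_frac[2]) %% 1
    model$z[sel] <- (model$z[sel] + d_frac[3]) %% 1
  })
  model
}

#' Named fixture presets
#'
#' Reproducible toy-crystal scenarios read from the plain-text preset
#' file shipped with the package (`inst/extdata/presets.yaml`): cell
#' size, atom count, resolution, noise level and the perturbation that
#' defines the refinement problem.
#'
#' @param name Preset name; `fixture_presets()` lists them.
#' @param seed Integer seed.
#' @return For `make_fixture`, a list with `truth` (ground-truth model),
#'   `start` (perturbed starting model) and `fobs` (simulated
#'   observations); the preset parameters are attached as `params`.
#' @export
make_fixture <- function(name, seed = 1) {
  p <- fixture_presets()[[name]]
  if (is.null(p)) {
    abort(paste0("unknown preset: ", name), class = "shiftfieldr_invalid_argument")
  }
  truth <- make_toy_structure(
    n_atoms = p$n_atoms,
    cell = unit_cell(p$cell, p$cell, p$cell),
    arrangement = p$arrangement,
    u_range = c(p$u_min, p$u_max),
    seed = seed
  )
  fobs <- simulate_observations(truth, p$d_min,
    noise_frac = p$noise_frac, free_fraction = p$free_fraction, seed = seed + 1)
  start <- perturb_model(truth, p$perturb, magnitude = p$magnitude, seed = seed + 2)
  list(truth = truth, start = start, fobs = fobs,
    params = c(p, list(seed = seed)))
}

#' @rdname make_fixture
#' @export
fixture_presets <- function() {
  path <- system.file("extdata", "presets.yaml", package = "shiftfieldr")
  yaml::read_yaml(path)
}
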