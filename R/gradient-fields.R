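# signed Miller-index arrays and the |s|^2 array for a full FFT grid
grid_hkl_arrays <- function(grid) {
  n <- grid$n
  hs <- signed_axis(n[1])
  ks <- signed_axis(n[2])
  ls <- signed_axis(n[3])
  H <- array(rep(hs, times = n[2] * n[3]), dim = n)
  K <- array(rep(rep(ks, each = n[1]), times = n[3]), dim = n)
  L <- array(rep(ls, each = n[1] * n[2]), dim = n)
  G <- grid$cell$recip_metric
  s2 <- G[1, 1] * H^2 + G[2, 2] * K^2 + G[3, 3] * L^2 +
    2 * (G[1, 2] * H * K + G[1, 3] * H * L + G[2, 3] * K * L)
  list(H = H, K = K, L = L, s2 = s2)
}

# canonical parameter order and the flags selecting them
PARAM_NAMES <- c("dx", "dy", "dz", "du", "dc")

active_mask <- function(positions = TRUE, u = TRUE, const = TRUE) {
  c(dx = positions, dy = positions, dz = positions, du = u, dc = const)
}

#' Gradient maps of the model density (design-matrix columns)
#'
#' Differentiates the band-limited model map with respect to each
#' refinable parameter by reciprocal-space multiplication: `2 pi i h_j`
#' for the fractional positional parameters and `-2 pi^2 |s|^2` for
#' U_iso, plus an all-ones constant column that absorbs slowly varying
#' offsets in the difference map.  The sign convention is the parameter
#' derivative: for a small shift `dp` applied to the underlying model,
#' `rho_new ~ rho + (d rho/d p) * dp`, so solved shifts are corrective
#' when added to model parameters.
#'
#' @param model_sf An [sf_set()] of model coefficients (complex `f`),
#'   band-limited to its d_min.
#' @param grid A Shannon-compliant [grid_spec()].
#' @param active Named logical vector over `dx, dy, dz, du, dc` (see
#'   [active_mask()]); only active columns are produced.
#' @return Object of class `gradient_fields`: list with `maps` (named
#'   list of [density_map()]s in canonical order), `grid`, `active`.
#' @export
gradient_maps <- function(model_sf, grid, active = active_mask()) {
  active <- active[PARAM_NAMES]
  if (!any(active, na.rm = TRUE)) {
    abort("no active parameters", class = "shiftfieldr_invalid_argument")
  }
  G <- sf_to_grid(model_sf, as.complex(model_sf$f), grid)
  hk <- grid_hkl_arrays(grid)
  vol <- grid$cell$volume
  maps <- list()
  mults <- list(
    dx = function() 2i * pi * hk$H,
    dy = function() 2i * pi * hk$K,
    dz = function() 2i * pi * hk$L,
    du = function() -2 * pi^2 * hk$s2
  )
  for (nm in PARAM_NAMES) {
    if (!isTRUE(active[[nm]])) next
    maps[[nm]] <- if (nm == "dc") {
      density_map(grid, array(1, dim = grid$n), role = "gradient")
    } else {
      density_map(grid, Re(fft(G * mults[[nm]]())) / vol, role = "gradient")
    }
  }
  structure(list(maps = maps, grid = grid, active = active), class = "gradient_fields")
}

#' @export
print.gradient_fields <- function(x, ...) {
  cat("<gradient_fields>", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}
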