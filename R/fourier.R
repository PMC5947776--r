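#' Structure-factor sets
#'
#' Structure factors are kept as a tibble with integer columns `h, k, l`
#' plus data columns that depend on the role: a complex `f` for calculated
#' or difference coefficients, or `fobs`, `sigma` and logical `free` for
#' observed amplitudes.  The unit cell and resolution limit ride along as
#' attributes.  Storage is Friedel-unique; expansion to the full sphere of
#' reflections applies conjugate symmetry.
#'
#' @param hkl Data frame with integer columns h, k, l.
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in angstrom.
#' @param ... Further per-reflection columns (`f`, `fobs`, `sigma`, `free`).
#' @return A tibble of class `sf_set`.
#' @export
sf_set <- function(hkl, cell, d_min, ...) {
  out <- tibble(h = as.integer(hkl$h), k = as.integer(hkl$k), l = as.integer(hkl$l))
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  attr(out, "cell") <- cell
  attr(out, "d_min") <- d_min
  class(out) <- c("sf_set", class(out))
  out
}

#' @export
#' @rdname sf_set
#' @param x An `sf_set`.
sf_cell <- function(x) attr(x, "cell")

#' @export
#' @rdname sf_set
sf_d_min <- function(x) attr(x, "d_min")

#' Friedel-unique Miller indices to a resolution limit
#'
#' All (h,k,l) with `1/|s| >= d_min`, one member per Friedel pair (the one
#' with h > 0, or h = 0 and k > 0, or h = k = 0 and l >= 0).
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in angstrom (> 0).
#' @param include_f000 Keep the (0,0,0) term?  Default `FALSE`.
#' @return Tibble with integer columns h, k, l and d-spacing `d`.
#' @export
hkl_list <- function(cell, d_min, include_f000 = FALSE) {
  if (!is.finite(d_min) || d_min <= 0) {
    abort("d_min must be positive", class = "shiftfieldr_invalid_argument")
  }
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min) + 1L
  g <- expand.grid(
    l = -hmax[3]:hmax[3], k = -hmax[2]:hmax[2], h = 0:hmax[1],
    KEEP.OUT.ATTRS = FALSE
  )
  H <- cbind(g$h, g$k, g$l)
  keep <- (g$h > 0) | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l >= 0)
  s2 <- s_squared(cell, H)
  keep <- keep & (s2 <= 1 / d_min^2 + 1e-12)
  if (!include_f000) keep <- keep & (s2 > 0)
  H <- H[keep, , drop = FALSE]
  d <- 1 / sqrt(pmax(s2[keep], .Machine$double.eps))
  d[s2[keep] == 0] <- Inf
  tibble(h = H[, 1], k = H[, 2], l = H[, 3], d = d)
}

# R array position (1-based) of Miller index h on an axis of length n
wrap_index <- function(h, n) ((h %% n) + n) %% n + 1L

# Place Friedel-unique coefficients `f` at indices hkl onto a full complex
# grid with conjugate symmetry.  Errors if any index aliases the grid.
sf_to_grid <- function(hkl, f, grid) {
  n <- grid$n
  H <- cbind(hkl$h, hkl$k, hkl$l)
  lim <- (n - 1L) %/% 2L
  if (any(abs(H[, 1]) > lim[1] | abs(H[, 2]) > lim[2] | abs(H[, 3]) > lim[3])) {
    abort("grid too coarse for these Miller indices (resolution aliasing)",
      class = "shiftfieldr_aliasing_error")
  }
  G <- array(0 + 0i, dim = n)
  idx <- function(M) {
    cbind(wrap_index(M[, 1], n[1]), wrap_index(M[, 2], n[2]), wrap_index(M[, 3], n[3]))
  }
  G[idx(H)] <- f
  self <- H[, 1] == 0 & H[, 2] == 0 & H[, 3] == 0
  if (any(!self)) G[idx(-H[!self, , drop = FALSE])] <- Conj(f[!self])
  G
}

#' Fourier transform of a map to structure factors
#'
#' Uses the convention `F(h) = integral rho(x) exp(+2 pi i h.x) dV`, so
#' that `F(0,0,0)` equals the grid sum of the map times the voxel volume
#' (the total electron count for a density map on an absolute scale).
#'
#' @param map A [density_map()].
#' @param d_min Resolution limit in angstrom; the grid must satisfy the
#'   Shannon bound for it.
#' @param include_f000 Keep the (0,0,0) term (default `TRUE`).
#' @return An [sf_set()] with complex column `f`.
#' @export
map_to_sf <- function(map, d_min, include_f000 = TRUE) {
  grid <- map$grid
  cell <- grid$cell
  hkl <- hkl_list(cell, d_min, include_f000 = include_f000)
  n <- grid$n
  lim <- (n - 1L) %/% 2L
  if (any(abs(hkl$h) > lim[1] | abs(hkl$k) > lim[2] | abs(hkl$l) > lim[3])) {
    abort("grid too coarse for d_min (resolution aliasing)",
      class = "shiftfieldr_aliasing_error")
  }
  # F(h) = (V/N) * sum_x rho(x) exp(+2 pi i h.x/n)
  Fg <- fft(map$data, inverse = TRUE) * (cell$volume / prod(n))
  f <- Fg[cbind(
    wrap_index(hkl$h, n[1]), wrap_index(hkl$k, n[2]), wrap_index(hkl$l, n[3])
  )]
  sf_set(hkl, cell, d_min, f = f)
}

#' Fourier synthesis of structure factors onto a grid
#'
#' Inverse of [map_to_sf()]: `rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x)`,
#' expanding the Friedel-unique input to the full sphere by conjugate
#' symmetry so the result is real.
#'
#' @param sf An [sf_set()] with complex column `f` (or the column named by
#'   `column`).
#' @param grid A [grid_spec()] satisfying the Shannon bound for the data.
#' @param column Name of the coefficient column (default "f").
#' @param role Role tag for the output map.
#' @return A [density_map()].
#' @export
sf_to_map <- function(sf, grid, column = "f", role = "model") {
  f <- sf[[column]]
  if (is.null(f)) abort("coefficient column not found", class = "shiftfieldr_invalid_argument")
  G <- sf_to_grid(sf, as.complex(f), grid)
  rho <- Re(fft(G)) / grid$cell$volume
  density_map(grid, rho, role = role)
}
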