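#' Sampling grid over a unit cell
#'
#' A `grid_spec` holds the unit cell plus the number of sampling divisions
#' along each cell axis.  Grid indexing is 0-based conceptually: voxel
#' (0,0,0) sits at fractional (0,0,0); in the underlying R array it is
#' element `[1,1,1]`, with the first (u) index fastest in memory.
#'
#' @param cell A [unit_cell()].
#' @param n Integer vector of length 3: divisions along a, b, c (each >= 2).
#' @return An object of class `grid_spec`: cell, counts `n` and the
#'   approximate voxel spacing (cell edge / count) in angstrom.
#' @export
grid_spec <- function(cell, n) {
  n <- as.integer(round(n))
  if (length(n) != 3 || any(n < 2)) {
    abort("grid needs three axis counts, each >= 2", class = "shiftfieldr_invalid_argument")
  }
  structure(
    list(
      cell = cell,
      n = n,
      spacing = c(cell$a, cell$b, cell$c) / n
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d x %d  spacing %.3f %.3f %.3f A\n",
    x$n[1], x$n[2], x$n[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

# smallest integer >= n whose prime factors are all in {2, 3, 5}
next_fft_friendly <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Build a Shannon-compliant grid for a resolution limit
#'
#' Chooses, per axis, the smallest FFT-friendly count (prime factors 2, 3,
#' 5) whose voxel spacing does not exceed `d_min / (2 * oversample)`.  At
#' the default `oversample = 1.5` the spacing is `d_min/3`, the common
#' crystallographic choice.
#'
#' @param cell A [unit_cell()].
#' @param d_min High-resolution limit in angstrom (> 0).
#' @param oversample Oversampling factor (>= 1); 1 gives exactly the
#'   Shannon rate `d_min/2`.
#' @return A [grid_spec()].
#' @export
build_grid <- function(cell, d_min, oversample = 1.5) {
  if (!is.finite(d_min) || d_min <= 0) {
    abort("d_min must be positive", class = "shiftfieldr_invalid_argument")
  }
  if (!is.finite(oversample) || oversample < 1) {
    abort("oversample must be >= 1", class = "shiftfieldr_invalid_argument")
  }
  target <- d_min / (2 * oversample)
  n <- vapply(
    c(cell$a, cell$b, cell$c),
    function(len) next_fft_friendly(len / target),
    integer(1)
  )
  grid_spec(cell, pmax(n, 2L))
}

#' Real-valued periodic density map
#'
#' A 3D array of real values on a [grid_spec()], wrapping periodically.
#' The same container plays the roles of model map, difference map,
#' gradient map, weight map and shift-field component, distinguished by
#' the `role` tag.
#'
#' @param grid A [grid_spec()].
#' @param data 3D numeric array with dim equal to `grid$n`, or a single
#'   number recycled to a constant map.  All values must be finite.
#' @param role Character tag: one of "model", "difference", "gradient",
#'   "weight", "shift".
#' @return An object of class `density_map`.
#' @export
density_map <- function(grid, data = 0, role = "model") {
  if (length(data) == 1) data <- array(as.numeric(data), dim = grid$n)
  if (!is.array(data) || !identical(dim(data), as.integer(grid$n))) {
    abort("map data must be an array matching the grid counts",
      class = "shiftfieldr_invalid_argument")
  }
  if (!all(is.finite(data))) {
    abort("map values must all be finite", class = "shiftfieldr_invalid_argument")
  }
  structure(list(grid = grid, data = data, role = role), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map:%s> %d x %d x %d  range [%.4g, %.4g]\n",
    x$role, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

# signed "minimum image" index offsets for one axis of length n:
# 0, 1, ..., floor(n/2), -(n - floor(n/2) - 1), ..., -1
signed_axis <- function(n) {
  i <- 0:(n - 1)
  ifelse(i <= n %/% 2, i, i - n)
}

# squared orthogonal distance from the grid origin to every voxel, using
# the wrapped (minimum-image) fractional offset.  Returns an array dim n.
grid_radius_squared <- function(grid) {
  n <- grid$n
  A <- grid$cell$orth
  du <- signed_axis(n[1]) / n[1]
  dv <- signed_axis(n[2]) / n[2]
  dw <- signed_axis(n[3]) / n[3]
  r2 <- array(0, dim = n)
  for (comp in 1:3) {
    m <- outer(outer(du * A[comp, 1], dv * A[comp, 2], `+`), dw * A[comp, 3], `+`)
    r2 <- r2 + m^2
  }
  r2
}

#' Trilinear interpolation on a periodic map
#'
#' Evaluates a [density_map()] at arbitrary fractional positions, exactly
#' at grid points and linearly in each axis between neighbours, wrapping
#' periodically across cell edges.
#'
#' @param map A [density_map()].
#' @param pos Fractional coordinates: length-3 vector or n-by-3 matrix.
#' @return Numeric vector of interpolated values, one per row of `pos`.
#' @export
trilinear_interpolate <- function(map, pos) {
  pos <- as_coord_matrix(pos)
  n <- map$grid$n
  d <- map$data
  out <- numeric(nrow(pos))
  # per-axis integer base and fraction, wrapped
  u <- pos[, 1] * n[1]
  v <- pos[, 2] * n[2]
  w <- pos[, 3] * n[3]
  i0 <- floor(u); j0 <- floor(v); k0 <- floor(w)
  tu <- u - i0; tv <- v - j0; tw <- w - k0
  i0 <- ((i0 %% n[1]) + n[1]) %% n[1]
  j0 <- ((j0 %% n[2]) + n[2]) %% n[2]
  k0 <- ((k0 %% n[3]) + n[3]) %% n[3]
  i1 <- (i0 + 1) %% n[1]
  j1 <- (j0 + 1) %% n[2]
  k1 <- (k0 + 1) %% n[3]
  lin <- function(i, j, k) d[1 + i + n[1] * (j + n[2] * k)]
  out <-
    lin(i0, j0, k0) * (1 - tu) * (1 - tv) * (1 - tw) +
    lin(i1, j0, k0) * tu * (1 - tv) * (1 - tw) +
    lin(i0, j1, k0) * (1 - tu) * tv * (1 - tw) +
    lin(i1, j1, k0) * tu * tv * (1 - tw) +
    lin(i0, j0, k1) * (1 - tu) * (1 - tv) * tw +
    lin(i1, j0, k1) * tu * (1 - tv) * tw +
    lin(i0, j1, k1) * (1 - tu) * tv * tw +
    lin(i1, j1, k1) * tu * tv * tw
  out
}

#' Plot a section through a density map
#'
#' @param object A [density_map()].
#' @param section 1-based index of the section along the third (w) axis.
#' @param ... Unused.
#' @return A ggplot object (raster of the u-v section).
#' @export
autoplot.density_map <- function(object, section = 1L, ...) {
  n <- object$grid$n
  section <- as.integer(section)
  stopifnot(section >= 1, section <= n[3])
  df <- tidyr::expand_grid(v = seq_len(n[2]) - 1L, u = seq_len(n[1]) - 1L)
  df$value <- as.vector(object$data[, , section])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s map, section w = %d", object$role, section - 1L),
      x = "u", y = "v", fill = expression(rho)
    )
}
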