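#' Radial regression kernel g(r)
#'
#' The spherically symmetric function that defines the neighbourhood of
#' the per-voxel regression: `g(r) = 1` (step), `1 - r/r0` (linear) or
#' `1 - (r/r0)^2` (quadratic) for `r < r0`, zero beyond.  The kernel is
#' sampled at every voxel's minimum-image orthogonal distance from the
#' grid origin, so convolution with it sums over a periodic (minimum
#' image) sphere.
#'
#' @param grid A [grid_spec()].
#' @param r0 Limit radius in angstrom; must exceed the largest voxel
#'   spacing and be less than half the shortest cell edge (no
#'   self-overlap through the periodic wrap).
#' @param form "step", "linear" or "quadratic".
#' @return Object of class `radial_kernel`: list with `grid`, `r0`,
#'   `form` and the sampled kernel `data` (array, values in \[0, 1\]).
#' @export
make_kernel <- function(grid, r0, form = c("quadratic", "step", "linear")) {
  form <- match.arg(form)
  if (!is.finite(r0) || r0 <= max(grid$spacing)) {
    abort("r0 must exceed the largest voxel spacing",
      class = "shiftfieldr_invalid_argument")
  }
  if (r0 >= min(grid$cell$a, grid$cell$b, grid$cell$c) / 2) {
    abort("r0 must be less than half the shortest cell edge",
      class = "shiftfieldr_invalid_argument")
  }
  r <- sqrt(grid_radius_squared(grid))
  g <- switch(form,
    step = as.numeric(r < r0),
    linear = pmax(1 - r / r0, 0) * (r < r0),
    quadratic = pmax(1 - (r / r0)^2, 0) * (r < r0)
  )
  structure(
    list(grid = grid, r0 = r0, form = form, data = array(g, dim = grid$n)),
    class = "radial_kernel"
  )
}

#' @export
print.radial_kernel <- function(x, ...) {
  cat(sprintf(
    "<radial_kernel> %s, r0 = %.2f A, %d nonzero voxels\n",
    x$form, x$r0, sum(x$data > 0)
  ))
  invisible(x)
}

# g(r) evaluated by formula (used by the brute-force oracle)
kernel_value <- function(r, r0, form) {
  switch(form,
    step = as.numeric(r < r0),
    linear = pmax(1 - r / r0, 0) * (r < r0),
    quadratic = pmax(1 - (r / r0)^2, 0) * (r < r0)
  )
}

#' Binary solvent mask around a model
#'
#' Weight 1 at voxels whose minimum-image distance to the nearest atomic
#' centre is at most `radius` (default 2.5 angstrom), 0 elsewhere,
#' down-weighting unmodelled solvent in the per-voxel regression.
#'
#' @param model An [atomic_model()].
#' @param grid A [grid_spec()].
#' @param radius Mask radius in angstrom.
#' @return A [density_map()] with role "weight" and values in \{0, 1\};
#'   the mask radius is attached as attribute `mask_radius`.
#' @export
solvent_mask <- function(model, grid, radius = 2.5) {
  cell <- grid$cell
  n <- grid$n
  A <- cell$orth
  frac_width <- sqrt(rowSums(cell$frac^2))
  inside <- array(FALSE, dim = n)
  for (i in seq_len(nrow(model))) {
    ctr <- c(model$x[i], model$y[i], model$z[i])
    lo <- floor((ctr - radius * frac_width) * n)
    hi <- ceiling((ctr + radius * frac_width) * n)
    iu <- lo[1]:hi[1]; iv <- lo[2]:hi[2]; iw <- lo[3]:hi[3]
    du <- iu / n[1] - ctr[1]
    dv <- iv / n[2] - ctr[2]
    dw <- iw / n[3] - ctr[3]
    r2 <- 0
    for (comp in 1:3) {
      m <- outer(outer(du * A[comp, 1], dv * A[comp, 2], `+`), dw * A[comp, 3], `+`)
      r2 <- r2 + m^2
    }
    sel <- which(r2 <= radius^2, arr.ind = TRUE)
    if (nrow(sel) > 0) {
      idx <- cbind(
        wrap_index(iu[sel[, 1]] , n[1]),
        wrap_index(iv[sel[, 2]] , n[2]),
        wrap_index(iw[sel[, 3]] , n[3])
      )
      inside[idx] <- TRUE
    }
  }
  m <- density_map(grid, array(as.numeric(inside), dim = n), role = "weight")
  attr(m, "mask_radius") <- radius
  m
}

#' Uniform (all-ones) weight map
#'
#' @param grid A [grid_spec()].
#' @return A [density_map()] of ones with role "weight".
#' @export
uniform_mask <- function(grid) {
  m <- density_map(grid, array(1, dim = grid$n), role = "weight")
  attr(m, "mask_radius") <- Inf
  m
}
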