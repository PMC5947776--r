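#' Model electron density from Gaussian atoms
#'
#' Each atom contributes a single normalized isotropic Gaussian,
#' `occ * Z * (2 pi U)^(-3/2) * exp(-r^2 / (2U))` in orthogonal angstrom
#' around its position, accumulated with periodic wrap and truncated at
#' `max(3*sqrt(U) + 1, 2.5)` angstrom (under 0.2% mass loss).  This keeps
#' every property the shift-field method depends on (exact analytic
#' Fourier transform, U-differentiability) while avoiding multi-term
#' scattering-factor tables; see the methods vignette.
#'
#' @param model An [atomic_model()].
#' @param grid A [grid_spec()]; spacing should resolve the sharpest atom
#'   (roughly `spacing <= sqrt(min U)`), otherwise a warning is issued.
#' @return A [density_map()] whose grid sum times the voxel volume equals
#'   the total electron count `sum(occ * Z)` to truncation tolerance.
#' @export
model_density <- function(model, grid) {
  cell <- grid$cell
  n <- grid$n
  if (max(grid$spacing) > sqrt(min(model$u_iso)) + 1e-12) {
    warning("grid spacing exceeds sqrt(min U_iso); sharpest atoms may alias",
      call. = FALSE)
  }
  A <- cell$orth
  # fractional half-width of a sphere of radius r along each cell axis
  frac_width <- sqrt(rowSums(cell$frac^2))
  acc <- array(0, dim = n)
  for (i in seq_len(nrow(model))) {
    u <- model$u_iso[i]
    rcut <- max(3 * sqrt(u) + 1, 2.5)
    ctr <- c(model$x[i], model$y[i], model$z[i])
    lo <- floor((ctr - rcut * frac_width) * n)
    hi <- ceiling((ctr + rcut * frac_width) * n)
    if (any(hi - lo + 1 > n)) {
      abort("atom footprint exceeds the unit cell; enlarge the cell or reduce U",
        class = "shiftfieldr_invalid_argument")
    }
    iu <- lo[1]:hi[1]; iv <- lo[2]:hi[2]; iw <- lo[3]:hi[3]
    du <- iu / n[1] - ctr[1]
    dv <- iv / n[2] - ctr[2]
    dw <- iw / n[3] - ctr[3]
    r2 <- 0
    for (comp in 1:3) {
      m <- outer(outer(du * A[comp, 1], dv * A[comp, 2], `+`), dw * A[comp, 3], `+`)
      r2 <- r2 + m^2
    }
    g <- model$occ[i] * model$elec[i] * (2 * pi * u)^(-1.5) * exp(-r2 / (2 * u))
    g[r2 > rcut^2] <- 0
    ui <- wrap_index(iu, n[1]); vi <- wrap_index(iv, n[2]); wi <- wrap_index(iw, n[3])
    acc[ui, vi, wi] <- acc[ui, vi, wi] + g
  }
  density_map(grid, acc, role = "model")
}

#' Direct-summation structure factors of a Gaussian-atom model
#'
#' The exact Fourier transform of the Gaussian-atom density:
#' `F(h) = sum_atoms occ * Z * exp(-2 pi^2 U |s|^2) * exp(2 pi i h.x)`.
#' Serves as the analytic cross-check for `map_to_sf(model_density(.))`
#' and as the driver's calculated-amplitude source.
#'
#' @param model An [atomic_model()].
#' @param hkl Data frame of Miller indices (columns h, k, l), e.g. from
#'   [hkl_list()].
#' @return An [sf_set()] with complex column `f`.
#' @export
sf_direct <- function(model, hkl) {
  cell <- model_cell(model)
  H <- cbind(hkl$h, hkl$k, hkl$l)
  s2 <- s_squared(cell, H)
  ph <- H %*% t(model_xyz(model)) # nrefl x natoms
  amp <- exp(-2 * pi^2 * outer(s2, model$u_iso)) *
    matrix(model$occ * model$elec, nrow(H), nrow(model), byrow = TRUE)
  f <- as.complex(rowSums(amp * exp(2i * pi * ph)))
  d_min <- if (!is.null(attr(hkl, "d_min"))) attr(hkl, "d_min") else {
    min(1 / sqrt(pmax(s2, .Machine$double.eps)))
  }
  sf_set(hkl, cell, d_min, f = f)
}

#' Fit an overall scale and B-factor offset
#'
#' Two-parameter log-linear scaling of calculated to observed amplitudes:
#' minimizes `sum (ln|Fobs| - ln(k |Fcalc|) + 2 pi^2 dU |s|^2)^2` over
#' reflections with positive amplitudes, excluding F(000).  The applied
#' scale is `k * exp(-2 pi^2 dU |s|^2)`, mirroring how full refinement
#' programs absorb a constant U offset into an overall displacement term.
#'
#' @param fobs [sf_set()] with amplitude column `fobs`.
#' @param fcalc [sf_set()] with complex column `f` (or amplitudes `fobs`).
#' @return List of class `scale_params` with elements `k` and `u_overall`
#'   (square angstrom).
#' @export
fit_scale <- function(fobs, fcalc) {
  j <- join_sf(fobs, fcalc)
  ok <- j$ao > 0 & j$ac > 0 & j$s2 > 0
  if (sum(ok) < 10) {
    abort("fewer than 10 usable reflections for scaling",
      class = "shiftfieldr_fit_degenerate")
  }
  y <- log(j$ao[ok]) - log(j$ac[ok])
  X <- cbind(1, j$s2[ok])
  coef <- qr.coef(qr(X), y)
  structure(
    list(k = exp(coef[[1]]), u_overall = -coef[[2]] / (2 * pi^2)),
    class = "scale_params"
  )
}

#' @export
print.scale_params <- function(x, ...) {
  cat(sprintf("<scale_params> k = %.4f  dU_overall = %.4f A^2\n", x$k, x$u_overall))
  invisible(x)
}

# applied per-reflection scale factor k * exp(-2 pi^2 dU s^2)
applied_scale <- function(scale, s2) {
  scale$k * exp(-2 * pi^2 * scale$u_overall * s2)
}

# match fobs and fcalc on (h,k,l); returns amplitudes, s^2, free flags,
# calculated phases.  F(000) rows are dropped.
join_sf <- function(fobs, fcalc) {
  a <- tibble(
    h = fobs$h, k = fobs$k, l = fobs$l,
    ao = if (!is.null(fobs[["fobs"]])) fobs[["fobs"]] else Mod(fobs[["f"]]),
    sigma = if (!is.null(fobs[["sigma"]])) fobs[["sigma"]] else NA_real_,
    free = if (!is.null(fobs[["free"]])) fobs[["free"]] else FALSE
  )
  b <- tibble(
    h = fcalc$h, k = fcalc$k, l = fcalc$l,
    ac = if (!is.null(fcalc[["f"]])) Mod(fcalc[["f"]]) else fcalc[["fobs"]],
    phi = if (!is.null(fcalc[["f"]])) Arg(fcalc[["f"]]) else 0
  )
  j <- dplyr::inner_join(a, b, by = c("h", "k", "l"))
  j <- j[!(j$h == 0 & j$k == 0 & j$l == 0), ]
  cell <- sf_cell(fobs)
  if (is.null(cell)) cell <- sf_cell(fcalc)
  j$s2 <- s_squared(cell, j)
  attr(j, "cell") <- cell
  j
}

#' Crystallographic R factor
#'
#' `R = sum | |Fobs| - k_s |Fcalc| | / sum |Fobs|` over the chosen
#' reflection subset, excluding F(000), with `k_s` the applied scale.
#'
#' @param fobs,fcalc [sf_set()]s sharing a cell.
#' @param scale A `scale_params` from [fit_scale()] (fit on the work set).
#' @param subset "all", "work" or "free".
#' @return The R factor (dimensionless).
#' @export
r_factor <- function(fobs, fcalc, scale, subset = c("all", "work", "free")) {
  subset <- match.arg(subset)
  j <- join_sf(fobs, fcalc)
  sel <- switch(subset, all = rep(TRUE, nrow(j)), work = !j$free, free = j$free)
  if (!any(sel)) abort("empty reflection subset", class = "shiftfieldr_invalid_argument")
  ks <- applied_scale(scale, j$s2[sel])
  sum(abs(j$ao[sel] - ks * j$ac[sel])) / sum(j$ao[sel])
}

#' Difference-map Fourier coefficients
#'
#' Per work reflection, `factor * w * (|Fobs| - k_s |Fcalc|) * exp(i phi_c)`,
#' with `w = 1` or `1/sigma^2` normalized to mean 1.  Free reflections and
#' F(000) are excluded, so held-out data never drive the shift field.  A
#' Fourier synthesis ([sf_to_map()]) of the result is the difference map D.
#' Likelihood (sigma-A) weighting, as used by full refinement programs, is
#' deliberately out of scope; this plain difference map is the package's
#' documented simplification.
#'
#' @inheritParams r_factor
#' @param weighting "none" or "sigma".
#' @param factor Multiplier on the coefficients (default 1; 2 gives the
#'   conventional Fo-Fc style map).
#' @return An [sf_set()] with complex column `f`.
#' @export
difference_coefficients <- function(fobs, fcalc, scale,
                                    weighting = c("none", "sigma"), factor = 1) {
  weighting <- match.arg(weighting)
  if (is.null(fcalc[["f"]])) {
    abort("fcalc must carry complex coefficients (phases required)",
      class = "shiftfieldr_invalid_state")
  }
  j <- join_sf(fobs, fcalc)
  cell <- attr(j, "cell")
  j <- j[!j$free, ]
  w <- rep(1, nrow(j))
  if (weighting == "sigma") {
    if (anyNA(j$sigma) || any(j$sigma <= 0)) {
      abort("sigma weighting requires positive sigmas",
        class = "shiftfieldr_invalid_state")
    }
    w <- 1 / j$sigma^2
    w <- w / mean(w)
  }
  ks <- applied_scale(scale, j$s2)
  f <- as.complex(factor * w * (j$ao - ks * j$ac) * exp(1i * j$phi))
  sf_set(j, cell, sf_d_min(fobs) %||% min(1 / sqrt(j$s2)), f = f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign cross-validation (free-set) flags
#'
#' Deterministic given the seed; each reflection is flagged free with the
#' given probability, independently.
#'
#' @param hkl Data frame of reflections (only the row count is used).
#' @param fraction Free fraction, in (0, 0.5).
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` = free.
#' @export
assign_free_set <- function(hkl, fraction = 0.05, seed = 1) {
  if (fraction <= 0 || fraction >= 0.5) {
    abort("free fraction must lie in (0, 0.5)", class = "shiftfieldr_invalid_argument")
  }
  with_seed(seed, runif(nrow(hkl)) < fraction)
}
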