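#' Unit cell
#'
#' Construct a triclinic unit cell from edge lengths (angstrom) and angles
#' (degrees).  The orthogonalization matrix follows the standard PDB
#' convention: the a axis lies along Cartesian x and the b axis in the x-y
#' plane.  Fractional coordinates are the primary coordinate system
#' throughout the package; orthogonal angstroms are used only for radii,
#' mask distances and reporting.
#'
#' @param a,b,c Cell edge lengths in angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a list with the edge lengths,
#'   angles, cell volume (`volume`, cubic angstrom), the orthogonalization
#'   matrix `orth` (columns are the cell basis vectors in angstrom), its
#'   inverse `frac`, and the reciprocal metric tensor `recip_metric` such
#'   that `|s|^2 = h' G* h` for a Miller-index triple h.
#' @examples
#' cell <- unit_cell(20, 24, 28)
#' frac_to_orth(cell, c(0.5, 0.5, 0.5))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (!all(is.finite(c(a, b, c, alpha, beta, gamma)))) {
    abort("unit cell parameters must be finite", class = "shiftfieldr_invalid_argument")
  }
  if (a <= 0 || b <= 0 || c <= 0) {
    abort("cell edges must be positive", class = "shiftfieldr_invalid_argument")
  }
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180)) {
    abort("cell angles must lie in (0, 180) degrees", class = "shiftfieldr_invalid_argument")
  }
  ca <- cos(alpha * pi / 180)
  cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) {
    abort("cell angles give non-positive volume", class = "shiftfieldr_invalid_argument")
  }
  volume <- a * b * c * sqrt(v2)
  orth <- matrix(
    c(
      a, 0, 0,
      b * cg, b * sg, 0,
      c * cb, c * (ca - cb * cg) / sg, c * sqrt(v2) / sg
    ),
    nrow = 3, ncol = 3
  )
  frac <- solve(orth)
  structure(
    list(
      a = a, b = b, c = c,
      alpha = alpha, beta = beta, gamma = gamma,
      volume = volume,
      orth = orth,
      frac = frac,
      recip_metric = frac %*% t(frac)
    ),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "<unit_cell> %.3f %.3f %.3f A  %.2f %.2f %.2f deg  V = %.1f A^3\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume
  ))
  invisible(x)
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 3, byrow = FALSE)
}

#' Convert between fractional and orthogonal coordinates
#'
#' @param cell A [unit_cell()].
#' @param x Numeric vector of length 3 or an n-by-3 matrix of coordinates
#'   (rows are points).
#' @return A matrix of the same shape in the other coordinate system
#'   (angstrom for `frac_to_orth`, fractional for `orth_to_frac`).
#' @export
frac_to_orth <- function(cell, x) {
  x <- as_coord_matrix(x)
  x %*% t(cell$orth)
}

#' @rdname frac_to_orth
#' @export
orth_to_frac <- function(cell, x) {
  x <- as_coord_matrix(x)
  x %*% t(cell$frac)
}

#' Resolution of Miller indices
#'
#' d-spacing (angstrom) of each reflection, `d = 1/|s|` with
#' `|s|^2 = h' G* h`.
#'
#' @param cell A [unit_cell()].
#' @param hkl n-by-3 integer matrix (or data frame with columns h, k, l).
#' @return Numeric vector of d-spacings; `Inf` for (0,0,0).
#' @export
d_spacing <- function(cell, hkl) {
  1 / sqrt(pmax(s_squared(cell, hkl), 0))
}

# |s|^2 = 1/d^2 for each row of hkl
s_squared <- function(cell, hkl) {
  if (is.data.frame(hkl)) hkl <- cbind(hkl$h, hkl$k, hkl$l)
  hkl <- as_coord_matrix(hkl)
  rowSums((hkl %*% cell$recip_metric) * hkl)
}
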