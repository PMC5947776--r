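#' Apply a shift field to an atomic model
#'
#' Each atom's fractional coordinates are incremented by `damping` times
#' the trilinear value of the `dx, dy, dz` shift maps at the atom's
#' position, and its U_iso by `damping` times the `du` value, clamped to
#' `U >= u_floor` (unconstrained per-voxel shifts can drive U negative on
#' noisy data).  Components absent from the field (inactive parameters)
#' leave the corresponding atom parameters unchanged; voxels flagged
#' singular carry zero shifts by construction.  The constant component
#' `dc` is discarded, as it has no model counterpart.
#'
#' @param model An [atomic_model()].
#' @param field A [shift_field_solve()] result covering the model's cell.
#' @param damping Step-size factor in (0, 1]; the default 1 applies the
#'   solved shifts directly.
#' @param u_floor Lower clamp for U_iso in square angstrom.
#' @return The updated [atomic_model()], with attribute `applied_rms`
#'   (named per-component RMS of the applied shifts: positions in
#'   angstrom along the cell axes, U in square angstrom).
#' @export
apply_to_model <- function(model, field, damping = 1, u_floor = 0.01) {
  stopifnot(damping > 0, damping <= 1)
  cell <- model_cell(model)
  pos <- model_xyz(model)
  rms <- c(dx = 0, dy = 0, dz = 0, du = 0)
  edge <- c(cell$a, cell$b, cell$c)
  for (i in 1:3) {
    nm <- PARAM_NAMES[i]
    if (!is.null(field$maps[[nm]])) {
      dd <- damping * trilinear_interpolate(field$maps[[nm]], pos)
      model[[c("x", "y", "z")[i]]] <- (pos[, i] + dd) %% 1
      rms[nm] <- sqrt(mean(dd^2)) * edge[i]
    }
  }
  if (!is.null(field$maps$du)) {
    dd <- damping * trilinear_interpolate(field$maps$du, pos)
    model$u_iso <- pmax(model$u_iso + dd, u_floor)
    rms["du"] <- sqrt(mean(dd^2))
  }
  attr(model, "applied_rms") <- rms
  model
}

#' Morph a density map with a shift field
#'
#' Pull-back resampling: the output voxel at position q takes the
#' trilinear-interpolated value of the input map at `q - Delta(q)`, using
#' the positional components of the field.  `du` and `dc` components are
#' ignored (applying U shifts to a map is a harder problem and is
#' deliberately not attempted); a notice is logged when they are present.
#'
#' @param map A [density_map()].
#' @param field A [shift_field_solve()] result with positional components.
#' @return The morphed [density_map()].
#' @export
morph_map <- function(map, field) {
  if (is.null(field$maps$dx) || is.null(field$maps$dy) || is.null(field$maps$dz)) {
    abort("morphing needs dx, dy, dz components",
      class = "shiftfieldr_invalid_argument")
  }
  if (!is.null(field$maps$du)) {
    message("morph_map: ignoring du (and dc) components; only positions are resampled")
  }
  n <- map$grid$n
  ax <- (seq_len(n[1]) - 1) / n[1]
  ay <- (seq_len(n[2]) - 1) / n[2]
  az <- (seq_len(n[3]) - 1) / n[3]
  q <- cbind(
    rep(ax, times = n[2] * n[3]),
    rep(rep(ay, each = n[1]), times = n[3]),
    rep(az, each = n[1] * n[2])
  )
  src <- q - cbind(
    as.vector(field$maps$dx$data),
    as.vector(field$maps$dy$data),
    as.vector(field$maps$dz$data)
  )
  density_map(map$grid, array(trilinear_interpolate(map, src), dim = n), role = map$role)
}
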