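# electron counts for the elements the toy crystals and typical PDB files use
ELEMENT_Z <- setNames(
  c(1, 6, 7, 8, 11, 12, 15, 16, 17, 19, 20, 25, 26, 27, 28, 29, 30, 34, 35, 53),
  c("H", "C", "N", "O", "NA", "MG", "P", "S", "CL", "K", "CA", "MN", "FE",
    "CO", "NI", "CU", "ZN", "SE", "BR", "I")
)

element_z <- function(element) {
  z <- ELEMENT_Z[toupper(trimws(element))]
  if (anyNA(z)) {
    abort(paste0(
      "unknown element(s): ",
      paste(unique(element[is.na(z)]), collapse = ", ")
    ), class = "shiftfieldr_invalid_argument")
  }
  unname(z)
}

#' Atomic model
#'
#' An atomic model is a tibble of atoms -- columns `element`, fractional
#' coordinates `x, y, z`, `occ` (occupancy in \[0,1\]), `u_iso` (isotropic
#' displacement, square angstrom; `B = 8 pi^2 U`), electron count `elec`,
#' and bookkeeping columns `chain`, `resno`, `domain` -- with the
#' [unit_cell()] attached as an attribute.  Positions are reduced to
#' \[0, 1) fractional on construction.
#'
#' @param atoms Data frame with at least `element`, `x`, `y`, `z`;
#'   `occ` defaults to 1, `u_iso` to 0.25, `elec` is looked up from the
#'   element symbol when absent.
#' @param cell A [unit_cell()].
#' @return A tibble of class `atomic_model`.
#' @export
atomic_model <- function(atoms, cell) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) < 1) {
    abort("a model needs at least one atom", class = "shiftfieldr_invalid_argument")
  }
  if (is.null(atoms[["occ"]])) atoms$occ <- 1
  if (is.null(atoms[["u_iso"]])) atoms$u_iso <- 0.25
  if (is.null(atoms[["elec"]])) atoms$elec <- element_z(atoms$element)
  if (is.null(atoms[["chain"]])) atoms$chain <- "A"
  if (is.null(atoms[["resno"]])) atoms$resno <- seq_len(nrow(atoms))
  if (is.null(atoms[["domain"]])) atoms$domain <- 1L
  if (any(atoms$u_iso <= 0)) {
    abort("u_iso must be positive", class = "shiftfieldr_invalid_argument")
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) {
    abort("occupancy must lie in [0, 1]", class = "shiftfieldr_invalid_argument")
  }
  for (cc in c("x", "y", "z")) atoms[[cc]] <- atoms[[cc]] %% 1
  atoms <- atoms[c("element", "elec", "x", "y", "z", "occ", "u_iso", "chain", "resno", "domain")]
  attr(atoms, "cell") <- cell
  class(atoms) <- c("atomic_model", class(atoms))
  atoms
}

#' @rdname atomic_model
#' @param model An `atomic_model`.
#' @export
model_cell <- function(model) attr(model, "cell")

# fractional positions as a matrix
model_xyz <- function(model) cbind(model$x, model$y, model$z)

#' Read and write PDB files
#'
#' Minimal fixed-width PDB support: CRYST1 carries the unit cell,
#' ATOM/HETATM records carry element, orthogonal coordinates, occupancy
#' and the B factor (`B = 8 pi^2 U`).  Coordinates are converted to and
#' from the package's fractional convention.
#'
#' @param path File path.
#' @return For `read_pdb`, an [atomic_model()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) < 1) {
    abort("PDB file has no CRYST1 record", class = "shiftfieldr_invalid_argument")
  }
  cv <- as.numeric(c(
    substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33),
    substr(cr[1], 34, 40), substr(cr[1], 41, 47), substr(cr[1], 48, 54)
  ))
  cell <- unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])
  at <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(at) < 1) abort("PDB file has no atoms", class = "shiftfieldr_invalid_argument")
  xyz <- cbind(
    as.numeric(substr(at, 31, 38)),
    as.numeric(substr(at, 39, 46)),
    as.numeric(substr(at, 47, 54))
  )
  elem <- trimws(substr(at, 77, 78))
  # fall back to the atom-name column when the element field is blank
  blank <- elem == ""
  if (any(blank)) elem[blank] <- substr(trimws(substr(at[blank], 13, 16)), 1, 1)
  occ <- as.numeric(substr(at, 55, 60))
  bfac <- as.numeric(substr(at, 61, 66))
  fr <- orth_to_frac(cell, xyz)
  atomic_model(
    tibble(
      element = elem,
      x = fr[, 1], y = fr[, 2], z = fr[, 3],
      occ = occ,
      u_iso = bfac / (8 * pi^2),
      chain = substr(at, 22, 22),
      resno = suppressWarnings(as.integer(substr(at, 23, 26)))
    ),
    cell
  )
}

#' @rdname read_pdb
#' @param model An [atomic_model()].
#' @export
write_pdb <- function(model, path) {
  cell <- model_cell(model)
  xyz <- frac_to_orth(cell, model_xyz(model))
  lines <- c(
    sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma
    ),
    sprintf(
      "ATOM  %5d %-4s LIG %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(model)) %% 100000,
      substr(model$element, 1, 4),
      substr(as.character(model$chain), 1, 1),
      model$resno %% 10000,
      xyz[, 1], xyz[, 2], xyz[, 3],
      model$occ,
      8 * pi^2 * model$u_iso,
      toupper(substr(model$element, 1, 2))
    ),
    "END"
  )
  writeLines(lines, path)
  invisible(path)
}
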