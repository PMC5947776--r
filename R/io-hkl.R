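#' Read and write plain-text reflection files
#'
#' Whitespace-separated columns `h k l Fobs sigma free` with `#` comment
#' lines; `free` is 0/1.  `write_hkl` records the unit cell and
#' resolution limit in a `# CELL` comment, which `read_hkl` recovers
#' (they can also be supplied explicitly).
#'
#' @param path File path.
#' @param cell Optional [unit_cell()] override when reading.
#' @param d_min Optional resolution-limit override when reading.
#' @return For `read_hkl`, an [sf_set()] with `fobs`, `sigma`, `free`.
#' @export
read_hkl <- function(path, cell = NULL, d_min = NULL) {
  lines <- readLines(path)
  cl <- grep("^#\\s*CELL", lines, value = TRUE)
  if (is.null(cell)) {
    if (length(cl) < 1) {
      abort("no cell: supply `cell` or a '# CELL a b c al be ga' header",
        class = "shiftfieldr_invalid_argument")
    }
    v <- as.numeric(strsplit(trimws(sub("^#\\s*CELL", "", cl[1])), "\\s+")[[1]])
    cell <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  d <- read.table(text = lines, comment.char = "#",
    col.names = c("h", "k", "l", "fobs", "sigma", "free"))
  if (is.null(d_min)) d_min <- min(d_spacing(cell, d))
  sf_set(d, cell, d_min, fobs = d$fobs, sigma = d$sigma, free = d$free != 0)
}

#' @rdname read_hkl
#' @param fobs An [sf_set()] with columns `fobs`, `sigma`, `free`.
#' @export
write_hkl <- function(fobs, path) {
  cell <- sf_cell(fobs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# CELL %.4f %.4f %.4f %.3f %.3f %.3f",
      cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
    "# h k l Fobs sigma free"
  ), con)
  write.table(
    data.frame(
      h = fobs$h, k = fobs$k, l = fobs$l,
      fobs = signif(fobs$fobs, 9),
      sigma = signif(fobs[["sigma"]] %||% 0, 9),
      free = as.integer(fobs[["free"]] %||% FALSE)
    ),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}
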