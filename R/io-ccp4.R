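#' Read and write CCP4/MRC density maps
#'
#' Mode-2 (32-bit float) maps covering the full unit cell.  Maps are
#' written X-fastest (axis order 1,2,3, zero start); on read, any axis
#' order in the MAPC/MAPR/MAPS header words is handled, and the header
#' cell and sampling counts are used exactly.  Values are stored in
#' native little-endian byte order.
#'
#' @param path File path.
#' @return For `read_ccp4`, a [density_map()].
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  ncrs <- hdr_int[1:3] # NC, NR, NS
  mode <- hdr_int[4]
  if (mode != 2) {
    abort("only mode-2 (float) CCP4 maps are supported",
      class = "shiftfieldr_invalid_argument")
  }
  nxyz <- hdr_int[8:10] # sampling along cell axes
  cellp <- readBin(con, "numeric", n = 6, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  seek(con, 1024)
  vals <- readBin(con, "numeric", n = prod(ncrs), size = 4, endian = "little")
  cell <- unit_cell(cellp[1], cellp[2], cellp[3], cellp[4], cellp[5], cellp[6])
  # data array in file axis order (col, row, section) -> permute to (x, y, z)
  a <- array(vals, dim = ncrs)
  perm <- order(mapcrs) # position of axis 1,2,3 among (col,row,sec)
  a <- aperm(a, perm)
  grid <- grid_spec(cell, nxyz)
  if (!identical(dim(a), as.integer(grid$n))) {
    abort("map extent does not cover the full cell sampling",
      class = "shiftfieldr_invalid_argument")
  }
  density_map(grid, a, role = "model")
}

#' @rdname read_ccp4
#' @param map A [density_map()].
#' @export
write_ccp4 <- function(map, path) {
  grid <- map$grid
  cell <- grid$cell
  n <- grid$n
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n) # NC NR NS
  wi(2) # MODE 2
  wi(c(0, 0, 0)) # NCSTART NRSTART NSSTART
  wi(n) # NX NY NZ (cell sampling)
  wf(c(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma))
  wi(c(1, 2, 3)) # MAPC MAPR MAPS: X fastest
  wf(c(min(map$data), max(map$data), mean(map$data))) # AMIN AMAX AMEAN
  wi(1) # ISPG = P1
  wi(0) # NSYMBT
  wi(rep(0, 25)) # extra
  wf(c(0, 0, 0)) # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con) # little-endian stamp
  wf(sd(as.vector(map$data))) # RMS
  wi(0) # NLABL
  writeBin(raw(1024 - 56 * 4), con) # pad label block
  wf(as.vector(map$data))
  invisible(path)
}
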