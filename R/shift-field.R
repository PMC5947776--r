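# circular convolution of two arrays of equal dim via FFT
conv_fft <- function(a, b_fft) {
  Re(fft(fft(a) * b_fft, inverse = TRUE)) / length(a)
}

#' Solve the per-voxel shift field by FFT convolution
#'
#' The package's central computation.  For every grid point q the
#' weighted normal equations `A(q) Delta(q) = b(q)` are built with
#' `A_ij(q) = [(w X_i X_j) (x) g](q)` and `b_i(q) = [(w X_i D) (x) g](q)`,
#' where `X_i` are the gradient (design-matrix) columns, `D` the
#' difference map, `w` the per-voxel weights and `g` the radial kernel;
#' `(x)` is periodic convolution, computed as FFT products so the cost is
#' independent of the kernel radius.  With n active columns exactly
#' `n(n+1)/2 + n` convolution passes are performed (20 in full
#' five-parameter mode).  Each voxel's n-by-n system is then solved;
#' `ridge > 0` adds `ridge * trace(A)/n` to the diagonal first, and
#' voxels whose condition number exceeds `cond_cap` get zero shifts and a
#' singular flag (unflagged garbage shifts would corrupt morphing).
#'
#' @param grads A [gradient_maps()] result.
#' @param diff The difference [density_map()] D, on the same grid.
#' @param weights A weight [density_map()] (from [solvent_mask()] or
#'   [uniform_mask()]), or `NULL` for uniform weights.
#' @param kernel A [make_kernel()] result on the same grid.
#' @param ridge Relative ridge regularization (>= 0, default 1e-6).
#' @param cond_cap Condition-number cap (default 1e8).
#' @return Object of class `shift_field`: list with `maps` (named list
#'   of [density_map()]s, one per solved parameter: `dx, dy, dz` in
#'   fractional units, `du` in square angstrom, `dc` in density units),
#'   `singular` (logical array), `n_convolutions`, `grid`.
#' @export
shift_field_solve <- function(grads, diff, weights = NULL, kernel,
                              ridge = 1e-6, cond_cap = 1e8) {
  grid <- grads$grid
  if (!identical(grid$n, diff$grid$n) || !identical(grid$n, kernel$grid$n)) {
    abort("gradient, difference and kernel grids must match",
      class = "shiftfieldr_invalid_argument")
  }
  if (all(kernel$data == 0)) {
    abort("kernel is identically zero", class = "shiftfieldr_invalid_argument")
  }
  w <- if (is.null(weights)) 1 else {
    if (!identical(grid$n, weights$grid$n)) {
      abort("weight grid must match", class = "shiftfieldr_invalid_argument")
    }
    weights$data
  }
  X <- lapply(grads$maps, function(m) m$data)
  nm <- names(X)
  n <- length(X)
  if (n < 1 || (n == 1 && nm[1] == "dc")) {
    abort("need at least one non-constant active parameter",
      class = "shiftfieldr_invalid_argument")
  }
  Kf <- fft(kernel$data)
  nconv <- 0L
  A <- vector("list", n * n) # column-major upper triangle, symmetric fill
  dim(A) <- c(n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      A[[i, j]] <- conv_fft(w * X[[i]] * X[[j]], Kf)
      nconv <- nconv + 1L
    }
  }
  b <- vector("list", n)
  for (i in seq_len(n)) {
    b[[i]] <- conv_fft(w * X[[i]] * diff$data, Kf)
    nconv <- nconv + 1L
  }
  sol <- solve_voxelwise(A, b, n, ridge, cond_cap)
  maps <- list()
  for (i in seq_len(n)) {
    maps[[nm[i]]] <- density_map(grid, array(sol$delta[[i]], dim = grid$n), role = "shift")
  }
  structure(
    list(
      maps = maps,
      singular = array(sol$singular, dim = grid$n),
      n_convolutions = nconv,
      grid = grid
    ),
    class = "shift_field"
  )
}

# Solve the symmetric n-by-n system at every voxel.  A is an n x n list
# matrix of arrays (upper triangle filled); b a list of arrays.  n == 2
# is solved in closed form, vectorized; larger n loops over voxels.
solve_voxelwise <- function(A, b, n, ridge, cond_cap) {
  nv <- length(b[[1]])
  if (n == 1) {
    a11 <- as.vector(A[[1, 1]])
    tr <- a11
    a11 <- a11 + ridge * tr
    bad <- !is.finite(a11) | a11 <= 0
    d1 <- ifelse(bad, 0, as.vector(b[[1]]) / a11)
    return(list(delta = list(d1), singular = bad))
  }
  if (n == 2) {
    a11 <- as.vector(A[[1, 1]]); a12 <- as.vector(A[[1, 2]]); a22 <- as.vector(A[[2, 2]])
    rr <- ridge * (a11 + a22) / 2
    a11 <- a11 + rr; a22 <- a22 + rr
    tr <- a11 + a22
    disc <- sqrt(pmax((a11 - a22)^2 + 4 * a12^2, 0))
    lmin <- (tr - disc) / 2
    lmax <- (tr + disc) / 2
    det <- a11 * a22 - a12^2
    b1 <- as.vector(b[[1]]); b2 <- as.vector(b[[2]])
    bad <- !is.finite(det) | lmin <= 0 | lmax > cond_cap * lmin
    d1 <- ifelse(bad, 0, (a22 * b1 - a12 * b2) / det)
    d2 <- ifelse(bad, 0, (a11 * b2 - a12 * b1) / det)
    return(list(delta = list(d1, d2), singular = bad))
  }
  Av <- matrix(0, nv, n * n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- as.vector(A[[i, j]])
      Av[, (j - 1) * n + i] <- v
      Av[, (i - 1) * n + j] <- v
    }
  }
  Bv <- vapply(b, as.vector, numeric(nv))
  delta <- matrix(0, nv, n)
  singular <- logical(nv)
  diag_idx <- (seq_len(n) - 1) * n + seq_len(n)
  for (q in seq_len(nv)) {
    Am <- matrix(Av[q, ], n, n)
    Am[diag_idx] <- Am[diag_idx] + ridge * sum(Am[diag_idx]) / n
    ok <- all(is.finite(Am))
    if (ok) {
      rc <- tryCatch(rcond(Am), error = function(e) 0)
      ok <- is.finite(rc) && rc > 1 / cond_cap
    }
    if (ok) {
      d <- tryCatch(solve(Am, Bv[q, ]), error = function(e) NULL)
      if (is.null(d) || !all(is.finite(d))) ok <- FALSE else delta[q, ] <- d
    }
    if (!ok) singular[q] <- TRUE
  }
  list(delta = lapply(seq_len(n), function(i) delta[, i]), singular = singular)
}

#' @export
print.shift_field <- function(x, ...) {
  cat(sprintf(
    "<shift_field> components: %s  (%d convolutions, %d singular voxels)\n",
    paste(names(x$maps), collapse = ", "), x$n_convolutions, sum(x$singular)
  ))
  invisible(x)
}

#' Brute-force per-voxel shift solution (reference oracle)
#'
#' Literal weighted least-squares evaluation at a few voxels: enumerates
#' every grid point within `r0` of the target voxel (minimum image),
#' builds the design matrix, weight vector (`w * g(r)`) and
#' difference-map vector explicitly, and solves the normal equations.
#' Quadratic in the sphere size, so intended only as the independent
#' check of [shift_field_solve()] on small grids.
#'
#' @inheritParams shift_field_solve
#' @param r0 Kernel radius in angstrom.
#' @param form Kernel form ("step", "linear", "quadratic").
#' @param voxels Integer m-by-3 matrix of 1-based grid indices.
#' @return Tibble with the voxel indices, one column per solved
#'   parameter, and a logical `singular` column.
#' @export
shift_field_direct <- function(grads, diff, weights = NULL, r0,
                               form = c("quadratic", "step", "linear"),
                               voxels, ridge = 1e-6, cond_cap = 1e8) {
  form <- match.arg(form)
  grid <- grads$grid
  n3 <- grid$n
  cell <- grid$cell
  A <- cell$orth
  w <- if (is.null(weights)) array(1, dim = n3) else weights$data
  X <- lapply(grads$maps, function(m) m$data)
  n <- length(X)
  voxels <- as_coord_matrix(voxels)
  # offsets within r0: enumerate the same signed grid offsets the sampled
  # kernel covers, with g computed from the formula
  off <- list(
    u = signed_axis(n3[1]), v = signed_axis(n3[2]), w = signed_axis(n3[3])
  )
  du <- off$u / n3[1]; dv <- off$v / n3[2]; dw <- off$w / n3[3]
  r2 <- 0
  for (comp in 1:3) {
    m <- outer(outer(du * A[comp, 1], dv * A[comp, 2], `+`), dw * A[comp, 3], `+`)
    r2 <- r2 + m^2
  }
  sel <- which(sqrt(r2) < r0, arr.ind = TRUE)
  g <- kernel_value(sqrt(r2[sel]), r0, form)
  offs <- cbind(off$u[sel[, 1]], off$v[sel[, 2]], off$w[sel[, 3]])
  out <- matrix(0, nrow(voxels), n)
  singular <- logical(nrow(voxels))
  for (qi in seq_len(nrow(voxels))) {
    q <- voxels[qi, ]
    # A_ij(q) = sum_p w[p] X_i[p] X_j[p] g(q - p): p = q + offset, g at -offset
    # (g is even, so enumerate p = q + offs with weight g(|offs|))
    iu <- wrap_index(q[1] - 1 + offs[, 1], n3[1])
    iv <- wrap_index(q[2] - 1 + offs[, 2], n3[2])
    iw <- wrap_index(q[3] - 1 + offs[, 3], n3[3])
    lin <- iu + n3[1] * (iv - 1L) + n3[1] * n3[2] * (iw - 1L)
    wg <- w[lin] * g
    Xm <- vapply(X, function(a) a[lin], numeric(length(lin)))
    Y <- diff$data[lin]
    Am <- crossprod(Xm, wg * Xm)
    bv <- crossprod(Xm, wg * Y)
    diag(Am) <- diag(Am) + ridge * sum(diag(Am)) / n
    ok <- all(is.finite(Am)) && nrow(Xm) >= n
    if (ok) {
      rc <- tryCatch(rcond(Am), error = function(e) 0)
      ok <- is.finite(rc) && rc > 1 / cond_cap
    }
    if (ok) {
      d <- tryCatch(solve(Am, bv), error = function(e) NULL)
      if (is.null(d) || !all(is.finite(d))) ok <- FALSE else out[qi, ] <- d
    }
    if (!ok) singular[qi] <- TRUE
  }
  res <- tibble(u = voxels[, 1], v = voxels[, 2], w = voxels[, 3])
  for (i in seq_len(n)) res[[names(X)[i]]] <- out[, i]
  res$singular <- singular
  res
}
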