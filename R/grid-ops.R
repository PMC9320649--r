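# Discrete operators on the vertex-centred unit-square grid.
#
# Spatial quadrature is the trapezoidal rule (1D weights h*(1/2,1,...,1,1/2),
# tensorised), which integrates the unit square to exactly 1 and makes the
# mean-projection / adjoint algebra exact.

#' Node coordinates of a grid
#' @param grid a [GridSpec].
#' @return numeric vector of length `n` with coordinates `0, h, ..., 1`.
#' @export
gridCoords <- function(grid) seq(0, 1, length.out = grid@n)

# Tensorised trapezoid weights *without* the h^2 factor (used to symmetrise
# the implicit operator); and with it (used for integrals).
trapWeights1 <- function(n) c(0.5, rep(1, n - 2L), 0.5)

quadWeights <- function(grid) {
  w1 <- trapWeights1(grid@n)
  outer(w1, w1) * grid@spacing^2
}

#' Quadrature integral and mean over the unit square
#'
#' Trapezoidal-rule integral of a nodal field; the mean equals the integral
#' because the domain has unit area.
#'
#' @param f numeric matrix or [PhaseField].
#' @param grid a [GridSpec] (ignored when `f` is a [PhaseField]).
#' @return numeric scalar.
#' @export
quadIntegral <- function(f, grid) {
  if (is(f, "PhaseField")) { grid <- f@grid; f <- f@values }
  sum(quadWeights(grid) * f)
}

#' @rdname quadIntegral
#' @export
quadMean <- function(f, grid) quadIntegral(f, grid)

#' Five-point Laplacian with homogeneous Neumann boundary
#'
#' Applies the standard five-point stencil with mirror (ghost-node
#' reflection) treatment of the boundary, so a constant field maps to exactly
#' zero everywhere including on the boundary.
#'
#' @param f numeric matrix shaped to the grid, or a [PhaseField].
#' @param grid a [GridSpec].
#' @return numeric matrix of the same shape.
#' @export
laplacianNeumann <- function(f, grid) {
  if (is(f, "PhaseField")) { grid <- f@grid; f <- f@values }
  n <- grid@n
  if (!all(dim(f) == c(n, n))) stop("field shape does not match the grid")
  im <- c(2L, seq_len(n - 1L))        # i-1 with mirror at the boundary
  ip <- c(seq(2L, n), n - 1L)         # i+1 with mirror
  (f[im, ] + f[ip, ] + f[, im] + f[, ip] - 4 * f) / grid@spacing^2
}

# Sparse 1D Neumann Laplacian (mirror ghosts), n x n, including 1/h^2.
neumannLap1D <- function(n, h) {
  i <- c(seq_len(n), seq_len(n - 1L), seq(2L, n))
  j <- c(seq_len(n), seq(2L, n), seq_len(n - 1L))
  x <- c(rep(-2, n), c(2, rep(1, n - 2L)), c(rep(1, n - 2L), 2))
  Matrix::sparseMatrix(i = i, j = j, x = x / h^2, dims = c(n, n))
}

# Cache of factorised implicit operators, keyed by (n, alpha).  The IMEX
# update solves (I - alpha * Lap) phi = rhs; the operator is symmetrised by
# the trapezoid weights W (W(I - alpha L) is SPD) and factorised once per
# (grid, dt) by sparse Cholesky.
.opCache <- new.env(parent = emptyenv())

implicitOperator <- function(grid, alpha) {
  key <- sprintf("n%d_a%.17g", grid@n, alpha)
  hit <- get0(key, envir = .opCache)
  if (!is.null(hit)) return(hit)
  n <- grid@n
  D1 <- neumannLap1D(n, grid@spacing)
  I1 <- Matrix::Diagonal(n)
  L2 <- Matrix::kronecker(I1, D1) + Matrix::kronecker(D1, I1)
  w2 <- as.vector(outer(trapWeights1(n), trapWeights1(n)))
  M <- Matrix::forceSymmetric(
    Matrix::Diagonal(x = w2) %*% (Matrix::Diagonal(n^2) - alpha * L2))
  ch <- Matrix::Cholesky(M, LDL = FALSE)
  op <- list(ch = ch, w2 = w2, n = n)
  assign(key, op, envir = .opCache)
  op
}

# Solve (I - alpha L) x = v  (v, x as n x n matrices).
applyAinv <- function(v, op) {
  x <- Matrix::solve(op$ch, op$w2 * as.vector(v), system = "A")
  matrix(as.numeric(x), op$n, op$n)
}

# Apply the transpose inverse (I - alpha L)^-T y = W (W(I-alpha L))^-1 y.
applyAinvT <- function(y, op) {
  x <- Matrix::solve(op$ch, as.vector(y), system = "A")
  matrix(op$w2 * as.numeric(x), op$n, op$n)
}

# Bilinear interpolation of Z given ascending source coordinates.  Queries
# outside the source rectangle are clamped to the boundary value.
interpBilinear <- function(xsrc, ysrc, Z, xq, yq) {
  nx <- length(xsrc); ny <- length(ysrc)
  xq <- pmin(pmax(xq, xsrc[1]), xsrc[nx])
  yq <- pmin(pmax(yq, ysrc[1]), ysrc[ny])
  ix <- pmin(pmax(findInterval(xq, xsrc), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(yq, ysrc), 1L), ny - 1L)
  tx <- (xq - xsrc[ix]) / (xsrc[ix + 1L] - xsrc[ix])
  ty <- (yq - ysrc[iy]) / (ysrc[iy + 1L] - ysrc[iy])
  z00 <- Z[cbind(ix, iy)]; z10 <- Z[cbind(ix + 1L, iy)]
  z01 <- Z[cbind(ix, iy + 1L)]; z11 <- Z[cbind(ix + 1L, iy + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

# Sample a nodal field at dimensionless points (vectorised).
sampleField <- function(values, grid, x, y) {
  co <- gridCoords(grid)
  interpBilinear(co, co, values, x, y)
}
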