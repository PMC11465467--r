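# Complex sparse operators as a pair of real dgCMatrix parts.
#
# 'Matrix' has no complex sparse class, so every operator in the package is a
# "zspm": list(re, im) with both parts n x n dgCMatrix.  All algebra needed for
# Hamiltonian assembly and state propagation (kron, add, scalar multiply,
# matrix-vector products) maps onto real sparse operations, which keeps the
# memory footprint O(nnz) and never densifies a large operator.

.as_dgc <- function(m) {
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

zspm <- function(re, im = NULL) {
  re <- .as_dgc(re)
  if (is.null(im)) im <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                              x = numeric(), dims = dim(re))
  im <- .as_dgc(im)
  stopifnot(identical(dim(re), dim(im)))
  structure(list(re = re, im = im), class = "zspm")
}

zspm_zero <- function(n) {
  z <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(n, n))
  zspm(z, z)
}

zspm_identity <- function(n) zspm(Matrix::Diagonal(n), NULL)

zspm_dim <- function(a) nrow(a$re)

zspm_from_dense <- function(m) {
  m <- as.matrix(m)
  zspm(Matrix::Matrix(Re(m), sparse = TRUE), Matrix::Matrix(Im(m), sparse = TRUE))
}

zspm_dense <- function(a) as.matrix(a$re) + 1i * as.matrix(a$im)

zspm_add <- function(a, b) zspm(a$re + b$re, a$im + b$im)

# scalar z may be complex
zspm_scale <- function(a, z) {
  zr <- Re(z); zi <- Im(z)
  if (zi == 0) return(zspm(zr * a$re, zr * a$im))
  zspm(zr * a$re - zi * a$im, zr * a$im + zi * a$re)
}

zspm_kron <- function(a, b) {
  re <- Matrix::kronecker(a$re, b$re) - Matrix::kronecker(a$im, b$im)
  im <- Matrix::kronecker(a$re, b$im) + Matrix::kronecker(a$im, b$re)
  zspm(re, im)
}

# y = A %*% v for complex v; returns a plain complex vector (or matrix if v is
# a matrix of column states).
zspm_matvec <- function(a, v) {
  if (is.matrix(v)) {
    xr <- Re(v); xi <- Im(v)
    yr <- as.matrix(a$re %*% xr - a$im %*% xi)
    yi <- as.matrix(a$re %*% xi + a$im %*% xr)
    matrix(complex(real = yr, imaginary = yi), nrow = nrow(v))
  } else {
    xr <- Re(v); xi <- Im(v)
    yr <- as.numeric(a$re %*% xr - a$im %*% xi)
    yi <- as.numeric(a$re %*% xi + a$im %*% xr)
    complex(real = yr, imaginary = yi)
  }
}

zspm_conj_transpose <- function(a) zspm(Matrix::t(a$re), -Matrix::t(a$im))

zspm_nnz <- function(a) length(a$re@x) + length(a$im@x)

zspm_is_hermitian <- function(a, tol = 1e-10) {
  dre <- max(0, abs(a$re - Matrix::t(a$re))@x, 0)
  dim_ <- a$im + Matrix::t(a$im)
  dim2 <- max(0, abs(dim_)@x, 0)
  isTRUE(dre < tol) && isTRUE(dim2 < tol)
}

# <u | A | v>  (single vectors)
zspm_quadform <- function(a, u, v = u) {
  sum(Conj(u) * zspm_matvec(a, v))
}

# Real expectation <v|A|v> per column of a state matrix, for Hermitian A.
zspm_expect_cols <- function(a, v) {
  av <- zspm_matvec(a, v)
  if (is.matrix(v)) Re(colSums(Conj(v) * av)) else Re(sum(Conj(v) * av))
}

# Dense complex matrix exponential by scaling-and-squaring with a Taylor
# series evaluated at norm <= 0.5 (converges to machine precision in ~ 20
# terms).  Used for the small matrices arising from Krylov projections and
# for whole propagators of small systems.
expm_z <- function(a) {
  a <- as.matrix(a)
  n <- nrow(a)
  nrm <- max(colSums(abs(a)))
  if (!is.finite(nrm)) stop("non-finite matrix passed to expm_z()")
  s <- if (nrm > 0.5) ceiling(log2(nrm / 0.5)) else 0L
  a <- a / 2^s
  acc <- diag(1 + 0i, n)
  term <- acc
  for (k in 1:40) {
    term <- (term %*% a) / k
    acc <- acc + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) acc <- acc %*% acc
  acc
}
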