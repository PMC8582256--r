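# Shared numerical helpers: canonical orbital-pair indexing, packed symmetric
# storage, and small linear-algebra utilities used across the package.

#' Number of canonical orbital pairs
#'
#' @param n Number of orbitals.
#' @return `n * (n + 1) / 2`.
#' @keywords internal
#' @noRd
pair_dim <- function(n) as.integer(n * (n + 1L) / 2L)

#' Canonical pair index of an orbital pair
#'
#' Pairs (p, q) are stored lower-triangular, p >= q, in the order
#' (1,1), (2,1), (2,2), (3,1), ... so that the index is p(p-1)/2 + q.
#' Vectorized over p and q.
#'
#' @param p,q 1-based orbital indices (order irrelevant).
#' @return Integer pair index.
#' @keywords internal
#' @noRd
pair_index <- function(p, q) {
  hi <- pmax(p, q)
  lo <- pmin(p, q)
  as.integer(hi * (hi - 1L) / 2L + lo)
}

#' Table of canonical pairs for n orbitals
#'
#' @return Integer matrix with columns `p`, `q` (p >= q), row i being the
#'   pair with index i.
#' @keywords internal
#' @noRd
pair_table <- function(n) {
  p <- rep.int(seq_len(n), times = seq_len(n))
  q <- sequence(seq_len(n))
  cbind(p = p, q = q)
}

#' Expand a packed pair vector to a symmetric matrix
#'
#' Cholesky vectors (and any quantity indexed by canonical orbital pairs)
#' are stored lower-triangular; this restores the full symmetric matrix.
#'
#' @param v Packed vector of length `n (n + 1) / 2`.
#' @param n Matrix dimension.
#' @export
unpack_sym <- function(v, n) {
  m <- matrix(0, n, n)
  tab <- pair_table(n)
  m[cbind(tab[, 1L], tab[, 2L])] <- v
  m[cbind(tab[, 2L], tab[, 1L])] <- v
  m
}

#' Pack a symmetric matrix to its lower-triangular pair vector
#'
#' Inverse of [unpack_sym()].
#'
#' @param m Symmetric matrix.
#' @export
pack_sym <- function(m) {
  tab <- pair_table(nrow(m))
  m[cbind(tab[, 1L], tab[, 2L])]
}

#' Root-mean-square norm ||v||_2 / sqrt(length(v))
#'
#' Dimension-robust gradient norm used for the convergence criterion; an
#' empty vector has RMS 0 by convention (e.g. full-space active sets have
#' no orbital rotations).
#'
#' @param v Numeric vector.
#' @export
rms_norm <- function(v) {
  if (length(v) == 0L) return(0)
  sqrt(sum(v^2) / length(v))
}

#' Check a matrix for symmetry within a relative tolerance
#' @keywords internal
#' @noRd
check_symmetric <- function(m, tol = 1e-12, what = "matrix") {
  if (nrow(m) != ncol(m)) stop(what, " must be square", call. = FALSE)
  scale <- max(1, max(abs(m)))
  dev <- max(abs(m - t(m))) / scale
  if (dev > tol) {
    stop(what, " not symmetric (relative deviation ", format(dev), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Symmetric orthogonalizer S^(-1/2)
#' @keywords internal
#' @noRd
inv_sqrt_sym <- function(s) {
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) <= 0) {
    stop("overlap matrix is not positive-definite (min eigenvalue ",
         format(min(e$values)), ")", call. = FALSE)
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Matrix exponential of an antisymmetric matrix via its spectral form
#'
#' exp(K) for K = -K^T is orthogonal to machine precision.  Uses the
#' eigendecomposition of the symmetric matrix i*K realized over the reals
#' through the complex Hermitian eigenproblem.
#' @keywords internal
#' @noRd
expm_antisym <- function(k) {
  n <- nrow(k)
  if (max(abs(k + t(k))) > 1e-10 * max(1, max(abs(k)))) {
    stop("rotation generator is not antisymmetric", call. = FALSE)
  }
  if (max(abs(k)) == 0) return(diag(n))
  # iK is Hermitian; exp(K) = V exp(-i theta) V^H restricted to the reals
  e <- eigen(1i * k, symmetric = TRUE)
  u <- e$vectors %*% (exp(-1i * e$values) * Conj(t(e$vectors)))
  Re(u)
}

#' Gram-Schmidt projection of a vector against an orthonormal set
#'
#' Columns of `basis` are assumed orthonormal; performs two passes for
#' numerical stability and returns NULL when the remainder is negligible.
#' @keywords internal
#' @noRd
orthonormalize_against <- function(v, basis, tol = 1e-10) {
  for (pass in 1:2) {
    if (!is.null(basis) && ncol(basis) > 0L) {
      v <- v - basis %*% crossprod(basis, v)
    }
  }
  nv <- sqrt(sum(v^2))
  if (nv < tol) return(NULL)
  as.numeric(v) / nv
}
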