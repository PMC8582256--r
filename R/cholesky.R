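# Threshold-controlled pivoted Cholesky decomposition of the ERI pair
# matrix, MO transformation of the Cholesky vectors, error certificates and
# the compression-rate diagnostic.
#
# The pair matrix M[(pq),(rs)] = (pq|rs) is symmetric positive-semidefinite,
# so it factorizes as M = sum_K L^K (L^K)^T with the greedy max-diagonal
# pivoting stopping as soon as the residual diagonal falls below the
# threshold; the Cauchy-Schwarz inequality then bounds the max error on any
# reconstructed integral by that same threshold.

#' Pivoted Cholesky decomposition of an ERI pair matrix
#'
#' @param eri Either an `eri_pair` matrix, or a list with function fields
#'   `diag()` (returning the exact pair diagonal (pq|pq)) and `column(j)`
#'   (returning pair column j of the exact matrix) for matrix-free use.
#' @param threshold Decomposition tolerance delta >= 0; iteration stops when
#'   the largest residual diagonal element is `<= threshold` (0 requests an
#'   exact factorization).
#' @param max_vectors Optional cap on the number of vectors.
#' @return An object of class `cholesky_factor`: packed vectors (one column
#'   per Cholesky vector over canonical pairs), `n_orb`, `n_ch`,
#'   `threshold`, `max_residual` (final max residual diagonal) and
#'   `pivot_order`.
#' @export
cd_decompose <- function(eri, threshold = 1e-4, max_vectors = NULL) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (inherits(eri, "eri_pair")) {
    n_orb <- attr(eri, "n_orb")
    d0 <- diag(eri)
    column <- function(j) eri[, j]
  } else if (is.list(eri) && is.function(eri$column)) {
    n_orb <- eri$n_orb
    d0 <- eri$diag()
    column <- eri$column
  } else {
    stop("eri must be an eri_pair matrix or a diag/column provider list",
         call. = FALSE)
  }
  np <- length(d0)
  if (is.null(max_vectors)) max_vectors <- np
  d <- d0
  if (min(d) < -1e-10) {
    stop("decomposition error: negative ERI diagonal at pair ",
         which.min(d), call. = FALSE)
  }
  d[d < 0] <- 0
  # threshold 0 means "to roundoff": stop at the numerical floor of the
  # residual update instead of factorizing accumulated noise
  stop_at <- max(threshold, 1e-12 * max(d, 1e-300))
  vecs <- matrix(0, np, 0L)
  pivots <- integer(0)
  while (max(d) > stop_at && ncol(vecs) < max_vectors) {
    j <- which.max(d)
    col <- column(j)
    if (ncol(vecs) > 0L) col <- col - vecs %*% vecs[j, ]
    lk <- as.numeric(col) / sqrt(d[j])
    vecs <- cbind(vecs, lk, deparse.level = 0)
    pivots <- c(pivots, j)
    d <- d - lk^2
    if (min(d) < -1e-10) {
      stop("decomposition error: matrix not positive-semidefinite ",
           "(residual ", format(min(d)), " after pivot ", j, ")",
           call. = FALSE)
    }
    d[d < 0] <- 0  # clip roundoff-level negatives
  }
  structure(
    list(vectors = vecs, n_orb = as.integer(n_orb),
         n_ch = ncol(vecs), threshold = threshold,
         max_residual = max(d), pivot_order = pivots),
    class = "cholesky_factor")
}

#' @export
print.cholesky_factor <- function(x, ...) {
  cat("Cholesky ERI factor:", x$n_ch, "vectors over",
      pair_dim(x$n_orb), "pairs\n")
  cat("  threshold:", format(x$threshold),
      " max residual:", format(x$max_residual), "\n")
  cat("  compression factor:",
      format(compression_factor(x$n_orb, max(x$n_ch, 1L)), digits = 4), "\n")
  invisible(x)
}

#' Reconstruct the dense ERI pair matrix from a Cholesky factor
#'
#' @param factor A `cholesky_factor`.
#' @return An `eri_pair` matrix `sum_K L^K (L^K)^T`.
#' @export
cd_reconstruct <- function(factor) {
  stopifnot(inherits(factor, "cholesky_factor"))
  as_eri_pair(tcrossprod(factor$vectors), factor$n_orb)
}

#' Maximum absolute reconstruction error of a Cholesky factor
#'
#' @param factor A `cholesky_factor`.
#' @param exact The exact `eri_pair` matrix it approximates.
#' @return max over canonical pairs of |sum_K L^K_pq L^K_rs - (pq|rs)|.
#' @export
cd_reconstruction_error <- function(factor, exact) {
  stopifnot(inherits(factor, "cholesky_factor"))
  if (pair_dim(factor$n_orb) != nrow(exact)) {
    stop("dimension mismatch between factor and exact ERI", call. = FALSE)
  }
  max(abs(tcrossprod(factor$vectors) - exact))
}

#' Cholesky compression rate
#'
#' f = N_b (N_b + 1) / (2 N_ch): the ratio between the full pair dimension
#' and the number of Cholesky vectors actually kept.
#'
#' @param n_b Number of basis functions.
#' @param n_ch Number of Cholesky vectors (>= 1).
#' @export
compression_factor <- function(n_b, n_ch) {
  if (n_ch < 1) stop("n_ch must be >= 1", call. = FALSE)
  n_b * (n_b + 1) / (2 * n_ch)
}

#' Transform Cholesky vectors from the AO to the MO basis
#'
#' Each packed vector is expanded to its symmetric matrix L^K and
#' transformed independently as C^T L^K C, so the transformed set inherits
#' the reconstruction guarantee of the AO factor for the MO-basis ERIs.
#'
#' @param factor A `cholesky_factor` in the AO basis.
#' @param mo_coeff `n_b x n_mo` MO coefficient matrix, S-orthonormal.
#' @param overlap AO overlap matrix (identity when omitted).
#' @return An object of class `mo_cholesky`: 3-D array `L[p, q, K]` of MO
#'   Cholesky vectors plus the originating threshold.
#' @export
cd_ao_to_mo <- function(factor, mo_coeff, overlap = NULL) {
  stopifnot(inherits(factor, "cholesky_factor"))
  mo_coeff <- as.matrix(mo_coeff)
  n_b <- factor$n_orb
  if (nrow(mo_coeff) != n_b) stop("mo_coeff row dimension mismatch",
                                  call. = FALSE)
  s <- if (is.null(overlap)) diag(n_b) else as.matrix(overlap)
  dev <- max(abs(crossprod(mo_coeff, s %*% mo_coeff) - diag(ncol(mo_coeff))))
  if (dev > 1e-8) {
    stop("mo_coeff not S-orthonormal (max deviation ", format(dev), ")",
         call. = FALSE)
  }
  n_mo <- ncol(mo_coeff)
  k <- factor$n_ch
  arr <- array(0, c(n_mo, n_mo, max(k, 0L)))
  for (K in seq_len(k)) {
    lk <- unpack_sym(factor$vectors[, K], n_b)
    m <- crossprod(mo_coeff, lk %*% mo_coeff)
    arr[, , K] <- (m + t(m)) / 2
  }
  structure(list(l = arr, n_mo = n_mo, n_ch = k,
                 threshold = factor$threshold,
                 mo_fingerprint = sum(mo_coeff * seq_along(mo_coeff))),
            class = "mo_cholesky")
}

#' Dense MO-basis ERI block from MO Cholesky vectors
#'
#' @param mo_chol An `mo_cholesky` object.
#' @param idx Orbital indices of the block (default all).
#' @return 4-index array g with g[u,v,x,y] = (uv|xy) over `idx`.
#' @export
mo_eri_block <- function(mo_chol, idx = seq_len(mo_chol$n_mo)) {
  na <- length(idx)
  k <- mo_chol$n_ch
  b <- matrix(0, na * na, max(k, 1L))
  for (K in seq_len(k)) {
    b[, K] <- as.numeric(mo_chol$l[idx, idx, K])
  }
  array(tcrossprod(b), c(na, na, na, na))
}
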