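# IntegralSet: the canonical one-/two-electron integral container.
#
# The two-electron integrals (pq|rs) (Mulliken notation, 8-fold permutational
# symmetry) are held as the symmetric positive-semidefinite pair matrix
# M[(pq),(rs)] over canonical lower-triangular pairs p >= q, the
# representation on which the pivoted Cholesky decomposition acts.

#' Construct an integral set
#'
#' Bundles the one-electron integrals, two-electron integrals, overlap,
#' nuclear repulsion and electron count describing a full system.  The
#' two-electron integrals may be either a dense pair matrix (see
#' [eri_pair_matrix()]) or a `cholesky_factor` from [cd_decompose()].
#'
#' @param h_core Symmetric `n_orb x n_orb` one-electron integral matrix
#'   h_pq (hartree).
#' @param eri Either an `eri_pair` matrix of (pq|rs) over canonical pairs,
#'   or a `cholesky_factor`.
#' @param n_elec Electron count.
#' @param e_nuc Nuclear repulsion / constant energy shift (hartree).
#' @param overlap Symmetric positive-definite overlap matrix S; identity
#'   (orthonormal basis) when omitted.
#' @return An object of class `integral_set` with fields `n_orb`, `n_elec`,
#'   `h_core`, `overlap`, `eri`, `e_nuc`.
#' @export
integral_set <- function(h_core, eri, n_elec, e_nuc = 0, overlap = NULL) {
  h_core <- as.matrix(h_core)
  check_symmetric(h_core, 1e-12, "h_core")
  n_orb <- nrow(h_core)
  if (is.null(overlap)) overlap <- diag(n_orb)
  overlap <- as.matrix(overlap)
  check_symmetric(overlap, 1e-12, "overlap")
  ev_s <- eigen(overlap, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_s) <= 0) stop("overlap must be positive-definite", call. = FALSE)
  if (inherits(eri, "cholesky_factor")) {
    if (eri$n_orb != n_orb) stop("ERI factor dimension mismatch", call. = FALSE)
  } else {
    eri <- as_eri_pair(eri, n_orb)
  }
  if (n_elec < 0 || n_elec > 2L * n_orb) {
    stop("impossible electron count ", n_elec, " for ", n_orb, " orbitals",
         call. = FALSE)
  }
  structure(
    list(n_orb = n_orb, n_elec = as.integer(n_elec), h_core = h_core,
         overlap = overlap, eri = eri, e_nuc = e_nuc),
    class = "integral_set")
}

#' @export
print.integral_set <- function(x, ...) {
  kind <- if (inherits(x$eri, "cholesky_factor")) {
    sprintf("Cholesky factor (%d vectors, threshold %g)",
            x$eri$n_ch, x$eri$threshold)
  } else "dense pair matrix"
  cat("Integral set:", x$n_orb, "orbitals,", x$n_elec, "electrons\n")
  cat("  ERI storage:", kind, "\n")
  cat("  e_nuc:", format(x$e_nuc), "\n")
  invisible(x)
}

#' Validate/construct a dense ERI pair matrix
#'
#' @param m Square matrix of dimension `n_orb (n_orb + 1) / 2` holding
#'   (pq|rs) at row `pair(p,q)`, column `pair(r,s)`.
#' @param n_orb Orbital count.
#' @return `m` with class `eri_pair` and attribute `n_orb`.
#' @export
as_eri_pair <- function(m, n_orb) {
  m <- as.matrix(m)
  np <- pair_dim(n_orb)
  if (nrow(m) != np || ncol(m) != np) {
    stop("ERI pair matrix must be ", np, " x ", np, " for ", n_orb,
         " orbitals", call. = FALSE)
  }
  check_symmetric(m, 1e-12, "ERI pair matrix")
  structure(m, class = "eri_pair", n_orb = as.integer(n_orb))
}

#' Build an ERI pair matrix from a dense 4-index array
#'
#' @param g `n^4` array with `g[p,q,r,s] = (pq|rs)`.
#' @return `eri_pair` matrix over canonical pairs.
#' @export
eri_pair_matrix <- function(g) {
  n <- dim(g)[1L]
  tab <- pair_table(n)
  np <- nrow(tab)
  m <- matrix(0, np, np)
  for (ij in seq_len(np)) {
    p <- tab[ij, 1L]; q <- tab[ij, 2L]
    m[ij, ] <- g[p, q, ][cbind(tab[, 1L], tab[, 2L])]
  }
  as_eri_pair((m + t(m)) / 2, n)
}

#' Expand an ERI pair matrix (or Cholesky factor) to a dense 4-index array
#'
#' Intended for small systems and test oracles; scales as n^4 in memory.
#'
#' @param eri `eri_pair` matrix or `cholesky_factor`.
#' @return Array `g` with `g[p,q,r,s] = (pq|rs)` and all 8 permutational
#'   symmetries exact.
#' @export
eri_array <- function(eri) {
  if (inherits(eri, "cholesky_factor")) eri <- cd_reconstruct(eri)
  n <- attr(eri, "n_orb")
  tab <- pair_table(n)
  g <- array(0, c(n, n, n, n))
  np <- nrow(tab)
  for (ij in seq_len(np)) {
    p <- tab[ij, 1L]; q <- tab[ij, 2L]
    col <- unpack_sym(eri[ij, ], n)
    g[p, q, , ] <- col
    g[q, p, , ] <- col
  }
  g
}

#' Look up a single two-electron integral (pq|rs)
#'
#' @param eri `eri_pair` matrix.
#' @param p,q,r,s 1-based orbital indices.
#' @export
eri_element <- function(eri, p, q, r, s) {
  eri[pair_index(p, q), pair_index(r, s)]
}

#' Diagonal (pq|pq) of the ERI pair matrix
#' @keywords internal
#' @noRd
eri_pair_diag <- function(eri) diag(eri)
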