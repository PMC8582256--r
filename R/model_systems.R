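# Model-Hamiltonian generators: synthetic integral sets with known
# structure (Hubbard chains, Pariser-Parr-Pople pi systems, seeded
# low-rank ERI fixtures) so that every downstream stage can be exercised
# and checked against closed forms without molecular integral data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Hubbard chain integral set
#'
#' One orbital per site, hopping -t between bonded neighbours (ring closure
#' when `periodic`), on-site repulsion (pp|pp) = U and no other two-electron
#' integrals.  The ERI pair matrix is diagonal, hence trivially
#' positive-semidefinite.
#'
#' @param n_sites Number of sites (>= 1).
#' @param t Hopping amplitude (hartree).
#' @param U On-site repulsion (hartree), U >= 0.
#' @param periodic Close the chain into a ring?
#' @param n_elec Electron count; defaults to half filling (one per site).
#' @return An [integral_set()].
#' @export
hubbard_chain <- function(n_sites, t = 1, U = 4, periodic = FALSE,
                          n_elec = n_sites) {
  if (n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  if (U < 0) stop("U must be >= 0", call. = FALSE)
  h <- matrix(0, n_sites, n_sites)
  if (n_sites > 1L) {
    for (p in seq_len(n_sites - 1L)) {
      h[p, p + 1L] <- h[p + 1L, p] <- -t
    }
    if (periodic && n_sites > 2L) h[1L, n_sites] <- h[n_sites, 1L] <- -t
  }
  np <- pair_dim(n_sites)
  m <- matrix(0, np, np)
  dpi <- pair_index(seq_len(n_sites), seq_len(n_sites))
  for (p in seq_len(n_sites)) m[dpi[p], dpi[p]] <- U
  integral_set(h_core = h, eri = as_eri_pair(m, n_sites), n_elec = n_elec)
}

#' Pariser-Parr-Pople pi-system integral set
#'
#' One p-pi orbital per site with hopping -t on bonds and Ohno-interpolated
#' two-center repulsion (pp|qq) = U / sqrt(1 + (U r_pq)^2) in atomic units
#' (r in bohr, e^2 = 1), which reduces to U at r = 0 and to the Coulomb
#' tail 1/r at large separation.  All other ERI classes vanish.  The
#' one-electron diagonal carries the attraction to the unit-charge cores
#' of the other sites, `h_pp = -sum_{q != p} V_pq`, and the core-core
#' repulsion `sum_{p<q} V_pq` enters `e_nuc`, so total energies are on the
#' usual molecular scale.
#'
#' @param coords Numeric matrix of site coordinates in Angstrom (rows are
#'   sites; 2 or 3 columns).
#' @param bonds Two-column integer matrix of bonded site pairs.
#' @param t Hopping amplitude (hartree).
#' @param U On-site repulsion (hartree).
#' @param n_elec Electron count; defaults to one pi electron per site.
#' @return An [integral_set()].
#' @export
ppp_model <- function(coords, bonds, t = 2.4 / 27.211386, U = 11.26 / 27.211386,
                      n_elec = nrow(coords)) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords)) * 1.8897259886  # Angstrom -> bohr
  if (n > 1L && min(d[upper.tri(d)]) < 1e-8) {
    stop("geometry error: coincident sites", call. = FALSE)
  }
  h <- matrix(0, n, n)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  for (b in seq_len(nrow(bonds))) {
    p <- bonds[b, 1L]; q <- bonds[b, 2L]
    h[p, q] <- h[q, p] <- -t
  }
  v <- ohno_repulsion(d, U)
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("model error: site-repulsion matrix is not positive-semidefinite",
         call. = FALSE)
  }
  off <- v
  diag(off) <- 0
  diag(h) <- diag(h) - rowSums(off)
  e_nuc <- sum(off[upper.tri(off)])
  np <- pair_dim(n)
  m <- matrix(0, np, np)
  dpi <- pair_index(seq_len(n), seq_len(n))
  m[dpi, dpi] <- v
  integral_set(h_core = h, eri = as_eri_pair(m, n), n_elec = n_elec,
               e_nuc = e_nuc)
}

#' Ohno two-center repulsion formula
#'
#' @param r Distance (bohr), scalar or matrix.
#' @param U On-site repulsion (hartree).
#' @return U / sqrt(1 + (U r)^2) in hartree.
#' @export
ohno_repulsion <- function(r, U) U / sqrt(1 + (U * r)^2)

#' Regular-polygon PPP ring (benzene-like fixture)
#'
#' @param n_sites Ring size.
#' @param bond_length Edge length in Angstrom (default the aromatic CC
#'   bond, 1.4 A).
#' @param ... Passed to [ppp_model()].
#' @export
ppp_ring <- function(n_sites, bond_length = 1.4, ...) {
  theta <- 2 * pi * (seq_len(n_sites) - 1L) / n_sites
  radius <- bond_length / (2 * sin(pi / n_sites))
  coords <- cbind(radius * cos(theta), radius * sin(theta))
  bonds <- cbind(seq_len(n_sites), c(seq_len(n_sites)[-1L], 1L))
  ppp_model(coords, bonds, ...)
}

#' Seeded random low-rank ERI fixture
#'
#' Draws `rank` symmetric matrices A^m and sets
#' (pq|rs) = sum_m A^m_pq A^m_rs, which is positive-semidefinite with full
#' 8-fold symmetry and pair-matrix rank <= `rank` by construction.  The
#' one-electron matrix is random symmetric.  Identical arguments and seed
#' reproduce the set bitwise.
#'
#' @param n_orb Orbital count.
#' @param rank Number of generating matrices (>= 1).
#' @param seed RNG seed (integer); part of the fixture's identity.
#' @param scale Overall magnitude of the generators.
#' @param decay Per-generator geometric damping in (0, 1]; values below 1
#'   give the pair matrix a decaying spectrum so that threshold truncation
#'   retains progressively fewer vectors.
#' @param n_elec Electron count stored on the set.
#' @return An [integral_set()].
#' @export
random_lowrank_eri <- function(n_orb, rank, seed, scale = 1, decay = 1,
                               n_elec = 2L) {
  if (rank < 1L) stop("rank must be >= 1", call. = FALSE)
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]", call. = FALSE)
  with_seed(seed, {
    np <- pair_dim(n_orb)
    a <- matrix(0, np, rank)
    for (m in seq_len(rank)) {
      x <- matrix(stats::rnorm(n_orb * n_orb, sd = scale * decay^(m - 1L)),
                  n_orb, n_orb)
      a[, m] <- pack_sym((x + t(x)) / 2)
    }
    m2 <- tcrossprod(a)
    hx <- matrix(stats::rnorm(n_orb * n_orb, sd = scale), n_orb, n_orb)
    integral_set(h_core = (hx + t(hx)) / 2, eri = as_eri_pair(m2, n_orb),
                 n_elec = n_elec)
  })
}
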