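# Determinant-based full CI in the active space.
#
# Sz-conserving determinants are products of alpha and beta occupation
# strings in lexical order; CI vectors are stored as n_alpha-string by
# n_beta-string matrices.  The direct sigma build is string-driven through
# precomputed sparse single-excitation operators E^sigma_uv, never forming
# the dense Hamiltonian.

#' Dimension of a determinant space without materializing it
#'
#' @param n_act Active orbital count.
#' @param n_alpha,n_beta Active alpha/beta electron counts.
#' @return `choose(n_act, n_alpha) * choose(n_act, n_beta)` as a double
#'   (may exceed integer range, e.g. CAS(14,14)).
#' @export
det_space_dimension <- function(n_act, n_alpha, n_beta) {
  choose(n_act, n_alpha) * choose(n_act, n_beta)
}

#' Build a determinant basis for an active space
#'
#' @param n_act Number of active orbitals.
#' @param n_alpha,n_beta Number of active alpha/beta electrons
#'   (0 <= n <= n_act).
#' @return An object of class `det_basis` holding the lexically ordered
#'   alpha/beta occupation strings, their addressing maps and the space
#'   dimension.  Excitation operator tables are built lazily by
#'   [excitation_tables()].
#' @export
build_determinant_basis <- function(n_act, n_alpha, n_beta) {
  n_act <- as.integer(n_act)
  n_alpha <- as.integer(n_alpha)
  n_beta <- as.integer(n_beta)
  if (n_alpha < 0L || n_beta < 0L || n_alpha > n_act || n_beta > n_act) {
    stop("impossible electron counts: ", n_alpha, " alpha / ", n_beta,
         " beta in ", n_act, " orbitals", call. = FALSE)
  }
  strings <- function(k) {
    if (k == 0L) return(matrix(integer(0), nrow = 0L, ncol = 1L))
    utils::combn(n_act, k)
  }
  sa <- strings(n_alpha)
  sb <- strings(n_beta)
  address <- function(s) {
    keys <- vapply(seq_len(ncol(s)), function(i) string_key(s[, i]),
                   character(1))
    stats::setNames(seq_along(keys), keys)
  }
  structure(
    list(n_act = n_act, n_alpha = n_alpha, n_beta = n_beta,
         strings_a = sa, strings_b = sb,
         n_str_a = ncol(sa), n_str_b = ncol(sb),
         addr_a = address(sa), addr_b = address(sb),
         dim = ncol(sa) * ncol(sb),
         cache = new.env(parent = emptyenv())),
    class = "det_basis")
}

#' @export
print.det_basis <- function(x, ...) {
  cat("Determinant basis: CAS with", x$n_act, "orbitals,",
      x$n_alpha, "alpha +", x$n_beta, "beta electrons;",
      x$dim, "determinants\n")
  invisible(x)
}

# occupation-string hash key ("." for the empty string, which cannot be
# used as a list name)
string_key <- function(occ) {
  if (length(occ) == 0L) "." else paste(occ, collapse = ",")
}

# Sparse matrices of <I'| a^+_u a_v |I> for one spin's strings.
# Returned as a list indexed [[ (v-1)*n_act + u ]].
string_excitation_ops <- function(strings, n_act, addr) {
  n_str <- ncol(strings)
  n_el <- nrow(strings)
  ops <- vector("list", n_act * n_act)
  trip <- lapply(seq_len(n_act * n_act),
                 function(i) list(i = integer(0), j = integer(0),
                                  x = numeric(0)))
  for (col in seq_len(n_str)) {
    occ <- strings[, col]
    for (vpos in seq_len(n_el)) {
      v <- occ[vpos]
      sign_v <- if (vpos %% 2L == 1L) 1 else -1  # (-1)^(vpos-1)
      rest <- occ[-vpos]
      for (u in seq_len(n_act)) {
        if (u != v && u %in% rest) next
        if (u == v) {
          new_occ <- occ
          sgn <- 1
        } else {
          sgn <- sign_v * (-1)^sum(rest < u)
          new_occ <- sort(c(rest, u))
        }
        row <- addr[[string_key(new_occ)]]
        k <- (v - 1L) * n_act + u
        trip[[k]]$i <- c(trip[[k]]$i, row)
        trip[[k]]$j <- c(trip[[k]]$j, col)
        trip[[k]]$x <- c(trip[[k]]$x, sgn)
      }
    }
  }
  for (k in seq_along(ops)) {
    ops[[k]] <- Matrix::sparseMatrix(i = trip[[k]]$i, j = trip[[k]]$j,
                                     x = trip[[k]]$x,
                                     dims = c(n_str, n_str))
  }
  ops
}

#' Excitation operator tables for a determinant basis
#'
#' Builds (and caches on the basis) the sparse representations of the
#' spin-resolved single excitation operators over alpha and beta strings.
#' @param basis A `det_basis`.
#' @return List with elements `alpha` and `beta`; each a list of sparse
#'   matrices indexed by `(v-1)*n_act + u` giving `<I'|a+_u a_v|I>`.
#' @export
excitation_tables <- function(basis) {
  if (!is.null(basis$cache$tables)) return(basis$cache$tables)
  a <- string_excitation_ops(basis$strings_a, basis$n_act, basis$addr_a)
  b <- if (basis$n_alpha == basis$n_beta &&
           identical(dim(basis$strings_a), dim(basis$strings_b))) {
    a
  } else {
    string_excitation_ops(basis$strings_b, basis$n_act, basis$addr_b)
  }
  basis$cache$tables <- list(alpha = a, beta = b)
  basis$cache$tables
}

# Coerce a CI vector to matrix layout (alpha strings x beta strings).
ci_matrix <- function(vec, basis) {
  if (is.matrix(vec)) {
    stopifnot(nrow(vec) == basis$n_str_a, ncol(vec) == basis$n_str_b)
    vec
  } else {
    matrix(vec, basis$n_str_a, basis$n_str_b)
  }
}

#' Apply the spin-traced excitation operator E_uv to a CI vector
#'
#' @param basis A `det_basis`.
#' @param cmat CI vector in matrix layout.
#' @param u,v Active orbital indices.
#' @return Matrix `E_uv |c>`.
#' @export
apply_excitation <- function(basis, cmat, u, v) {
  tabs <- excitation_tables(basis)
  k <- (v - 1L) * basis$n_act + u
  out <- as.matrix(tabs$alpha[[k]] %*% cmat) +
    as.matrix(cmat %*% Matrix::t(tabs$beta[[k]]))
  out
}

# All E_xy |c> at once: array D[, , x, y].
apply_excitation_all <- function(basis, cmat) {
  n <- basis$n_act
  d <- array(0, c(basis$n_str_a, basis$n_str_b, n, n))
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      d[, , x, y] <- apply_excitation(basis, cmat, x, y)
    }
  }
  d
}

#' Direct sigma build: H applied to a CI vector
#'
#' Computes `sigma = H c` for the active-space Hamiltonian
#' `H = sum h_uv E_uv + 1/2 sum (uv|xy) (E_uv E_xy - delta_vx E_uy)`
#' without forming H, via the string excitation tables.
#'
#' @param active_h Symmetric effective one-electron matrix over active
#'   orbitals (hartree).
#' @param active_eri 4-index array (uv|xy) over active orbitals.
#' @param vec CI vector (matrix layout or flat, alpha-major).
#' @param basis A `det_basis`.
#' @return Sigma in the same layout as `vec`.
#' @export
sigma_apply <- function(active_h, active_eri, vec, basis) {
  n <- basis$n_act
  stopifnot(nrow(active_h) == n)
  was_matrix <- is.matrix(vec)
  cmat <- ci_matrix(vec, basis)
  # fold the -1/2 delta_vx E_uy term into the one-electron part
  hp <- active_h
  if (n > 0L) {
    for (u in seq_len(n)) {
      for (y in seq_len(n)) {
        hp[u, y] <- hp[u, y] - 0.5 * sum(active_eri[u, , , y][cbind(seq_len(n), seq_len(n))])
      }
    }
  }
  d <- apply_excitation_all(basis, cmat)
  sig <- matrix(0, basis$n_str_a, basis$n_str_b)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (hp[u, v] != 0) sig <- sig + hp[u, v] * d[, , u, v]
    }
  }
  # two-electron part: sigma2 = sum_uv E_uv G_uv, G_uv = 1/2 sum_xy (uv|xy) D_xy
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      g <- matrix(0, basis$n_str_a, basis$n_str_b)
      for (x in seq_len(n)) {
        for (y in seq_len(n)) {
          w <- active_eri[u, v, x, y]
          if (w != 0) g <- g + w * d[, , x, y]
        }
      }
      if (any(g != 0)) sig <- sig + 0.5 * apply_excitation(basis, g, u, v)
    }
  }
  if (was_matrix) sig else as.numeric(sig)
}

#' Diagonal of the active Hamiltonian
#'
#' Used as the Davidson preconditioner; exact diagonal elements
#' `<I|H|I>` computed per determinant.
#'
#' @inheritParams sigma_apply
#' @return Matrix (alpha strings x beta strings) of diagonal elements.
#' @export
hamiltonian_diagonal <- function(active_h, active_eri, basis) {
  n <- basis$n_act
  na <- basis$n_str_a
  nb <- basis$n_str_b
  out <- matrix(0, na, nb)
  occ_a <- lapply(seq_len(na), function(i) basis$strings_a[, i])
  occ_b <- lapply(seq_len(nb), function(i) basis$strings_b[, i])
  for (ia in seq_len(na)) {
    oa <- occ_a[[ia]]
    for (ib in seq_len(nb)) {
      ob <- occ_b[[ib]]
      e <- sum(active_h[cbind(oa, oa)]) + sum(active_h[cbind(ob, ob)])
      allocc <- c(oa, ob)
      # Coulomb over all pairs of spin orbitals
      if (length(allocc) > 1L) {
        for (i in seq_along(allocc)) {
          for (j in seq_along(allocc)) {
            if (i < j) {
              e <- e + active_eri[allocc[i], allocc[i], allocc[j], allocc[j]]
            }
          }
        }
      }
      # exchange within same spin
      for (occ in list(oa, ob)) {
        if (length(occ) > 1L) {
          pr <- utils::combn(occ, 2L)
          for (k in seq_len(ncol(pr))) {
            e <- e - active_eri[pr[1L, k], pr[2L, k], pr[2L, k], pr[1L, k]]
          }
        }
      }
      out[ia, ib] <- e
    }
  }
  out
}
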