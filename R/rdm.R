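# Active-space reduced density matrices.
#
# Conventions: gamma_uv = <0|E_uv|0>; spin-traced two-body matrix
# Gamma_uvxy = <0|E_uv E_xy - delta_vx E_uy|0>, so that
# E = E_i + sum_uv gamma_uv F^I_uv + 1/2 sum_uvxy Gamma_uvxy (uv|xy).

#' One- and two-body reduced density matrices of a CI vector
#'
#' @param vec Normalized CI vector (matrix layout or flat).
#' @param basis A `det_basis`.
#' @return List of class `rdm_set` with `gamma` (n_act x n_act) and
#'   `Gamma2` (n_act^4 array).
#' @export
one_two_rdm <- function(vec, basis) {
  cmat <- ci_matrix(vec, basis)
  n <- basis$n_act
  d <- apply_excitation_all(basis, cmat)
  gamma <- matrix(0, n, n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) gamma[u, v] <- sum(cmat * d[, , u, v])
  }
  gam2 <- array(0, c(n, n, n, n))
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      for (x in seq_len(n)) {
        for (y in seq_len(n)) {
          val <- sum(d[, , v, u] * d[, , x, y])
          if (v == x) val <- val - gamma[u, y]
          gam2[u, v, x, y] <- val
        }
      }
    }
  }
  structure(list(gamma = (gamma + t(gamma)) / 2, Gamma2 = gam2),
            class = "rdm_set")
}

#' Symmetrized transition reduced density matrices
#'
#' Computes gamma and Gamma2 with the symmetrized bra/ket convention
#' `1/2 (<b|...|k> + <k|...|b>)`, as used by the transition-gradient part
#' of the Hessian-vector products.
#'
#' @param bra,ket CI vectors on the same basis.
#' @param basis A `det_basis`.
#' @return An `rdm_set` with the symmetrized transition matrices.
#' @export
transition_rdms <- function(bra, ket, basis) {
  bmat <- ci_matrix(bra, basis)
  kmat <- ci_matrix(ket, basis)
  n <- basis$n_act
  db <- apply_excitation_all(basis, bmat)
  dk <- apply_excitation_all(basis, kmat)
  gamma <- matrix(0, n, n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      gamma[u, v] <- 0.5 * (sum(bmat * dk[, , u, v]) +
                            sum(kmat * db[, , u, v]))
    }
  }
  gam2 <- array(0, c(n, n, n, n))
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      for (x in seq_len(n)) {
        for (y in seq_len(n)) {
          val <- 0.5 * (sum(db[, , v, u] * dk[, , x, y]) +
                        sum(dk[, , v, u] * db[, , x, y]))
          if (v == x) val <- val - gamma[u, y]
          gam2[u, v, x, y] <- val
        }
      }
    }
  }
  structure(list(gamma = gamma, Gamma2 = gam2), class = "rdm_set")
}

#' Expectation value of S^2 for a CI vector
#'
#' Diagnostic for spin purity; determinants conserve only Sz, so singlet
#' character is monitored rather than enforced.
#'
#' @inheritParams one_two_rdm
#' @return `<c|S^2|c>`.
#' @export
s_squared <- function(vec, basis) {
  cmat <- ci_matrix(vec, basis)
  n <- basis$n_act
  sz <- (basis$n_alpha - basis$n_beta) / 2
  tabs <- excitation_tables(basis)
  # S^2 = S- S+ + Sz(Sz + 1); S+ = sum_u a+_{u,alpha} a_{u,beta}
  acc <- sz * (sz + 1) * sum(cmat^2)
  # <c| S- S+ |c> = |S+ c|^2 computed on the (n_alpha+1, n_beta-1) basis
  if (basis$n_beta >= 1L && basis$n_alpha < n) {
    up <- build_determinant_basis(n, basis$n_alpha + 1L, basis$n_beta - 1L)
    acc_v <- matrix(0, up$n_str_a, up$n_str_b)
    for (u in seq_len(n)) {
      acc_v <- acc_v + raise_spin(basis, up, cmat, u)
    }
    acc <- acc + sum(acc_v^2)
  }
  acc
}

# a+_{u,alpha} a_{u,beta} |c>: moves one electron from beta string to alpha.
raise_spin <- function(basis, up, cmat, u) {
  out <- matrix(0, up$n_str_a, up$n_str_b)
  for (ib in seq_len(basis$n_str_b)) {
    ob <- basis$strings_b[, ib]
    pos <- match(u, ob)
    if (is.na(pos)) next
    sgn_b <- (-1)^(pos - 1L)
    newb <- ob[-pos]
    jb <- up$addr_b[[string_key(newb)]]
    # annihilating from beta passes over all alpha electrons
    sgn_cross <- (-1)^basis$n_alpha
    for (ia in seq_len(basis$n_str_a)) {
      oa <- basis$strings_a[, ia]
      if (u %in% oa) next
      sgn_a <- (-1)^sum(oa < u)
      newa <- sort(c(oa, u))
      ja <- up$addr_a[[string_key(newa)]]
      out[ja, jb] <- out[ja, jb] + sgn_a * sgn_b * sgn_cross * cmat[ia, ib]
    }
  }
  out
}
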