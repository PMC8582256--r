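# Direct Hessian-vector products for the NEO eigenproblem.
#
# The four blocks act on configuration-only and orbital-only trial
# vectors.  Orbital directions enter through one-index-transformed
# integrals: for an antisymmetric generator K every MO-basis quantity
# transforms along d/dt [U(t)^T X U(t)] = [X, K], so each Cholesky vector
# transforms independently as L~ = [L, K] (still symmetric) and every
# transformed Fock-type matrix is assembled per vector from (L, L~) pairs
# by the product rule — the Hessian matrix itself is never formed.

#' One-index-transformed Fock set for an orbital trial vector
#'
#' Builds the transformed inactive Fock, active Fock and Q matrices plus
#' the transformed one-electron matrix and transformed active ERI block,
#' all per Cholesky vector.  Linear in `v_orb`; identically zero at
#' `v_orb = 0`.
#'
#' @param cep A `cep_state` from [cep_context()].
#' @param v_orb Packed orbital trial vector (length `n_rot`), or a full
#'   antisymmetric generator matrix.
#' @return List with `h_t`, `f_inactive_t`, `f_active_t`, `q_t`,
#'   `active_eri_t` and the generator `kmat`.
#' @export
build_transformed_fock <- function(cep, v_orb) {
  spaces <- cep$spaces
  kmat <- if (is.matrix(v_orb)) v_orb else unpack_rotation(spaces, v_orb)
  n <- spaces$n_mo
  act <- spaces$act_idx
  na <- spaces$n_act
  occ <- spaces$int_idx
  gamma <- cep$rdms$gamma
  g2 <- if (na > 0L) matrix(cep$rdms$Gamma2, na * na, na * na) else NULL

  h_t <- cep$h_mo %*% kmat - kmat %*% cep$h_mo
  fi_t <- h_t
  fa_t <- matrix(0, n, n)
  q_t <- matrix(0, na, n)
  eri_t <- if (na > 0L) array(0, c(na, na, na, na)) else
    array(0, c(0, 0, 0, 0))
  for (K in seq_len(cep$mo_chol$n_ch)) {
    l <- cep$mo_chol$l[, , K]
    lt <- l %*% kmat - kmat %*% l
    if (length(occ) > 0L) {
      d_k <- sum(diag(l)[occ])
      dt_k <- sum(diag(lt)[occ])
      locc <- l[, occ, drop = FALSE]
      ltocc <- lt[, occ, drop = FALSE]
      fi_t <- fi_t + 2 * (dt_k * l + d_k * lt) -
        (tcrossprod(ltocc, locc) + tcrossprod(locc, ltocc))
    }
    if (na > 0L) {
      laa <- l[act, act]
      ltaa <- lt[act, act]
      w_k <- sum(gamma * laa)
      wt_k <- sum(gamma * ltaa)
      lact <- l[, act, drop = FALSE]
      ltact <- lt[, act, drop = FALSE]
      fa_t <- fa_t + wt_k * l + w_k * lt -
        0.5 * (ltact %*% gamma %*% t(lact) + lact %*% gamma %*% t(ltact))
      m <- matrix(g2 %*% as.numeric(laa), na, na)
      mt <- matrix(g2 %*% as.numeric(ltaa), na, na)
      q_t <- q_t + mt %*% l[act, , drop = FALSE] +
        m %*% lt[act, , drop = FALSE]
      eri_t <- eri_t +
        array(outer(as.numeric(ltaa), as.numeric(laa)) +
              outer(as.numeric(laa), as.numeric(ltaa)), c(na, na, na, na))
    }
  }
  list(h_t = (h_t + t(h_t)) / 2,
       f_inactive_t = (fi_t + t(fi_t)) / 2,
       f_active_t = (fa_t + t(fa_t)) / 2,
       q_t = q_t, active_eri_t = eri_t, kmat = kmat)
}

#' Configuration-configuration Hessian product
#'
#' `2 P (H - E0) P v_conf` through the direct sigma build.
#'
#' @param cep A `cep_state`.
#' @param v_conf CI-part trial vector (matrix layout or flat).
#' @return CI-part product in matrix layout.
#' @export
hess_cc_apply <- function(cep, v_conf) {
  v <- ci_matrix(v_conf, cep$basis)
  v <- v - sum(cep$c0 * v) * cep$c0
  sig <- sigma_apply(cep$active_h, cep$active_eri, v, cep$basis)
  out <- 2 * (sig - cep$e_active * v)
  out - sum(cep$c0 * out) * cep$c0
}

#' Orbital-part product from a configuration trial vector
#'
#' The transition gradient: the orbital-gradient contraction evaluated
#' with symmetrized transition density matrices between the CEP vector and
#' the projected trial vector.  The inactive-density contribution vanishes
#' because the projected trial vector is orthogonal to the CEP.
#'
#' @param cep A `cep_state`.
#' @param v_conf CI-part trial vector.
#' @return Packed orbital-part product (length `n_rot`).
#' @export
hess_oc_apply <- function(cep, v_conf) {
  spaces <- cep$spaces
  v <- ci_matrix(v_conf, cep$basis)
  v <- v - sum(cep$c0 * v) * cep$c0
  trdm <- transition_rdms(cep$c0, v, cep$basis)
  fa_t <- build_active_fock(cep$mo_chol, trdm$gamma, spaces$act_idx)
  q_t <- build_q_matrix(cep$mo_chol, trdm$Gamma2, spaces$act_idx)
  zero <- matrix(0, spaces$n_mo, spaces$n_mo)
  ft <- generalized_fock(spaces, f_inactive = zero, f_active = fa_t,
                         gamma = trdm$gamma, q = q_t,
                         f_inactive_active = cep$f_inactive)
  4 * pack_rotation(spaces, t(ft) - ft)
}

#' CI-part product from an orbital trial vector
#'
#' Action of the one-index-transformed Hamiltonian on the CEP vector,
#' projected on the orthogonal complement of the CEP: the transformed
#' effective one-electron matrix is the active block of the transformed
#' inactive Fock matrix and the transformed active ERIs come from the
#' (L, L~) product rule.
#'
#' @param cep A `cep_state`.
#' @param v_orb Packed orbital trial vector.
#' @param tf Optional precomputed [build_transformed_fock()] output.
#' @return CI-part product in matrix layout.
#' @export
hess_co_apply <- function(cep, v_orb, tf = NULL) {
  if (is.null(tf)) tf <- build_transformed_fock(cep, v_orb)
  act <- cep$spaces$act_idx
  h_eff_t <- tf$f_inactive_t[act, act, drop = FALSE]
  sig <- sigma_apply(h_eff_t, tf$active_eri_t, cep$c0, cep$basis)
  out <- 2 * sig
  out - sum(cep$c0 * out) * cep$c0
}

#' Orbital-orbital Hessian product
#'
#' Gradient-like contraction of the one-index-transformed Fock matrices
#' plus the commutator term `-1/2 [A, K]` (A the antisymmetric gradient
#' matrix) that renders the map symmetric.
#'
#' @param cep A `cep_state`.
#' @param v_orb Packed orbital trial vector.
#' @param tf Optional precomputed [build_transformed_fock()] output.
#' @return Packed orbital-part product.
#' @export
hess_oo_apply <- function(cep, v_orb, tf = NULL) {
  spaces <- cep$spaces
  if (is.null(tf)) tf <- build_transformed_fock(cep, v_orb)
  ft <- generalized_fock(spaces, tf$f_inactive_t, tf$f_active_t,
                         cep$rdms$gamma, tf$q_t)
  a_t <- t(ft) - ft
  a <- t(cep$f_general) - cep$f_general
  comm <- a %*% tf$kmat - tf$kmat %*% a
  pack_rotation(spaces, 2 * a_t - comm)
}

#' Full Hessian-vector product
#'
#' Combines the four blocks on a trial vector with configuration part
#' `v_conf` and orbital part `v_orb`.
#'
#' @param cep A `cep_state`.
#' @param v_conf CI part (matrix layout or flat); may be NULL/zero.
#' @param v_orb Packed orbital part; may be NULL/zero.
#' @return List with `v_conf` (matrix layout) and `v_orb` (packed).
#' @export
hessian_apply <- function(cep, v_conf = NULL, v_orb = NULL) {
  basis <- cep$basis
  spaces <- cep$spaces
  if (is.null(v_conf)) v_conf <- matrix(0, basis$n_str_a, basis$n_str_b)
  if (is.null(v_orb)) v_orb <- numeric(spaces$n_rot)
  have_c <- any(v_conf != 0)
  have_o <- any(v_orb != 0)
  out_c <- matrix(0, basis$n_str_a, basis$n_str_b)
  out_o <- numeric(spaces$n_rot)
  if (have_c) {
    out_c <- out_c + hess_cc_apply(cep, v_conf)
    out_o <- out_o + hess_oc_apply(cep, v_conf)
  }
  if (have_o) {
    tf <- build_transformed_fock(cep, v_orb)
    out_c <- out_c + hess_co_apply(cep, v_orb, tf)
    out_o <- out_o + hess_oo_apply(cep, v_orb, tf)
  }
  list(v_conf = out_c, v_orb = out_o)
}

#' Approximate orbital-Hessian diagonal preconditioner
#'
#' Fock-difference estimate `2 (n_q - n_p)((F^I + F^A)_pp - (F^I + F^A)_qq)`
#' for the rotation (p, q) with occupations n in {2, gamma_uu, 0},
#' floored at a positive value before use in the Davidson
#' microiterations.
#'
#' @param cep A `cep_state`.
#' @param floor_value Lower bound applied elementwise.
#' @return Length-`n_rot` positive vector.
#' @export
orbital_hessian_diagonal <- function(cep, floor_value = 0.05) {
  spaces <- cep$spaces
  if (spaces$n_rot == 0L) return(numeric(0))
  ft <- diag(cep$f_inactive + cep$f_active)
  occ <- numeric(spaces$n_mo)
  occ[spaces$int_idx] <- 2
  if (spaces$n_act > 0L) occ[spaces$act_idx] <- diag(cep$rdms$gamma)
  pr <- spaces$rotation_pairs
  d <- 2 * (occ[pr[, 2L]] - occ[pr[, 1L]]) * (ft[pr[, 1L]] - ft[pr[, 2L]])
  pmax(d, floor_value)
}
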