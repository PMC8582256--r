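# Cholesky-based Fock-type intermediates and first derivatives: inactive
# and active Fock matrices, the Q matrix, the CASSCF energy, the
# generalized Fock matrix and the packed orbital / projected CI gradients.
#
# All two-electron contractions run vector-by-vector over the MO Cholesky
# factor; every per-vector contribution is independent, so sums over K
# commute.

#' Inactive Fock matrix and inactive energy
#'
#' `F^I = h + sum_i (2 (pq|ii) - (pi|iq))` over the internal orbitals,
#' assembled per Cholesky vector; the inactive energy is
#' `E_i = sum_i (h_ii + F^I_ii) + e_nuc`.
#'
#' @param mo_chol `mo_cholesky` factor in the current MO basis.
#' @param h_mo MO-basis one-electron matrix.
#' @param n_int Number of internal orbitals.
#' @param e_nuc Nuclear repulsion energy added to `E_i`.
#' @return List with `F_inactive` and `E_inactive`.
#' @export
build_inactive_fock <- function(mo_chol, h_mo, n_int, e_nuc = 0) {
  n <- mo_chol$n_mo
  if (n_int > n) stop("n_int exceeds the orbital count", call. = FALSE)
  f <- h_mo
  if (n_int > 0L && mo_chol$n_ch > 0L) {
    occ <- seq_len(n_int)
    for (K in seq_len(mo_chol$n_ch)) {
      l <- mo_chol$l[, , K]
      d_k <- sum(diag(l)[occ])
      locc <- l[, occ, drop = FALSE]
      f <- f + 2 * d_k * l - tcrossprod(locc)
    }
  }
  e_i <- e_nuc + if (n_int > 0L) {
    occ <- seq_len(n_int)
    sum(diag(h_mo)[occ] + diag(f)[occ])
  } else 0
  list(F_inactive = (f + t(f)) / 2, E_inactive = e_i)
}

#' Active Fock matrix
#'
#' `F^A_pq = sum_uv gamma_uv ((pq|uv) - 1/2 (pu|vq))`, per Cholesky vector.
#'
#' @param mo_chol `mo_cholesky` factor.
#' @param gamma Active one-body density matrix.
#' @param act_idx Indices of the active orbitals in the MO basis.
#' @export
build_active_fock <- function(mo_chol, gamma, act_idx) {
  n <- mo_chol$n_mo
  f <- matrix(0, n, n)
  if (length(act_idx) == 0L || mo_chol$n_ch == 0L) return(f)
  if (nrow(gamma) != length(act_idx)) {
    stop("RDM dimension mismatch with the active index set", call. = FALSE)
  }
  for (K in seq_len(mo_chol$n_ch)) {
    l <- mo_chol$l[, , K]
    lact <- l[, act_idx, drop = FALSE]
    w_k <- sum(gamma * l[act_idx, act_idx])
    f <- f + w_k * l - 0.5 * lact %*% gamma %*% t(lact)
  }
  (f + t(f)) / 2
}

#' Q matrix
#'
#' `Q_up = sum_vxy Gamma_uvxy (pv|xy)`, built per Cholesky vector from the
#' active sub-blocks.
#'
#' @param mo_chol `mo_cholesky` factor.
#' @param Gamma2 Active two-body density matrix (4-index array).
#' @param act_idx Active orbital indices.
#' @return `n_act x n_mo` matrix.
#' @export
build_q_matrix <- function(mo_chol, Gamma2, act_idx) {
  n <- mo_chol$n_mo
  na <- length(act_idx)
  q <- matrix(0, na, n)
  if (na == 0L || mo_chol$n_ch == 0L) return(q)
  if (dim(Gamma2)[1L] != na) {
    stop("RDM dimension mismatch with the active index set", call. = FALSE)
  }
  g2 <- matrix(Gamma2, na * na, na * na)  # (uv) x (xy)
  for (K in seq_len(mo_chol$n_ch)) {
    l <- mo_chol$l[, , K]
    m <- matrix(g2 %*% as.numeric(l[act_idx, act_idx]), na, na)  # M_uv
    q <- q + m %*% l[act_idx, , drop = FALSE]
  }
  q
}

#' CASSCF energy from density matrices
#'
#' `E = E_i + sum_uv gamma_uv F^I_uv + 1/2 sum Gamma_uvxy (uv|xy)`.
#'
#' @param f_inactive Inactive Fock matrix (MO basis).
#' @param gamma,Gamma2 Active RDMs.
#' @param active_eri Active-block ERI array (uv|xy).
#' @param e_inactive Inactive energy `E_i` (includes e_nuc).
#' @param act_idx Active orbital indices.
#' @export
casscf_energy <- function(f_inactive, gamma, Gamma2, active_eri, e_inactive,
                          act_idx) {
  if (length(act_idx) == 0L) return(e_inactive)
  e_inactive + sum(gamma * f_inactive[act_idx, act_idx]) +
    0.5 * sum(Gamma2 * active_eri)
}

#' Generalized Fock matrix
#'
#' Rows by orbital class: `F_iq = 2 (F^I + F^A)_qi` for internal i,
#' `F_uq = sum_v gamma_uv F^I_qv + Q_uq` for active u, zero for external
#' rows.  The same contraction applies to one-index-transformed or
#' transition-density inputs.
#'
#' @param spaces An `orbital_space`.
#' @param f_inactive,f_active MO Fock matrices (the inactive-row
#'   contribution uses their sum).
#' @param gamma Active 1-RDM.
#' @param q Q matrix (`n_act x n_mo`).
#' @param f_inactive_active Matrix contracted with gamma on active rows;
#'   defaults to `f_inactive` (differs for transition-density builds where
#'   the h/F^I term drops out).
#' @return `n_mo x n_mo` generalized Fock matrix.
#' @export
generalized_fock <- function(spaces, f_inactive, f_active, gamma, q,
                             f_inactive_active = f_inactive) {
  n <- spaces$n_mo
  f <- matrix(0, n, n)
  if (spaces$n_int > 0L) {
    tot <- f_inactive + f_active
    f[spaces$int_idx, ] <- 2 * t(tot[, spaces$int_idx, drop = FALSE])
  }
  if (spaces$n_act > 0L) {
    f[spaces$act_idx, ] <-
      gamma %*% t(f_inactive_active[, spaces$act_idx, drop = FALSE]) + q
  }
  f
}

#' Packed orbital gradient
#'
#' `g_pq = 2 (F_pq - F_qp)` over the nonredundant rotation pairs; the
#' unpacked matrix is antisymmetric by construction.
#'
#' @param fgen Generalized Fock matrix.
#' @param spaces An `orbital_space`.
#' @return Numeric vector of length `n_rot`.
#' @export
orbital_gradient <- function(fgen, spaces) {
  # sign fixed by the finite-difference oracle for C <- C exp(K)
  a <- t(fgen) - fgen
  2 * pack_rotation(spaces, a)
}

#' Projected CI gradient
#'
#' `g_ci = 2 P (H - E) |0>` with `P = 1 - |0><0|`; vanishes iff the CEP
#' vector is an eigenvector of the active Hamiltonian.
#'
#' @param active_h Effective one-electron active matrix (inactive Fock
#'   active block).
#' @param active_eri Active ERI array.
#' @param c0 Normalized CEP CI vector (matrix layout).
#' @param basis A `det_basis`.
#' @return List with `g_ci` (matrix layout) and `e_active`
#'   (`<0|H_act|0>`).
#' @export
ci_gradient <- function(active_h, active_eri, c0, basis) {
  sig <- sigma_apply(active_h, active_eri, c0, basis)
  e_act <- sum(c0 * sig)
  resid <- sig - e_act * c0
  g <- 2 * (resid - sum(c0 * resid) * c0)
  list(g_ci = g, e_active = e_act)
}

#' Assemble the full state at a current expansion point
#'
#' Performs the per-macroiteration work of the optimizer: AO-to-MO
#' transformation of the Cholesky vectors, inactive/active Fock and Q
#' builds, CI solution (or adoption of a supplied CI vector), reduced
#' density matrices, total energy and both gradients.
#'
#' @param integrals An [integral_set()].
#' @param spaces An `orbital_space` for the current coefficients.
#' @param factor_ao AO-basis `cholesky_factor` of the ERIs.
#' @param basis `det_basis` of the active space.
#' @param ci Either `NULL` (solve the active CI problem by Davidson) or a
#'   CI vector to freeze as the CEP (matrix layout; used by derivative
#'   checks and by warm starts).
#' @param ci_guess Optional Davidson starting vector when `ci` is NULL.
#' @param ci_tol Davidson residual tolerance for the CEP solve.
#' @return An object of class `cep_state` with fields used throughout the
#'   Hessian and NEO layers: MO integrals, Cholesky factor, Fock set,
#'   RDMs, energy and gradients.
#' @export
cep_context <- function(integrals, spaces, factor_ao, basis, ci = NULL,
                        ci_guess = NULL, ci_tol = 1e-10) {
  c_mo <- spaces$mo_coeff
  h_mo <- crossprod(c_mo, integrals$h_core %*% c_mo)
  h_mo <- (h_mo + t(h_mo)) / 2
  mo_chol <- cd_ao_to_mo(factor_ao, c_mo, integrals$overlap)
  fi <- build_inactive_fock(mo_chol, h_mo, spaces$n_int, integrals$e_nuc)
  act <- spaces$act_idx
  active_eri <- if (spaces$n_act > 0L) mo_eri_block(mo_chol, act) else
    array(0, c(0, 0, 0, 0))
  active_h <- fi$F_inactive[act, act, drop = FALSE]
  ci_iterations <- 0L
  if (is.null(ci)) {
    sol <- davidson_ground_state(active_h, active_eri, basis,
                                 guess = ci_guess, tol = ci_tol)
    c0 <- sol$vector
    ci_iterations <- sol$iterations
  } else {
    c0 <- ci_matrix(ci, basis)
    c0 <- c0 / sqrt(sum(c0^2))
  }
  rdms <- one_two_rdm(c0, basis)
  fa <- build_active_fock(mo_chol, rdms$gamma, act)
  q <- build_q_matrix(mo_chol, rdms$Gamma2, act)
  fgen <- generalized_fock(spaces, fi$F_inactive, fa, rdms$gamma, q)
  g_orb <- orbital_gradient(fgen, spaces)
  cig <- ci_gradient(active_h, active_eri, c0, basis)
  e_total <- casscf_energy(fi$F_inactive, rdms$gamma, rdms$Gamma2,
                           active_eri, fi$E_inactive, act)
  structure(
    list(integrals = integrals, spaces = spaces, basis = basis,
         factor_ao = factor_ao, mo_chol = mo_chol, h_mo = h_mo,
         f_inactive = fi$F_inactive, e_inactive = fi$E_inactive,
         f_active = fa, q_matrix = q, f_general = fgen,
         active_h = active_h, active_eri = active_eri,
         c0 = c0, rdms = rdms,
         e_total = e_total, e_active = cig$e_active,
         g_orb = g_orb, g_ci = cig$g_ci,
         ci_iterations = ci_iterations),
    class = "cep_state")
}

#' @export
print.cep_state <- function(x, ...) {
  cat("CEP state: E =", format(x$e_total, digits = 12),
      " RMS g_orb =", format(rms_norm(x$g_orb), digits = 3),
      " RMS g_ci =", format(rms_norm(as.numeric(x$g_ci)), digits = 3), "\n")
  invisible(x)
}
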