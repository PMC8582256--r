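# Shared fixtures and independent oracles for the test suite.
#
# Oracles are deliberately separate code paths from the implementation:
# dense 4-index transforms by reshape/aperm, Fock matrices contracted
# directly from the dense ERI array, finite differences of the energy, and
# brute-force orbital optimization through stats::optim on dense FCI.

# dense 4-index MO transform (reshape/aperm route)
transform_eri_dense <- function(g, c_mo) {
  n <- nrow(c_mo)
  for (rep in 1:4) {
    g <- array(apply(matrix(g, n, n^3), 2,
                     function(col) crossprod(c_mo, col)), c(n, n, n, n))
    g <- aperm(g, c(2, 3, 4, 1))
  }
  g
}

# dense one-index transform: directional derivative of the MO ERIs along
# the antisymmetric generator k
one_index_eri_dense <- function(gmo, k) {
  n <- dim(gmo)[1]
  gt <- array(0, dim(gmo))
  for (p in 1:n) for (q in 1:n) for (r in 1:n) for (s in 1:n) {
    gt[p, q, r, s] <- sum(k[, p] * gmo[, q, r, s]) +
      sum(k[, q] * gmo[p, , r, s]) +
      sum(k[, r] * gmo[p, q, , s]) +
      sum(k[, s] * gmo[p, q, r, ])
  }
  gt
}

# dense-ERI Fock matrices (independent of the Cholesky builds)
dense_inactive_fock <- function(hmo, gmo, n_int) {
  f <- hmo
  for (i in seq_len(n_int)) f <- f + 2 * gmo[, , i, i] - gmo[, i, i, ]
  f
}
dense_active_fock <- function(gmo, gamma, act) {
  n <- dim(gmo)[1]
  f <- matrix(0, n, n)
  na <- length(act)
  for (u in seq_len(na)) for (v in seq_len(na)) {
    f <- f + gamma[u, v] *
      (gmo[, , act[u], act[v]] - 0.5 * gmo[, act[u], act[v], ])
  }
  f
}
dense_q_matrix <- function(gmo, Gamma2, act) {
  n <- dim(gmo)[1]
  na <- length(act)
  q <- matrix(0, na, n)
  for (u in seq_len(na)) for (p in seq_len(n)) {
    s <- 0
    for (v in seq_len(na)) for (x in seq_len(na)) for (y in seq_len(na)) {
      s <- s + Gamma2[u, v, x, y] * gmo[p, act[v], act[x], act[y]]
    }
    q[u, p] <- s
  }
  q
}

# total CASSCF energy at rotated orbitals with CI solved by dense
# diagonalization (independent of the NEO machinery)
dense_cas_energy <- function(ints, spaces, kappa = NULL, basis) {
  sp <- if (is.null(kappa)) spaces else rotate_orbitals(spaces, kappa)
  c_mo <- sp$mo_coeff
  gmo <- transform_eri_dense(eri_array(ints$eri), c_mo)
  hmo <- crossprod(c_mo, ints$h_core %*% c_mo)
  fi <- dense_inactive_fock(hmo, gmo, sp$n_int)
  e_i <- sum(diag(hmo)[sp$int_idx] + diag(fi)[sp$int_idx]) + ints$e_nuc
  act <- sp$act_idx
  hd <- dense_active_hamiltonian(fi[act, act, drop = FALSE],
                                 gmo[act, act, act, act, drop = FALSE],
                                 basis)
  min(eigen(hd, symmetric = TRUE)$values) + e_i
}

# energy at a displaced point with the CI vector held fixed (for FD of the
# orbital gradient / Hessian); uses the package energy assembly but the
# differentiation itself is the oracle
cep_energy_at <- function(ints, spaces, factor, basis, c0, kappa,
                          delta_c = NULL) {
  c0v <- as.numeric(c0)
  ci <- if (is.null(delta_c)) c0 else {
    y <- as.numeric(delta_c)
    y <- y - sum(c0v * y) * c0v
    matrix((c0v + y) / sqrt(1 + sum(y^2)), nrow(c0), ncol(c0))
  }
  sp <- rotate_orbitals(spaces, kappa)
  cep_context(ints, sp, factor, basis, ci = ci)$e_total
}

# standard small fixtures
fix_hubbard4 <- function() {
  ints <- hubbard_chain(4, t = 1, U = 4, n_elec = 4)
  factor <- cd_decompose(ints$eri, 0)
  spaces <- orbital_space(core_guess(ints), 1, 2)
  basis <- build_determinant_basis(2, 1, 1)
  list(ints = ints, factor = factor, spaces = spaces, basis = basis)
}

fix_ppp_chain6 <- function() {
  x <- seq(0, by = 1.4, length.out = 6)
  coords <- cbind(x, 0.2 * (-1)^(1:6))
  ints <- ppp_model(coords, cbind(1:5, 2:6))
  factor <- cd_decompose(ints$eri, 0)
  spaces <- orbital_space(core_guess(ints), 1, 4)
  basis <- build_determinant_basis(4, 2, 2)
  list(ints = ints, factor = factor, spaces = spaces, basis = basis)
}

# orthogonal exponential of an antisymmetric matrix (test-local copy)
expm_antisym_test <- function(k) {
  if (max(abs(k)) == 0) return(diag(nrow(k)))
  e <- eigen(1i * k, symmetric = TRUE)
  Re(e$vectors %*% (exp(-1i * e$values) * Conj(t(e$vectors))))
}

# core-Hamiltonian guess orbitals (test-local copy)
core_guess <- function(ints) {
  s <- ints$overlap
  e_s <- eigen(s, symmetric = TRUE)
  x <- e_s$vectors %*% (t(e_s$vectors) / sqrt(e_s$values))
  ho <- crossprod(x, ints$h_core %*% x)
  e <- eigen((ho + t(ho)) / 2, symmetric = TRUE)
  x %*% e$vectors[, order(e$values)]
}

# generic non-symmetric CEP for Hessian oracle tests: randomly rotated
# orbitals and a perturbed CI vector, under a fixed seed
generic_cep <- function(fix, seed = 42, rot_sd = 0.2, ci_sd = 0.1) {
  set.seed(seed)
  sp <- rotate_orbitals(fix$spaces, rnorm(fix$spaces$n_rot, sd = rot_sd))
  cep0 <- cep_context(fix$ints, sp, fix$factor, fix$basis)
  cp <- cep0$c0 + ci_sd * matrix(rnorm(fix$basis$dim),
                                 fix$basis$n_str_a, fix$basis$n_str_b)
  cep_context(fix$ints, sp, fix$factor, fix$basis,
              ci = cp / sqrt(sum(cp^2)))
}

# dense bordered L(alpha) assembled column by column from l_alpha_apply
dense_l_alpha <- function(cep, alpha) {
  nd <- cep$basis$dim
  nr <- cep$spaces$n_rot
  dim <- 1L + nd + nr
  l <- matrix(0, dim, dim)
  for (j in seq_len(dim)) {
    v_c <- numeric(nd)
    v_o <- numeric(nr)
    if (j > 1L && j <= 1L + nd) v_c[j - 1L] <- 1
    if (j > 1L + nd) v_o[j - 1L - nd] <- 1
    out <- l_alpha_apply(cep, alpha, list(
      border = as.numeric(j == 1L),
      v_conf = matrix(v_c, cep$basis$n_str_a, cep$basis$n_str_b),
      v_orb = v_o))
    l[, j] <- c(out$border, as.numeric(out$v_conf), out$v_orb)
  }
  (l + t(l)) / 2
}
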