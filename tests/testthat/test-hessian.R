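# Hessian-vector products: linearity, dense one-index-transform oracles,
# adjoint consistency, finite differences of the energy and the dense
# double-FD Hessian.

test_that("transformed Fock set vanishes at v_orb = 0 and is linear", {
  fix <- fix_ppp_chain6()
  cep <- generic_cep(fix, seed = 101)
  nr <- fix$spaces$n_rot
  tf0 <- build_transformed_fock(cep, numeric(nr))
  expect_equal(max(abs(tf0$f_inactive_t)), 0)
  expect_equal(max(abs(tf0$f_active_t)), 0)
  expect_equal(max(abs(tf0$q_t)), 0)
  set.seed(102)
  v1 <- rnorm(nr); v2 <- rnorm(nr)
  t1 <- build_transformed_fock(cep, v1)
  t2 <- build_transformed_fock(cep, v2)
  t12 <- build_transformed_fock(cep, 2 * v1 - 0.5 * v2)
  for (fld in c("h_t", "f_inactive_t", "f_active_t", "q_t",
                "active_eri_t")) {
    expect_lt(max(abs(t12[[fld]] - (2 * t1[[fld]] - 0.5 * t2[[fld]]))),
              1e-11)
  }
})

test_that("transformed matrices equal the dense one-index-transform oracle", {
  fix <- fix_ppp_chain6()
  cep <- generic_cep(fix, seed = 103)
  set.seed(104)
  v <- rnorm(fix$spaces$n_rot)
  tf <- build_transformed_fock(cep, v)
  c_mo <- cep$spaces$mo_coeff
  gmo <- transform_eri_dense(eri_array(fix$ints$eri), c_mo)
  hmo <- crossprod(c_mo, fix$ints$h_core %*% c_mo)
  k <- unpack_rotation(cep$spaces, v)
  gt <- one_index_eri_dense(gmo, k)
  ht <- t(k) %*% hmo + hmo %*% k
  expect_lt(max(abs(ht - tf$h_t)), 1e-9)
  # transformed inactive Fock from transformed dense integrals
  n_int <- cep$spaces$n_int
  fit <- ht
  for (i in seq_len(n_int)) fit <- fit + 2 * gt[, , i, i] - gt[, i, i, ]
  expect_lt(max(abs(fit - tf$f_inactive_t)), 1e-9)
  # transformed Q via the naive dense pathway
  act <- cep$spaces$act_idx
  qt_dense <- dense_q_matrix(gt, cep$rdms$Gamma2, act)
  expect_lt(max(abs(qt_dense - tf$q_t)), 1e-9)
  # transformed active ERI block
  expect_lt(max(abs(gt[act, act, act, act] - tf$active_eri_t)), 1e-10)
})

test_that("the four blocks match the dense double-FD Hessian", {
  fix <- fix_hubbard4()
  cep <- generic_cep(fix, seed = 105, rot_sd = 0.15, ci_sd = 0.1)
  nd <- fix$basis$dim
  nr <- fix$spaces$n_rot
  dim_tot <- nd + nr
  c0 <- as.numeric(cep$c0)
  e_x <- function(x) {
    cep_energy_at(fix$ints, cep$spaces, fix$factor, fix$basis, cep$c0,
                  kappa = x[nd + seq_len(nr)], delta_c = x[seq_len(nd)])
  }
  h <- 1e-4
  hfd <- matrix(0, dim_tot, dim_tot)
  for (i in seq_len(dim_tot)) {
    for (j in seq_len(i)) {
      ei <- replace(numeric(dim_tot), i, h)
      ej <- replace(numeric(dim_tot), j, h)
      hfd[i, j] <- hfd[j, i] <-
        (e_x(ei + ej) - e_x(ei - ej) - e_x(ej - ei) + e_x(-ei - ej)) /
        (4 * h^2)
    }
  }
  g_an <- matrix(0, dim_tot, dim_tot)
  for (j in seq_len(dim_tot)) {
    v_c <- numeric(nd); v_o <- numeric(nr)
    if (j <= nd) v_c[j] <- 1 else v_o[j - nd] <- 1
    hh <- hessian_apply(cep, matrix(v_c, fix$basis$n_str_a,
                                    fix$basis$n_str_b), v_o)
    g_an[, j] <- c(as.numeric(hh$v_conf), hh$v_orb)
  }
  # projector null space: compare on the complement of the CEP direction
  expect_lt(max(abs(g_an - t(g_an))), 1e-10)
  proj <- diag(dim_tot)
  proj[seq_len(nd), seq_len(nd)] <- diag(nd) - tcrossprod(c0)
  expect_lt(max(abs(proj %*% (g_an - hfd) %*% proj)), 1e-5)
})

test_that("hess_cc annihilates the CEP direction and is symmetric", {
  fix <- fix_ppp_chain6()
  cep <- generic_cep(fix, seed = 106)
  out <- hess_cc_apply(cep, cep$c0)
  expect_lt(max(abs(out)), 1e-12)
  set.seed(107)
  v <- matrix(rnorm(fix$basis$dim), fix$basis$n_str_a, fix$basis$n_str_b)
  w <- matrix(rnorm(fix$basis$dim), fix$basis$n_str_a, fix$basis$n_str_b)
  expect_equal(sum(w * hess_cc_apply(cep, v)),
               sum(v * hess_cc_apply(cep, w)), tolerance = 1e-10)
  expect_lt(abs(sum(cep$c0 * hess_cc_apply(cep, v))), 1e-11)
})

test_that("configuration-orbital blocks are mutually adjoint", {
  for (fix in list(fix_hubbard4(), fix_ppp_chain6())) {
    cep <- generic_cep(fix, seed = 108)
    set.seed(109)
    for (k in 1:4) {
      v_c <- matrix(rnorm(fix$basis$dim), fix$basis$n_str_a,
                    fix$basis$n_str_b)
      v_o <- rnorm(fix$spaces$n_rot)
      lhs <- sum(v_o * hess_oc_apply(cep, v_c))
      rhs <- sum(v_c * hess_co_apply(cep, v_o))
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  }
})

test_that("directional second derivatives match the full Hessian map", {
  fix <- fix_ppp_chain6()
  cep <- generic_cep(fix, seed = 110)
  nd <- fix$basis$dim
  nr <- fix$spaces$n_rot
  c0 <- as.numeric(cep$c0)
  set.seed(111)
  h <- 1e-4
  for (k in 1:3) {
    v_c <- rnorm(nd); v_c <- v_c - sum(c0 * v_c) * c0
    v_o <- rnorm(nr)
    f <- function(t) {
      cep_energy_at(fix$ints, cep$spaces, fix$factor, fix$basis, cep$c0,
                    kappa = t * v_o, delta_c = t * v_c)
    }
    d2 <- (f(h) - 2 * f(0) + f(-h)) / h^2
    hh <- hessian_apply(cep, matrix(v_c, fix$basis$n_str_a,
                                    fix$basis$n_str_b), v_o)
    an <- sum(v_c * as.numeric(hh$v_conf)) + sum(v_o * hh$v_orb)
    expect_equal(d2, an, tolerance = 1e-5)
  }
})

test_that("the orbital-Hessian diagonal is a useful preconditioner", {
  fix <- fix_ppp_chain6()
  res <- run_casscf(fix$ints, n_act = 4, n_elec_act = 4, guess = "core",
                    cd_threshold = 0)
  cep <- res$cep
  d_approx <- orbital_hessian_diagonal(cep, floor_value = -1e9)
  nr <- cep$spaces$n_rot
  d_exact <- vapply(seq_len(nr), function(i) {
    hess_oo_apply(cep, replace(numeric(nr), i, 1))[i]
  }, numeric(1))
  # at the converged point the exact diagonal is positive and the
  # Fock-difference estimate shares its sign pattern
  expect_true(all(d_exact > 0))
  expect_true(all(d_approx * d_exact > 0))
  # core-virtual rotations dominate the diagonal
  pr <- cep$spaces$rotation_pairs
  core_virt <- pr[, 2] %in% cep$spaces$int_idx &
    pr[, 1] %in% cep$spaces$ext_idx
  expect_gt(min(d_exact[core_virt]), stats::median(d_exact))
})
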