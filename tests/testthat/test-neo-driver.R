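# NEO layer: bordered operator, split-Davidson microiterations, step
# extraction, alpha control, Fletcher policy, exponential map and the full
# macroiteration driver.

test_that("L(alpha) matches its dense assembly and decouples at g = 0", {
  fix <- fix_hubbard4()
  cep <- generic_cep(fix, seed = 201)
  l <- dense_l_alpha(cep, 1.3)
  expect_lt(max(abs(l - t(l))), 1e-12)
  # linearity of the operator
  set.seed(202)
  nd <- fix$basis$dim; nr <- fix$spaces$n_rot
  t1 <- list(border = rnorm(1),
             v_conf = matrix(rnorm(nd), fix$basis$n_str_a),
             v_orb = rnorm(nr))
  t2 <- list(border = rnorm(1),
             v_conf = matrix(rnorm(nd), fix$basis$n_str_a),
             v_orb = rnorm(nr))
  o1 <- l_alpha_apply(cep, 1.3, t1)
  o2 <- l_alpha_apply(cep, 1.3, t2)
  o12 <- l_alpha_apply(cep, 1.3, list(
    border = 2 * t1$border - t2$border,
    v_conf = 2 * t1$v_conf - t2$v_conf,
    v_orb = 2 * t1$v_orb - t2$v_orb))
  expect_lt(abs(o12$border - (2 * o1$border - o2$border)), 1e-11)
  expect_lt(max(abs(o12$v_conf - (2 * o1$v_conf - o2$v_conf))), 1e-11)
  expect_lt(max(abs(o12$v_orb - (2 * o1$v_orb - o2$v_orb))), 1e-11)
  # converged CEP (g = 0): lowest eigenvalue of L is min(0, lowest of G)
  res <- run_casscf(fix$ints, 2, 2, guess = "core", cd_threshold = 0)
  l0 <- dense_l_alpha(res$cep, 1)
  ev_l <- eigen(l0, symmetric = TRUE, only.values = TRUE)$values
  ev_g <- eigen(l0[-1, -1], symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev_l), min(0, min(ev_g)), tolerance = 1e-9)
})

test_that("split-Davidson matches dense diagonalization of L(alpha)", {
  for (fix in list(fix_hubbard4(), fix_ppp_chain6())) {
    cep <- generic_cep(fix, seed = 203)
    for (alpha in c(1, 2.5)) {
      l <- dense_l_alpha(cep, alpha)
      ev <- eigen(l, symmetric = TRUE)
      i <- which.min(ev$values)
      mic <- neo_micro(cep, tol_micro = 1e-11, alpha = alpha)
      expect_equal(mic$lambda, ev$values[i], tolerance = 1e-9)
      st <- extract_step(ev$vectors[, i], alpha, cep)
      expect_lt(max(abs(st$kappa - mic$kappa)), 1e-8)
      expect_lt(max(abs(st$delta_c - mic$delta_c)), 1e-8)
    }
  }
})

test_that("with no orbital freedom the micro solve is plain Davidson", {
  x <- random_lowrank_eri(4, 8, seed = 204, n_elec = 4)
  spaces <- orbital_space(diag(4), 0L, 4L)
  basis <- build_determinant_basis(4, 2, 2)
  factor <- cd_decompose(x$eri, 0)
  set.seed(205)
  v <- matrix(rnorm(basis$dim), basis$n_str_a, basis$n_str_b)
  cep <- cep_context(x, spaces, factor, basis, ci = v / sqrt(sum(v^2)))
  mic <- neo_micro(cep, tol_micro = 1e-10, alpha = 1)
  l <- dense_l_alpha(cep, 1)
  expect_equal(mic$lambda, min(eigen(l, symmetric = TRUE)$values),
               tolerance = 1e-9)
  expect_length(mic$kappa, 0)
})

test_that("the CI part of the step is orthogonal to the CEP", {
  fix <- fix_ppp_chain6()
  cep <- generic_cep(fix, seed = 206)
  mic <- neo_micro(cep, tol_micro = 1e-10, r_t = 0.3)
  expect_lt(abs(sum(cep$c0 * mic$delta_c)), 1e-10)
})

test_that("the 1-D bordered model reproduces Newton and alpha closed forms", {
  # scalar g, scalar positive G: L(a) = [[0, a g], [a g, G]]
  g <- 0.3
  big_g <- 2.0
  step_1d <- function(alpha) {
    lam <- (big_g - sqrt(big_g^2 + 4 * alpha^2 * g^2)) / 2
    -g / (big_g - lam)  # body/(alpha*border) in closed form
  }
  # alpha -> 0+ recovers the Newton step -g/G; alpha = 1 is level-shifted
  expect_equal(step_1d(1e-8), -g / big_g, tolerance = 1e-8)
  # solve_alpha on the closed-form norm map
  r_t <- 0.05
  a <- solve_alpha(function(al) abs(step_1d(al)), r_t)
  expect_equal(abs(step_1d(a)), r_t, tolerance = 1e-3)
  # analytic inversion: |step| = g/(G - lam(a)); lam from the quadratic
  lam_target <- big_g - g / r_t
  a_exact <- sqrt(lam_target^2 - lam_target * big_g) / g
  expect_equal(a, a_exact, tolerance = 2e-3 * a_exact)
  # huge trust radius: alpha stays at its minimum
  expect_equal(solve_alpha(function(al) abs(step_1d(al)), 10), 1)
})

test_that("step norm decreases monotonically in alpha and obeys R_t", {
  fix <- fix_ppp_chain6()
  cep <- generic_cep(fix, seed = 207)
  norms <- vapply(c(1, 3, 10, 30, 100, 1000), function(a) {
    neo_micro(cep, tol_micro = 1e-9, alpha = a)$step_norm
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  for (r_t in c(1e-3, 1e-2, 0.1)) {
    mic <- neo_micro(cep, tol_micro = 1e-9, r_t = r_t)
    expect_lte(mic$step_norm, r_t * (1 + 1e-2))
  }
})

test_that("the Fletcher rule rejects uphill steps and adapts the radius", {
  pol <- trust_region_policy()
  up <- fletcher_update(e_new = -1.0, e_old = -1.2, e_pred = -1.3,
                        r_t = 0.4, policy = pol)
  expect_false(up$accept)
  expect_equal(up$r_t, 0.2)
  good <- fletcher_update(-1.3, -1.2, -1.3, 0.4, pol)  # ratio exactly 1
  expect_true(good$accept)
  expect_equal(good$r_t, 0.4 * 1.2)
  mid <- fletcher_update(-1.25, -1.2, -1.3, 0.4, pol)  # ratio 0.5
  expect_true(mid$accept)
  expect_equal(mid$r_t, 0.4)
  poor <- fletcher_update(-1.21, -1.2, -1.3, 0.4, pol)  # ratio 0.1
  expect_true(poor$accept)
  expect_equal(poor$r_t, 0.4 * 0.7)
  expect_equal(fletcher_update(-1.3, -1.2, -1.3, 0.9, pol)$r_t, 1)  # cap
})

test_that("near a minimum the first step has predicted/actual ratio 1", {
  # the quadratic model is locally exact, so close to the minimum the
  # predicted and actual energy changes agree
  ints <- ppp_ring(6)
  res <- run_casscf(ints, 4, 4, guess = "core", cd_threshold = 0)
  cep <- res$cep
  basis <- res$basis
  factor <- res$factor_ao
  set.seed(208)
  sp <- rotate_orbitals(cep$spaces, rnorm(cep$spaces$n_rot, sd = 1e-3))
  cep_d <- cep_context(ints, sp, factor, basis)
  mic <- neo_micro(cep_d, tol_micro = 1e-11, r_t = 0.5)
  sp2 <- rotate_orbitals(cep_d$spaces, mic$kappa)
  cep2 <- cep_context(ints, sp2, factor, basis,
                      ci_guess = cep_d$c0 + mic$delta_c)
  fl <- fletcher_update(cep2$e_total, cep_d$e_total,
                        cep_d$e_total + mic$de_pred, 0.5)
  expect_true(fl$accept)
  expect_equal(fl$ratio, 1, tolerance = 1e-3)
  expect_equal(cep2$e_total, res$energy, tolerance = 1e-8)
})

test_that("the exponential map is orthogonal and third-order accurate", {
  fix <- fix_ppp_chain6()
  sp <- fix$spaces
  set.seed(209)
  kap <- rnorm(sp$n_rot)
  kap <- kap / sqrt(sum(kap^2))
  u <- expm_antisym_test(unpack_rotation(sp, kap))
  expect_lt(max(abs(crossprod(u) - diag(sp$n_mo))), 1e-12)
  sp_rot <- rotate_orbitals(sp, kap)
  expect_lt(max(abs(sp_rot$mo_coeff - sp$mo_coeff %*% u)), 1e-12)
  expect_identical(rotate_orbitals(sp, numeric(sp$n_rot))$mo_coeff,
                   sp$mo_coeff)
  # E(rotate(C, t k)) - quadratic model = O(t^3)
  cep <- cep_context(fix$ints, sp, fix$factor, fix$basis)
  model_err <- vapply(c(1e-1, 1e-2, 1e-3), function(t) {
    kt <- t * kap
    e_true <- cep_energy_at(fix$ints, sp, fix$factor, fix$basis, cep$c0, kt)
    hk <- hessian_apply(cep, v_orb = kt)$v_orb
    e_model <- cep$e_total + sum(cep$g_orb * kt) + 0.5 * sum(kt * hk)
    abs(e_true - e_model)
  }, numeric(1))
  # each tenfold reduction in step shrinks the error ~1000-fold
  expect_gt(model_err[1] / model_err[2], 100)
  expect_gt(model_err[2] / model_err[3], 100)
})

test_that("full-space CAS optimizations equal dense FCI", {
  hub <- hubbard_chain(2, t = 1, U = 4)
  res <- run_casscf(hub, 2, 2, guess = "core", cd_threshold = 0)
  expect_equal(res$energy, 2 - 2 * sqrt(2), tolerance = 1e-10)
  ben <- ppp_ring(6)
  basis <- build_determinant_basis(6, 3, 3)
  hd <- dense_active_hamiltonian(ben$h_core, eri_array(ben$eri), basis)
  e_fci <- min(eigen(hd, symmetric = TRUE)$values) + ben$e_nuc
  res_b <- run_casscf(ben, 6, 6, guess = "core", cd_threshold = 1e-4)
  expect_equal(res_b$energy, e_fci, tolerance = 1e-9)
  expect_lte(res_b$n_macro, 10)
})

test_that("CASSCF matches brute-force orbital optimization", {
  fix <- fix_ppp_chain6()
  res <- run_casscf(fix$ints, 4, 4, guess = "core", cd_threshold = 0)
  ef <- function(kap) dense_cas_energy(fix$ints, fix$spaces, kap, fix$basis)
  opt <- stats::optim(numeric(fix$spaces$n_rot), ef, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
  expect_equal(res$energy, opt$value, tolerance = 1e-9)
})

test_that("accepted energies decrease and gradients converge quadratically", {
  fix <- fix_ppp_chain6()
  res <- run_casscf(fix$ints, 4, 4, guess = "core", cd_threshold = 1e-6)
  expect_true(res$converged)
  expect_lt(rms_final <- max(rms_norm(res$cep$g_orb),
                             rms_norm(as.numeric(res$cep$g_ci))), 1e-7)
  acc <- res$log[!is.na(res$log$accepted) & res$log$accepted, ]
  expect_true(all(diff(res$log$e[!is.na(res$log$accepted)][
    res$log$accepted[!is.na(res$log$accepted)]]) < 0 |
    abs(diff(acc$e)) < 1e-14))
  # quadratic tail: g_{k+1} <= c g_k^2 over the last macroiterations
  gr <- res$log$rms_orb
  tail_gr <- gr[gr < 1e-2 & gr > 0]
  if (length(tail_gr) >= 2) {
    ratios <- tail_gr[-1] / tail_gr[-length(tail_gr)]^2
    expect_true(all(ratios < 1e3))
  }
})

test_that("the optimum is independent of the starting guess", {
  # benzene CAS(4,4): every start reaches the same minimum
  ints <- ppp_ring(6)
  res_core <- run_casscf(ints, 4, 4, guess = "core", cd_threshold = 0)
  sp0 <- orbital_space(core_guess(ints), 1L, 4L)
  set.seed(210)
  sp_r <- rotate_orbitals(sp0, rnorm(sp0$n_rot, sd = 0.3))
  res_rand <- run_casscf(ints, 4, 4, guess = "manual",
                         mo_coeff = sp_r$mo_coeff, cd_threshold = 0)
  expect_equal(res_rand$energy, res_core$energy, tolerance = 1e-9)
  res_restart <- run_casscf(ints, 4, 4, guess = "manual",
                            mo_coeff = res_core$spaces$mo_coeff,
                            cd_threshold = 0)
  expect_equal(res_restart$energy, res_core$energy, tolerance = 1e-10)
  expect_lte(res_restart$n_macro, 2)
})
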