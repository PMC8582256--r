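# Determinant basis, direct sigma builds, Davidson ground states and
# reduced density matrices.

test_that("determinant space dimensions follow the binomial counts", {
  b <- build_determinant_basis(2, 1, 1)
  expect_equal(b$dim, 4)
  b2 <- build_determinant_basis(8, 4, 4)
  expect_equal(b2$dim, 4900)
  expect_equal(det_space_dimension(14, 7, 7), 11778624)
  expect_error(build_determinant_basis(3, 4, 1), "impossible")
})

test_that("string addressing is a bijection in lexical order", {
  b <- build_determinant_basis(5, 2, 3)
  expect_equal(b$n_str_a, choose(5, 2))
  keys <- apply(b$strings_a, 2, paste, collapse = ",")
  expect_identical(unname(b$addr_a[keys]), seq_len(b$n_str_a))
})

test_that("sigma of zero integrals vanishes and sigma is linear", {
  b <- build_determinant_basis(3, 2, 1)
  z <- sigma_apply(matrix(0, 3, 3), array(0, c(3, 3, 3, 3)),
                   rnorm(b$dim), b)
  expect_equal(max(abs(z)), 0)
  x <- random_lowrank_eri(3, 4, seed = 1)
  g <- eri_array(x$eri)
  v1 <- rnorm(b$dim); v2 <- rnorm(b$dim)
  s12 <- sigma_apply(x$h_core, g, 2 * v1 - 3 * v2, b)
  s1 <- sigma_apply(x$h_core, g, v1, b)
  s2 <- sigma_apply(x$h_core, g, v2, b)
  expect_lt(max(abs(s12 - (2 * s1 - 3 * s2))), 1e-12)
})

test_that("string-driven sigma agrees with the Slater-Condon Hamiltonian", {
  set.seed(10)
  cases <- list(c(3, 1, 1), c(4, 2, 2), c(4, 3, 1), c(5, 2, 3), c(6, 3, 3))
  for (cs in cases) {
    b <- build_determinant_basis(cs[1], cs[2], cs[3])
    x <- random_lowrank_eri(cs[1], 2 * cs[1], seed = sum(cs))
    g <- eri_array(x$eri)
    hd <- dense_active_hamiltonian(x$h_core, g, b)
    v <- rnorm(b$dim)
    expect_lt(max(abs(as.numeric(sigma_apply(x$h_core, g, v, b)) -
                      as.numeric(hd %*% v))), 1e-11)
    # Hermiticity through the sigma build
    w <- rnorm(b$dim)
    sv <- as.numeric(sigma_apply(x$h_core, g, v, b))
    sw <- as.numeric(sigma_apply(x$h_core, g, w, b))
    expect_equal(sum(w * sv), sum(v * sw), tolerance = 1e-10)
  }
})

test_that("Davidson matches dense diagonalization on seeded Hamiltonians", {
  set.seed(20)
  for (k in 1:10) {
    n <- sample(3:5, 1)
    na <- sample(seq_len(n - 1L), 1)
    nb <- sample(seq_len(n - 1L), 1)
    b <- build_determinant_basis(n, na, nb)
    x <- random_lowrank_eri(n, n + 3L, seed = 100 + k)
    g <- eri_array(x$eri)
    hd <- dense_active_hamiltonian(x$h_core, g, b)
    e_ref <- min(eigen(hd, symmetric = TRUE)$values)
    sol <- davidson_ground_state(x$h_core, g, b, tol = 1e-9)
    expect_equal(sol$energy, e_ref, tolerance = 1e-10)
    resid <- sigma_apply(x$h_core, g, sol$vector, b) -
      sol$energy * sol$vector
    expect_lt(sqrt(sum(resid^2)), 1e-9)
  }
})

test_that("a dimension-1 basis returns its diagonal element", {
  b <- build_determinant_basis(2, 2, 2)
  expect_equal(b$dim, 1)
  x <- random_lowrank_eri(2, 3, seed = 6)
  g <- eri_array(x$eri)
  sol <- davidson_ground_state(x$h_core, g, b)
  hd <- dense_active_hamiltonian(x$h_core, g, b)
  expect_equal(sol$energy, hd[1, 1])
})

test_that("RDMs obey trace, symmetry and sum rules", {
  set.seed(30)
  b <- build_determinant_basis(4, 2, 2)
  x <- random_lowrank_eri(4, 8, seed = 31)
  g <- eri_array(x$eri)
  for (k in 1:4) {
    v <- matrix(rnorm(b$dim), b$n_str_a, b$n_str_b)
    v <- v / sqrt(sum(v^2))
    r <- one_two_rdm(v, b)
    n_el <- b$n_alpha + b$n_beta
    expect_equal(sum(diag(r$gamma)), n_el, tolerance = 1e-11)
    expect_lt(max(abs(r$gamma - t(r$gamma))), 1e-12)
    ev <- eigen(r$gamma, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10 & ev < 2 + 1e-10))
    # partial trace: sum_x Gamma_uvxx = (N-1) gamma_uv
    pt <- apply(r$Gamma2, c(1, 2), function(m) sum(diag(m)))
    expect_lt(max(abs(pt - (n_el - 1) * r$gamma)), 1e-11)
    # exchange symmetry Gamma_uvxy = Gamma_xyuv
    expect_lt(max(abs(r$Gamma2 - aperm(r$Gamma2, c(3, 4, 1, 2)))), 1e-11)
  }
})

test_that("a closed-shell single determinant has gamma = diag(2, ..., 0)", {
  b <- build_determinant_basis(3, 1, 1)
  v <- matrix(0, b$n_str_a, b$n_str_b)
  v[1, 1] <- 1  # alpha and beta both occupy orbital 1
  r <- one_two_rdm(v, b)
  expect_equal(r$gamma, diag(c(2, 0, 0)), tolerance = 1e-13)
})

test_that("energy from RDM contraction equals the sigma expectation", {
  set.seed(40)
  b <- build_determinant_basis(4, 2, 2)
  x <- random_lowrank_eri(4, 8, seed = 41)
  g <- eri_array(x$eri)
  for (k in 1:3) {
    v <- matrix(rnorm(b$dim), b$n_str_a, b$n_str_b)
    v <- v / sqrt(sum(v^2))
    r <- one_two_rdm(v, b)
    e_rdm <- sum(r$gamma * x$h_core) + 0.5 * sum(r$Gamma2 * g)
    e_sig <- sum(v * sigma_apply(x$h_core, g, v, b))
    expect_equal(e_rdm, e_sig, tolerance = 1e-11)
  }
})

test_that("transition RDMs are bra/ket symmetric and reduce correctly", {
  set.seed(50)
  b <- build_determinant_basis(3, 2, 1)
  v <- matrix(rnorm(b$dim), b$n_str_a, b$n_str_b); v <- v / sqrt(sum(v^2))
  w <- matrix(rnorm(b$dim), b$n_str_a, b$n_str_b); w <- w / sqrt(sum(w^2))
  t_vw <- transition_rdms(v, w, b)
  t_wv <- transition_rdms(w, v, b)
  expect_lt(max(abs(t_vw$gamma - t_wv$gamma)), 1e-12)
  expect_lt(max(abs(t_vw$Gamma2 - t_wv$Gamma2)), 1e-12)
  t_vv <- transition_rdms(v, v, b)
  r_v <- one_two_rdm(v, b)
  expect_lt(max(abs(t_vv$gamma - r_v$gamma)), 1e-12)
  expect_lt(max(abs(t_vv$Gamma2 - r_v$Gamma2)), 1e-12)
})

test_that("the singlet ground state of the Hubbard dimer has S^2 = 0", {
  ints <- hubbard_chain(2, t = 1, U = 4)
  b <- build_determinant_basis(2, 1, 1)
  sol <- davidson_ground_state(ints$h_core, eri_array(ints$eri), b)
  expect_equal(s_squared(sol$vector, b), 0, tolerance = 1e-10)
  # a single open-shell determinant with Sz = 0 is a 50/50 singlet/triplet
  v <- matrix(0, 2, 2)
  v[cascd::build_determinant_basis(2, 1, 1)$addr_a[["1"]],
    cascd::build_determinant_basis(2, 1, 1)$addr_b[["2"]]] <- 1
  expect_equal(s_squared(v, b), 1, tolerance = 1e-10)
})
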