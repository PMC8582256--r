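# Restricted and unrestricted SCF with DIIS, both built on per-vector
# Cholesky Coulomb/exchange contractions in the AO basis:
#   J(D) = sum_K L tr(D L),  K(D) = sum_K L D L.

chol_jk <- function(factor, d) {
  n <- factor$n_orb
  j <- matrix(0, n, n)
  k <- matrix(0, n, n)
  for (K in seq_len(factor$n_ch)) {
    l <- unpack_sym(factor$vectors[, K], n)
    j <- j + sum(d * l) * l
    k <- k + l %*% d %*% l
  }
  list(j = j, k = k)
}

diis_extrapolate <- function(fock_hist, err_hist) {
  m <- length(fock_hist)
  b <- matrix(0, m + 1L, m + 1L)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) b[i, j] <- sum(err_hist[[i]] * err_hist[[j]])
  }
  b[m + 1L, seq_len(m)] <- -1
  b[seq_len(m), m + 1L] <- -1
  rhs <- c(numeric(m), -1)
  coef <- tryCatch(solve(b, rhs)[seq_len(m)], error = function(e) NULL)
  if (is.null(coef)) return(fock_hist[[m]])
  out <- 0
  for (i in seq_len(m)) out <- out + coef[i] * fock_hist[[i]]
  out
}

#' Restricted Hartree-Fock with DIIS
#'
#' Roothaan SCF using Cholesky-based Fock builds; converges on the RMS
#' change of the (per-spin) density matrix.  Canonical orbitals are
#' returned ordered by orbital energy.
#'
#' @param integrals An [integral_set()] with an even electron count.
#' @param cd_threshold CD threshold used when the ERIs are dense.
#' @param tol Density RMS convergence threshold.
#' @param max_iter Iteration cap.
#' @param diis_depth Number of retained DIIS vectors.
#' @return List with `energy`, `mo_coeff`, `orbital_energies`, `n_occ`,
#'   `density` (per-spin AO density), `n_iter`, `factor_ao`.
#' @export
restricted_scf <- function(integrals, cd_threshold = 1e-8, tol = 1e-9,
                           max_iter = 200L, diis_depth = 8L) {
  if (integrals$n_elec %% 2L != 0L) {
    stop("restricted SCF needs an even electron count", call. = FALSE)
  }
  n_occ <- integrals$n_elec %/% 2L
  factor <- if (inherits(integrals$eri, "cholesky_factor")) integrals$eri
            else cd_decompose(integrals$eri, cd_threshold)
  s <- integrals$overlap
  x <- inv_sqrt_sym(s)
  h <- integrals$h_core
  # core guess
  c_mo <- core_guess_from(h, x)
  fock_hist <- list(); err_hist <- list()
  d_old <- NULL
  energy <- NA_real_
  for (it in seq_len(max_iter)) {
    d <- if (n_occ > 0L) tcrossprod(c_mo[, seq_len(n_occ), drop = FALSE])
         else matrix(0, nrow(h), nrow(h))
    jk <- chol_jk(factor, d)
    f <- h + 2 * jk$j - jk$k
    energy <- sum(d * (h + f)) + integrals$e_nuc
    err <- x %*% (f %*% d %*% s - s %*% d %*% f) %*% x
    fock_hist <- c(fock_hist, list(f))
    err_hist <- c(err_hist, list(err))
    if (length(fock_hist) > diis_depth) {
      fock_hist <- fock_hist[-1L]; err_hist <- err_hist[-1L]
    }
    f_use <- if (length(fock_hist) > 1L) diis_extrapolate(fock_hist, err_hist)
             else f
    fo <- crossprod(x, f_use %*% x)
    e <- eigen((fo + t(fo)) / 2, symmetric = TRUE)
    ord <- order(e$values)
    c_mo <- x %*% e$vectors[, ord]
    eps <- e$values[ord]
    if (!is.null(d_old) && rms_norm(as.numeric(d - d_old)) < tol) {
      return(list(energy = energy, mo_coeff = c_mo, orbital_energies = eps,
                  n_occ = n_occ, density = d, n_iter = it,
                  factor_ao = factor))
    }
    d_old <- d
  }
  stop("restricted SCF did not converge in ", max_iter, " iterations ",
       "(last DIIS error ", format(max(abs(err_hist[[length(err_hist)]]))),
       ")", call. = FALSE)
}

core_guess_from <- function(h, x) {
  ho <- crossprod(x, h %*% x)
  e <- eigen((ho + t(ho)) / 2, symmetric = TRUE)
  x %*% e$vectors[, order(e$values)]
}

#' Unrestricted Hartree-Fock with DIIS
#'
#' @param integrals An [integral_set()].
#' @param c_alpha,c_beta Starting orbitals for each spin (AO columns).
#' @param n_alpha,n_beta Occupied counts per spin (defaults split
#'   `n_elec` as evenly as possible).
#' @param cd_threshold,tol,max_iter,diis_depth As in [restricted_scf()].
#' @return List with `energy`, `mo_coeff_alpha/beta`,
#'   `orbital_energies_alpha/beta`, per-spin densities and `n_iter`.
#' @export
unrestricted_scf <- function(integrals, c_alpha, c_beta,
                             n_alpha = NULL, n_beta = NULL,
                             cd_threshold = 1e-8, tol = 1e-9,
                             max_iter = 300L, diis_depth = 8L) {
  n_elec <- integrals$n_elec
  if (is.null(n_alpha)) n_alpha <- (n_elec + n_elec %% 2L) %/% 2L
  if (is.null(n_beta)) n_beta <- n_elec - n_alpha
  factor <- if (inherits(integrals$eri, "cholesky_factor")) integrals$eri
            else cd_decompose(integrals$eri, cd_threshold)
  s <- integrals$overlap
  x <- inv_sqrt_sym(s)
  h <- integrals$h_core
  ca <- as.matrix(c_alpha); cb <- as.matrix(c_beta)
  fock_hist <- list(); err_hist <- list()
  d_old <- NULL
  energy <- NA_real_
  for (it in seq_len(max_iter)) {
    da <- if (n_alpha > 0L) tcrossprod(ca[, seq_len(n_alpha), drop = FALSE])
          else matrix(0, nrow(h), nrow(h))
    db <- if (n_beta > 0L) tcrossprod(cb[, seq_len(n_beta), drop = FALSE])
          else matrix(0, nrow(h), nrow(h))
    jk_tot <- chol_jk(factor, da + db)
    ka <- chol_jk(factor, da)$k
    kb <- chol_jk(factor, db)$k
    fa <- h + jk_tot$j - ka
    fb <- h + jk_tot$j - kb
    energy <- 0.5 * (sum(da * (h + fa)) + sum(db * (h + fb))) +
      integrals$e_nuc
    err <- rbind(x %*% (fa %*% da %*% s - s %*% da %*% fa) %*% x,
                 x %*% (fb %*% db %*% s - s %*% db %*% fb) %*% x)
    fock_hist <- c(fock_hist, list(rbind(fa, fb)))
    err_hist <- c(err_hist, list(err))
    if (length(fock_hist) > diis_depth) {
      fock_hist <- fock_hist[-1L]; err_hist <- err_hist[-1L]
    }
    f_use <- if (length(fock_hist) > 1L) diis_extrapolate(fock_hist, err_hist)
             else rbind(fa, fb)
    n <- nrow(h)
    solve_spin <- function(f) {
      fo <- crossprod(x, f %*% x)
      e <- eigen((fo + t(fo)) / 2, symmetric = TRUE)
      ord <- order(e$values)
      list(c = x %*% e$vectors[, ord], eps = e$values[ord])
    }
    sa <- solve_spin(f_use[seq_len(n), , drop = FALSE])
    sb <- solve_spin(f_use[n + seq_len(n), , drop = FALSE])
    ca <- sa$c; cb <- sb$c
    d_new <- rbind(da, db)
    if (!is.null(d_old) && rms_norm(as.numeric(d_new - d_old)) < tol) {
      return(list(energy = energy, mo_coeff_alpha = ca, mo_coeff_beta = cb,
                  orbital_energies_alpha = sa$eps,
                  orbital_energies_beta = sb$eps,
                  density_alpha = da, density_beta = db,
                  n_alpha = n_alpha, n_beta = n_beta, n_iter = it))
    }
    d_old <- d_new
  }
  stop("unrestricted SCF did not converge in ", max_iter, " iterations",
       call. = FALSE)
}
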