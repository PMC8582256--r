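# Macro/microiteration CASSCF driver.
#
# Each macroiteration: AO-to-MO transformation of the Cholesky vectors,
# Davidson solution of the active CI problem at the current expansion
# point (warm-started from the step-updated vector), density matrices and
# Fock builds, gradients, then split-Davidson microiterations on the
# bordered Hessian to obtain a trust-region step; Fletcher's rule accepts
# or rejects the step and adapts the radius.  Convergence is declared when
# the RMS norms of both the orbital and CI gradient fall below the
# tolerance (default 1e-7).

#' Run a CD-CASSCF optimization
#'
#' @param integrals An [integral_set()]; the ERIs may be dense or already
#'   Cholesky-decomposed.
#' @param n_act Number of active orbitals.
#' @param n_elec_act Number of active electrons.
#' @param guess Orbital guess: `"core"` (eigenvectors of the core
#'   Hamiltonian), `"uno"` (unrestricted natural orbitals via the
#'   triplet-instability protocol) or `"manual"` (user `mo_coeff`).
#' @param mo_coeff Starting orbitals for `guess = "manual"`.
#' @param active_list For `guess = "manual"`: indices (into the supplied
#'   orbitals) to place in the active window; defaults to the orbitals
#'   already in active position.
#' @param cd_threshold Cholesky decomposition threshold for dense input
#'   ERIs (ignored when `integrals$eri` is already a factor).
#' @param conv_tol RMS gradient convergence tolerance.
#' @param max_macro Maximum number of macroiteration attempts.
#' @param policy A [trust_region_policy()].
#' @param ci_tol Davidson tolerance for each CEP CI solution.
#' @param verbose Print one line per macroiteration?
#' @return Object of class `casscf_result`: converged energy, orbital
#'   space, CI vector, final `cep_state`, iteration log (one row per
#'   attempted macroiteration) and counters.
#' @export
run_casscf <- function(integrals, n_act, n_elec_act,
                       guess = c("core", "uno", "manual"),
                       mo_coeff = NULL, active_list = NULL,
                       cd_threshold = 1e-4, conv_tol = 1e-7,
                       max_macro = 50L, policy = trust_region_policy(),
                       ci_tol = 1e-10, verbose = FALSE) {
  guess <- match.arg(guess)
  n_elec <- integrals$n_elec
  n_core <- n_elec - n_elec_act
  if (n_core < 0L || n_core %% 2L != 0L) {
    stop("inactive electron count ", n_core, " must be even and >= 0",
         call. = FALSE)
  }
  n_int <- n_core %/% 2L
  if (n_int + n_act > integrals$n_orb) {
    stop("partition exceeds orbital count", call. = FALSE)
  }
  n_alpha <- (n_elec_act + n_elec_act %% 2L) %/% 2L
  n_beta <- n_elec_act - n_alpha
  basis <- build_determinant_basis(n_act, n_alpha, n_beta)

  c0_mo <- switch(guess,
    core = core_guess_orbitals(integrals),
    uno = {
      ug <- uno_active_space(integrals)
      ug$spaces$mo_coeff
    },
    manual = {
      if (is.null(mo_coeff)) stop("guess = 'manual' needs mo_coeff",
                                  call. = FALSE)
      reorder_active(mo_coeff, n_int, n_act, active_list)
    })
  spaces <- orbital_space(c0_mo, n_int, n_act, integrals$overlap)

  factor_ao <- if (inherits(integrals$eri, "cholesky_factor")) {
    integrals$eri
  } else {
    cd_decompose(integrals$eri, cd_threshold)
  }

  r_t <- policy$r_init
  log <- list()
  ci_guess <- NULL
  cep <- cep_context(integrals, spaces, factor_ao, basis,
                     ci_guess = ci_guess, ci_tol = ci_tol)
  macro <- 0L
  accepted <- 0L
  converged <- FALSE
  prev_e <- Inf
  while (macro < max_macro) {
    macro <- macro + 1L
    rms_o <- rms_norm(cep$g_orb)
    rms_c <- rms_norm(as.numeric(cep$g_ci))
    if (verbose) {
      cat(sprintf("macro %2d  E = %.12f  rms(g_orb) = %.3e  rms(g_ci) = %.3e  R_t = %.3g\n",
                  macro, cep$e_total, rms_o, rms_c, r_t))
    }
    if (max(rms_o, rms_c) < conv_tol) {
      log[[length(log) + 1L]] <- data.frame(
        macro = macro, e = cep$e_total, rms_orb = rms_o, rms_ci = rms_c,
        micro = 0L, step_norm = 0, alpha = NA_real_, ratio = NA_real_,
        accepted = NA, r_t = r_t)
      converged <- TRUE
      break
    }
    tol_micro <- max(1e-2 * max(rms_o, rms_c), 1e-10)
    micro <- neo_micro(cep, tol_micro = tol_micro, r_t = r_t)
    if (micro$step_norm == 0) {
      converged <- max(rms_o, rms_c) < conv_tol
      break
    }
    spaces_new <- rotate_orbitals(cep$spaces, micro$kappa)
    ci_warm <- cep$c0 + micro$delta_c
    cep_new <- cep_context(integrals, spaces_new, factor_ao, basis,
                           ci_guess = ci_warm, ci_tol = ci_tol)
    fl <- fletcher_update(cep_new$e_total, cep$e_total,
                          cep$e_total + micro$de_pred, r_t, policy)
    log[[length(log) + 1L]] <- data.frame(
      macro = macro, e = cep$e_total, rms_orb = rms_o, rms_ci = rms_c,
      micro = micro$n_micro, step_norm = micro$step_norm,
      alpha = micro$alpha, ratio = fl$ratio, accepted = fl$accept,
      r_t = r_t)
    r_t <- fl$r_t
    if (fl$accept) {
      if (cep_new$e_total > cep$e_total) {
        stop("internal invariant violation: accepted step raised the energy",
             call. = FALSE)
      }
      cep <- cep_new
      accepted <- accepted + 1L
    }
  }
  log_df <- do.call(rbind, log)
  if (!converged) {
    stop("CASSCF did not converge in ", max_macro,
         " macroiterations; last RMS gradients ",
         format(rms_norm(cep$g_orb)), " / ",
         format(rms_norm(as.numeric(cep$g_ci))),
         " (inspect the attached log attribute)",
         call. = FALSE)
  }
  structure(
    list(energy = cep$e_total, spaces = cep$spaces, c0 = cep$c0,
         cep = cep, basis = basis, factor_ao = factor_ao,
         n_macro = macro, n_accepted = accepted, converged = converged,
         log = log_df, conv_tol = conv_tol),
    class = "casscf_result")
}

#' @export
print.casscf_result <- function(x, ...) {
  cat("CASSCF result (NEO, Cholesky-decomposed ERIs)\n")
  cat("  E =", format(x$energy, digits = 13), "hartree\n")
  cat("  macroiterations:", x$n_macro, "(", x$n_accepted, "accepted steps )\n")
  cat("  final RMS g_orb:", format(rms_norm(x$cep$g_orb), digits = 3),
      " RMS g_ci:", format(rms_norm(as.numeric(x$cep$g_ci)), digits = 3),
      "\n")
  invisible(x)
}

# eigenvectors of the core Hamiltonian in the S-orthonormal metric,
# ordered by energy
core_guess_orbitals <- function(integrals) {
  x <- inv_sqrt_sym(integrals$overlap)
  ho <- crossprod(x, integrals$h_core %*% x)
  e <- eigen((ho + t(ho)) / 2, symmetric = TRUE)
  x %*% e$vectors[, order(e$values)]
}

# place active_list columns into the active window, preserving order of
# the remaining columns
reorder_active <- function(mo_coeff, n_int, n_act, active_list) {
  n_mo <- ncol(mo_coeff)
  if (is.null(active_list)) return(mo_coeff)
  active_list <- as.integer(active_list)
  if (length(active_list) != n_act) {
    stop("active_list must name exactly n_act orbitals", call. = FALSE)
  }
  rest <- setdiff(seq_len(n_mo), active_list)
  ord <- c(rest[seq_len(n_int)], active_list,
           rest[-seq_len(n_int)])
  mo_coeff[, ord, drop = FALSE]
}
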