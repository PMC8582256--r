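# Starting-orbital and active-space selection: triplet-instability search
# on the restricted solution, symmetry breaking along the unstable
# directions, unrestricted natural orbitals (UNO) from the averaged charge
# density, and occupation-window selection of the active orbitals.

#' Triplet instability analysis of a restricted SCF solution
#'
#' Eigenpairs of the triplet (real, external) stability matrix
#' `H_ia,jb = delta_ij delta_ab (eps_a - eps_i) - (ij|ab) - (ib|ja)`;
#' a negative eigenvalue signals an RHF -> UHF instability.  The matrix is
#' applied through the Cholesky vectors and diagonalized by Davidson; for
#' small rotation spaces the dense spectrum is computed instead so that
#' all unstable directions are available.
#'
#' @param integrals An [integral_set()].
#' @param scf A [restricted_scf()] result for these integrals.
#' @param n_roots Number of lowest eigenpairs requested (dense path).
#' @param dense_cutoff Rotation-space size up to which the dense spectrum
#'   is used.
#' @return List with `values` (ascending eigenvalues, at most `n_roots`),
#'   `vectors` (list of occ x virt matrices) and the space dimensions.
#' @export
triplet_instability_lowest <- function(integrals, scf, n_roots = 4L,
                                       dense_cutoff = 400L) {
  n <- integrals$n_orb
  n_occ <- scf$n_occ
  n_virt <- n - n_occ
  if (n_occ == 0L || n_virt == 0L) {
    return(list(values = numeric(0), vectors = list(),
                n_occ = n_occ, n_virt = n_virt))
  }
  factor <- scf$factor_ao
  mo_chol <- cd_ao_to_mo(factor, scf$mo_coeff, integrals$overlap)
  occ <- seq_len(n_occ)
  virt <- n_occ + seq_len(n_virt)
  eps <- scf$orbital_energies
  de <- outer(eps[occ], eps[virt], function(ei, ea) ea - ei)
  apply_h <- function(vmat) {
    out <- de * vmat
    for (K in seq_len(mo_chol$n_ch)) {
      l <- mo_chol$l[, , K]
      loo <- l[occ, occ, drop = FALSE]
      lvv <- l[virt, virt, drop = FALSE]
      lov <- l[occ, virt, drop = FALSE]
      out <- out - loo %*% vmat %*% lvv          # (ij|ab) v_jb
      out <- out - (lov %*% t(vmat)) %*% lov     # (ib|ja) v_jb
    }
    out
  }
  n_ov <- n_occ * n_virt
  if (n_ov <= dense_cutoff) {
    hm <- matrix(0, n_ov, n_ov)
    for (col in seq_len(n_ov)) {
      v <- matrix(0, n_occ, n_virt)
      v[col] <- 1
      hm[, col] <- as.numeric(apply_h(v))
    }
    hm <- (hm + t(hm)) / 2
    e <- eigen(hm, symmetric = TRUE)
    ord <- order(e$values)
    k <- min(n_roots, n_ov)
    vals <- e$values[ord][seq_len(k)]
    vecs <- lapply(seq_len(k), function(i) {
      matrix(e$vectors[, ord[i]], n_occ, n_virt)
    })
  } else {
    g <- matrix(0, n_occ, n_virt)
    g[which.min(de)] <- 1
    res <- davidson_lowest(
      apply_fn = function(v) as.numeric(apply_h(matrix(v, n_occ, n_virt))),
      diag_vec = as.numeric(de), guess = as.numeric(g), tol = 1e-9)
    vals <- res$value
    vecs <- list(matrix(res$vector, n_occ, n_virt))
  }
  list(values = vals, vectors = vecs, n_occ = n_occ, n_virt = n_virt)
}

#' UNO active-space selection
#'
#' The production starting guess: find triplet instabilities of the
#' restricted solution; perturb the orbitals along each unstable
#' direction (alpha and beta in opposite senses) and converge an
#' unrestricted SCF; form the charge density averaged over the
#' unrestricted solutions; diagonalize it for the unrestricted natural
#' orbitals; and select as active the orbitals whose occupation lies
#' strictly inside the window (default (0.01, 1.99)).
#'
#' @param integrals An [integral_set()] (even electron count).
#' @param window Occupation window `(lo, hi)`.
#' @param mix_angle Rotation angle (rad) along each instability
#'   eigenvector used to break spin symmetry.
#' @param follow `"all"` instabilities (averaged density) or
#'   `"strongest"` (most negative eigenvalue only).
#' @param cd_threshold CD threshold for the underlying SCF Fock builds.
#' @return List with `spaces` (an [orbital_space()] over the natural
#'   orbitals, ordered by descending occupation) and `report` (class
#'   `guess_report`): SCF energies, instability eigenvalues, occupation
#'   numbers, the selected active set and the resulting (n_elec_act,
#'   n_act).
#' @export
uno_active_space <- function(integrals, window = c(0.01, 1.99),
                             mix_angle = 0.2, follow = c("all", "strongest"),
                             cd_threshold = 1e-8) {
  follow <- match.arg(follow)
  stopifnot(length(window) == 2L, window[1L] < window[2L])
  rhf <- restricted_scf(integrals, cd_threshold = cd_threshold)
  stab <- triplet_instability_lowest(integrals, rhf)
  neg <- which(stab$values < -1e-8)
  report <- list(kind = "uno", scf_energy = rhf$energy,
                 instability_values = stab$values, window = window,
                 uhf_energies = numeric(0))
  if (length(neg) == 0L) {
    warning("no triplet instability: restricted orbitals returned with ",
            "an empty active selection", call. = FALSE)
    report$occupations <- c(rep(2, rhf$n_occ),
                            rep(0, integrals$n_orb - rhf$n_occ))
    report$active <- integer(0)
    report$n_act <- 0L
    report$n_elec_act <- 0L
    report$message <- "no instability"
    spaces <- orbital_space(rhf$mo_coeff, rhf$n_occ, 0L, integrals$overlap)
    return(list(spaces = spaces, report = structure(report,
                                                    class = "guess_report")))
  }
  if (follow == "strongest") neg <- neg[which.min(stab$values[neg])]
  n <- integrals$n_orb
  n_occ <- rhf$n_occ
  d_sum <- matrix(0, n, n)
  n_sol <- 0L
  for (i in neg) {
    v <- stab$vectors[[i]]
    v <- v / sqrt(sum(v^2))
    uhf <- NULL
    # escalate the mixing angle if the unrestricted solution falls back
    # into the restricted saddle point
    for (angle in unique(c(mix_angle, 0.4, 0.8, 1.2))) {
      k <- matrix(0, n, n)
      k[seq_len(n_occ), n_occ + seq_len(n - n_occ)] <- angle * v
      k <- k - t(k)
      cand <- tryCatch(
        unrestricted_scf(integrals,
                         rhf$mo_coeff %*% expm_antisym(k),
                         rhf$mo_coeff %*% expm_antisym(-k),
                         n_alpha = integrals$n_elec %/% 2L,
                         n_beta = integrals$n_elec -
                           integrals$n_elec %/% 2L,
                         cd_threshold = cd_threshold),
        error = function(e) list(energy = Inf))
      if (cand$energy < rhf$energy - 1e-10) {
        uhf <- cand
        break
      }
    }
    if (is.null(uhf)) {
      report$uhf_energies <- c(report$uhf_energies,
                               if (is.finite(cand$energy)) cand$energy
                               else NA_real_)
      warning("unrestricted SCF collapsed back to the restricted solution ",
              "for instability ", i, call. = FALSE)
      next
    }
    report$uhf_energies <- c(report$uhf_energies, uhf$energy)
    d_sum <- d_sum + uhf$density_alpha + uhf$density_beta
    n_sol <- n_sol + 1L
  }
  if (n_sol == 0L) {
    report$occupations <- c(rep(2, n_occ), rep(0, n - n_occ))
    report$active <- integer(0)
    report$n_act <- 0L
    report$n_elec_act <- 0L
    report$message <- "all unrestricted solutions collapsed"
    spaces <- orbital_space(rhf$mo_coeff, n_occ, 0L, integrals$overlap)
    return(list(spaces = spaces,
                report = structure(report, class = "guess_report")))
  }
  d_avg <- d_sum / n_sol  # charge density, trace = n_elec
  s <- integrals$overlap
  s_half <- expm_sqrt(s)
  no <- eigen((s_half %*% d_avg %*% s_half +
               t(s_half %*% d_avg %*% s_half)) / 2, symmetric = TRUE)
  ord <- order(no$values, decreasing = TRUE)
  occupations <- no$values[ord]
  c_no <- inv_sqrt_sym(s) %*% no$vectors[, ord]
  active <- which(occupations > window[1L] & occupations < window[2L])
  n_elec_act <- as.integer(round(sum(occupations[active])))
  n_int <- (integrals$n_elec - n_elec_act) %/% 2L
  report$occupations <- occupations
  report$active <- active
  report$n_act <- length(active)
  report$n_elec_act <- n_elec_act
  report$message <- sprintf("CAS(%d,%d) selected", n_elec_act,
                            length(active))
  spaces <- orbital_space(c_no, n_int, length(active), integrals$overlap)
  list(spaces = spaces, report = structure(report, class = "guess_report"))
}

# principal square root of a symmetric positive-definite matrix
expm_sqrt <- function(s) {
  e <- eigen(s, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

#' @export
print.guess_report <- function(x, ...) {
  cat("Starting-guess report (", x$kind, ")\n", sep = "")
  cat("  SCF energy:", format(x$scf_energy, digits = 12), "\n")
  if (length(x$instability_values)) {
    cat("  lowest triplet-stability eigenvalues:",
        paste(format(x$instability_values, digits = 4), collapse = ", "),
        "\n")
  }
  cat("  occupation window:", paste(x$window, collapse = " .. "), "\n")
  cat("  ", x$message, "\n", sep = "")
  invisible(x)
}
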