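# Davidson subspace eigensolver for the lowest eigenpair of a symmetric
# linear operator given only through matrix-vector products, with a
# diagonal preconditioner, bounded subspace and collapse restarts.

#' Davidson solver for the lowest eigenpair
#'
#' @param apply_fn Function `v -> A v` for the symmetric operator A.
#' @param diag_vec Approximate (or exact) diagonal of A, used as the
#'   preconditioner.
#' @param guess Starting vector.
#' @param tol Residual 2-norm convergence threshold.
#' @param max_iter Maximum number of iterations.
#' @param max_subspace Subspace bound before collapsing.
#' @param collapse_to Number of Ritz vectors retained on collapse.
#' @return List with `value`, `vector` (unit norm), `iterations`,
#'   `residuals` (history of residual norms).
#' @export
davidson_lowest <- function(apply_fn, diag_vec, guess, tol = 1e-10,
                            max_iter = 300L, max_subspace = 24L,
                            collapse_to = 6L) {
  n <- length(guess)
  v <- guess / sqrt(sum(guess^2))
  basis <- matrix(v, ncol = 1L)
  sig <- matrix(apply_fn(v), ncol = 1L)
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    hs <- crossprod(basis, sig)
    hs <- (hs + t(hs)) / 2
    e <- eigen(hs, symmetric = TRUE)
    theta <- e$values[which.min(e$values)]
    y <- e$vectors[, which.min(e$values)]
    x <- as.numeric(basis %*% y)
    ax <- as.numeric(sig %*% y)
    r <- ax - theta * x
    rn <- sqrt(sum(r^2))
    history <- c(history, rn)
    if (rn <= tol) {
      return(list(value = theta, vector = x / sqrt(sum(x^2)),
                  iterations = it, residuals = history))
    }
    denom <- diag_vec - theta
    denom[abs(denom) < 1e-8] <- sign(denom[abs(denom) < 1e-8] + 1e-300) * 1e-8
    if (ncol(basis) >= min(max_subspace, n)) {
      # collapse to the best Ritz vectors, keeping the current iterate exact
      keep <- order(e$values)[seq_len(min(collapse_to, ncol(basis)))]
      newb <- basis %*% e$vectors[, keep, drop = FALSE]
      basis <- qr.Q(qr(newb))
      sig <- matrix(0, n, ncol(basis))
      for (k in seq_len(ncol(basis))) sig[, k] <- apply_fn(basis[, k])
    }
    # preconditioned residual, with raw-residual and coordinate fallbacks
    candidates <- list(-r / denom, r,
                       replace(numeric(n), which.max(abs(r)), 1))
    t_vec <- NULL
    for (cand in candidates) {
      t_vec <- orthonormalize_against(cand, basis)
      if (!is.null(t_vec)) break
    }
    if (is.null(t_vec)) break  # basis spans the reachable space
    basis <- cbind(basis, t_vec)
    sig <- cbind(sig, apply_fn(t_vec))
  }
  stop("Davidson did not converge in ", max_iter,
       " iterations; residual history: ",
       paste(format(utils::tail(history, 5L), digits = 3), collapse = ", "),
       call. = FALSE)
}

#' Davidson ground state of the active-space Hamiltonian
#'
#' @inheritParams sigma_apply
#' @param basis A `det_basis`.
#' @param guess Optional starting CI vector (flat or matrix layout);
#'   defaults to the unit vector on the lowest-diagonal determinant.
#' @param tol Residual norm tolerance for the eigenpair.
#' @return List with `energy` (electronic active energy, no nuclear or
#'   inactive contributions), `vector` (matrix layout, unit norm, phase
#'   fixed so the largest-magnitude coefficient is positive),
#'   `iterations`, `residuals`.
#' @export
davidson_ground_state <- function(active_h, active_eri, basis, guess = NULL,
                                  tol = 1e-10) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  hd <- hamiltonian_diagonal(active_h, active_eri, basis)
  if (basis$dim == 1L) {
    return(list(energy = hd[1L, 1L],
                vector = matrix(1, 1L, 1L), iterations = 0L,
                residuals = numeric(0)))
  }
  if (is.null(guess)) {
    g <- matrix(0, basis$n_str_a, basis$n_str_b)
    g[which.min(hd)] <- 1
    # small admixture to avoid an exactly-deficient starting space
    g[which(hd == sort(hd)[2L])[1L]] <- 1e-3
    guess <- g
  }
  res <- davidson_lowest(
    apply_fn = function(v) sigma_apply(active_h, active_eri, v, basis),
    diag_vec = as.numeric(hd),
    guess = as.numeric(ci_matrix(guess, basis)),
    tol = tol)
  vec <- ci_matrix(res$vector, basis)
  vec <- fix_phase(vec)
  list(energy = res$value, vector = vec, iterations = res$iterations,
       residuals = res$residuals)
}

# deterministic CI phase: largest-magnitude coefficient positive
fix_phase <- function(vec) {
  i <- which.max(abs(vec))
  if (vec[i] < 0) -vec else vec
}
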