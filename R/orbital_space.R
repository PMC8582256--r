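# Orbital spaces and nonredundant rotations.
#
# MOs are partitioned into internal (always doubly occupied), active and
# external (always empty) classes.  Only inter-class rotations change the
# energy; the packed rotation vector kappa enumerates the pairs
# (active,internal), (external,internal), (external,active) with
# N_rot = n_int n_act + n_int n_ext + n_act n_ext entries.

#' Construct an orbital space
#'
#' @param mo_coeff `n_b x n_mo` MO coefficient matrix.
#' @param n_int,n_act Internal and active orbital counts (externals make up
#'   the remainder).
#' @param overlap AO overlap for the orthonormality check (identity when
#'   omitted).
#' @return Object of class `orbital_space` with the partition, the packed
#'   rotation-pair index (`rotation_pairs`: matrix with columns `p`, `q`,
#'   p the higher class) and `n_rot`.
#' @export
orbital_space <- function(mo_coeff, n_int, n_act, overlap = NULL) {
  mo_coeff <- as.matrix(mo_coeff)
  n_mo <- ncol(mo_coeff)
  n_int <- as.integer(n_int)
  n_act <- as.integer(n_act)
  if (n_int < 0L || n_act < 0L || n_int + n_act > n_mo) {
    stop("invalid partition: ", n_int, " internal + ", n_act,
         " active > ", n_mo, " orbitals", call. = FALSE)
  }
  n_ext <- n_mo - n_int - n_act
  s <- if (is.null(overlap)) diag(nrow(mo_coeff)) else as.matrix(overlap)
  dev <- max(abs(crossprod(mo_coeff, s %*% mo_coeff) - diag(n_mo)))
  if (dev > 1e-8) {
    stop("mo_coeff not S-orthonormal (max deviation ", format(dev), ")",
         call. = FALSE)
  }
  int_idx <- seq_len(n_int)
  act_idx <- n_int + seq_len(n_act)
  ext_idx <- n_int + n_act + seq_len(n_ext)
  pairs <- rbind(
    expand_pairs(act_idx, int_idx),
    expand_pairs(ext_idx, int_idx),
    expand_pairs(ext_idx, act_idx))
  structure(
    list(mo_coeff = mo_coeff, n_mo = n_mo,
         n_int = n_int, n_act = n_act, n_ext = n_ext,
         int_idx = int_idx, act_idx = act_idx, ext_idx = ext_idx,
         rotation_pairs = pairs, n_rot = nrow(pairs)),
    class = "orbital_space")
}

expand_pairs <- function(hi, lo) {
  if (length(hi) == 0L || length(lo) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("p", "q"))))
  }
  g <- expand.grid(p = hi, q = lo)
  as.matrix(g[order(g$q, g$p), , drop = FALSE])
}

#' @export
print.orbital_space <- function(x, ...) {
  cat("Orbital space:", x$n_int, "internal /", x$n_act, "active /",
      x$n_ext, "external;", x$n_rot, "nonredundant rotations\n")
  invisible(x)
}

#' Unpack a rotation vector to the full antisymmetric generator
#'
#' Redundant (within-class) blocks are zero.
#'
#' @param spaces An `orbital_space`.
#' @param kappa Packed rotation vector of length `n_rot`.
#' @return `n_mo x n_mo` antisymmetric matrix K with `K[p,q] = kappa` for
#'   each rotation pair (p, q).
#' @export
unpack_rotation <- function(spaces, kappa) {
  stopifnot(length(kappa) == spaces$n_rot)
  k <- matrix(0, spaces$n_mo, spaces$n_mo)
  pr <- spaces$rotation_pairs
  k[pr] <- kappa
  k[pr[, c(2L, 1L), drop = FALSE]] <- -kappa
  k
}

#' Pack the rotation components of a full matrix
#'
#' @param spaces An `orbital_space`.
#' @param k Full `n_mo x n_mo` matrix.
#' @return Entries of `k` at the nonredundant rotation pairs.
#' @export
pack_rotation <- function(spaces, k) {
  k[spaces$rotation_pairs]
}

#' Rotate orbitals by the exponential map
#'
#' Applies `C <- C exp(K)` with K the antisymmetric generator unpacked
#' from `kappa`; the exponential is evaluated through the spectral
#' decomposition of K so the rotation is orthogonal to machine precision
#' and S-orthonormality is preserved exactly.
#'
#' @param spaces An `orbital_space`.
#' @param kappa Packed rotation vector.
#' @return A new `orbital_space` with rotated coefficients.
#' @export
rotate_orbitals <- function(spaces, kappa) {
  if (any(!is.finite(kappa))) stop("kappa must be finite", call. = FALSE)
  if (spaces$n_rot == 0L || max(abs(kappa)) == 0) {
    u <- diag(spaces$n_mo)
  } else {
    u <- expm_antisym(unpack_rotation(spaces, kappa))
  }
  out <- spaces
  out$mo_coeff <- spaces$mo_coeff %*% u
  out
}
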