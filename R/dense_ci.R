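# Dense active-space Hamiltonian assembled determinant pair by determinant
# pair through the Slater-Condon rules over spin orbitals.  This is an
# intentionally independent code path from the string-driven sigma build
# and serves as its cross-check (and as the exact-diagonalization route on
# small fixtures).  Capped at modest dimensions to stay desk-scale.

# spin-orbital occupation of a determinant: alpha orbital u -> u,
# beta orbital u -> n_act + u; returned sorted.
spin_orb_occ <- function(oa, ob, n_act) sort(c(oa, n_act + ob))

# parity of the permutation aligning occI (holes replaced by particles)
# with its sorted order
align_sign <- function(occ_new) {
  inv <- 0L
  k <- length(occ_new)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      inv <- inv + sum(occ_new[(i + 1L):k] < occ_new[i])
    }
  }
  if (inv %% 2L == 0L) 1 else -1
}

# Mulliken-notation spatial integral lookup for spin orbitals
so_spatial <- function(p, n_act) ifelse(p > n_act, p - n_act, p)
so_spin <- function(p, n_act) p > n_act

#' Dense active-space Hamiltonian (Slater-Condon construction)
#'
#' Builds the full determinant-basis Hamiltonian matrix explicitly.  This
#' route is independent of [sigma_apply()] and is intended for small
#' spaces (dimension capped at 4000).
#'
#' @inheritParams sigma_apply
#' @param basis A `det_basis`.
#' @return Dense symmetric `dim x dim` matrix in alpha-major determinant
#'   order (alpha string index fastest).
#' @export
dense_active_hamiltonian <- function(active_h, active_eri, basis) {
  if (basis$dim > 4000) {
    stop("dense Hamiltonian capped at dimension 4000 (requested ",
         basis$dim, ")", call. = FALSE)
  }
  n <- basis$n_act
  dets <- vector("list", basis$dim)
  idx <- 0L
  for (ib in seq_len(basis$n_str_b)) {
    for (ia in seq_len(basis$n_str_a)) {
      idx <- idx + 1L
      dets[[idx]] <- spin_orb_occ(basis$strings_a[, ia],
                                  basis$strings_b[, ib], n)
    }
  }
  g <- active_eri
  h <- active_h
  two <- function(p, q, r, s) {
    # <pq|rs> physicists = (pr|qs) Mulliken, with spin deltas
    v <- 0
    if (so_spin(p, n) == so_spin(r, n) && so_spin(q, n) == so_spin(s, n)) {
      v <- g[so_spatial(p, n), so_spatial(r, n),
             so_spatial(q, n), so_spatial(s, n)]
    }
    v
  }
  dim <- basis$dim
  hm <- matrix(0, dim, dim)
  for (i in seq_len(dim)) {
    di <- dets[[i]]
    # diagonal
    e <- sum(h[cbind(so_spatial(di, n), so_spatial(di, n))])
    if (length(di) > 1L) {
      for (a in seq_along(di)) {
        for (b in seq_along(di)) {
          if (a < b) {
            p <- di[a]; q <- di[b]
            e <- e + two(p, q, p, q) - two(p, q, q, p)
          }
        }
      }
    }
    hm[i, i] <- e
    if (i == dim) break
    for (j in (i + 1L):dim) {
      dj <- dets[[j]]
      holes <- setdiff(di, dj)
      parts <- setdiff(dj, di)
      nex <- length(holes)
      if (nex > 2L) next
      if (nex == 1L) {
        a <- holes; b <- parts
        if (so_spin(a, n) != so_spin(b, n)) next
        occ_new <- di
        occ_new[occ_new == a] <- b
        sgn <- align_sign(occ_new)
        v <- h[so_spatial(a, n), so_spatial(b, n)] *
          (so_spin(a, n) == so_spin(b, n))
        for (q in setdiff(di, a)) {
          v <- v + two(a, q, b, q) - two(a, q, q, b)
        }
        hm[i, j] <- hm[j, i] <- sgn * v
      } else if (nex == 2L) {
        a1 <- holes[1L]; a2 <- holes[2L]
        b1 <- parts[1L]; b2 <- parts[2L]
        occ_new <- di
        occ_new[occ_new == a1] <- b1
        occ_new[occ_new == a2] <- b2
        sgn <- align_sign(occ_new)
        v <- two(a1, a2, b1, b2) - two(a1, a2, b2, b1)
        hm[i, j] <- hm[j, i] <- sgn * v
      }
    }
  }
  hm
}
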