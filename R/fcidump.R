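# FCIDUMP interchange: free-format, Molpro-style &FCI header, records
# "value i j k l" with 1-based indices in Mulliken order.  Zero indices mark
# one-electron records (k = l = 0) and the scalar/nuclear record (all zero).
# ORBSYM/ISYM are read and ignored; orbitals are assumed orthonormal, so the
# overlap of the returned set is the identity.

#' Read an FCIDUMP integral file
#'
#' @param path Path to an FCIDUMP file.
#' @return An [integral_set()] with dense ERI storage; `overlap` is the
#'   identity.  All eight permutational images of each two-electron record
#'   are populated.
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  header_end <- grep("(&END|/|\\$END)\\s*$", toupper(trimws(txt)))[1L]
  if (is.na(header_end) || !grepl("&FCI", toupper(txt[1L]), fixed = TRUE)) {
    stop("format error: missing &FCI ... &END header in ", path,
         call. = FALSE)
  }
  header <- paste(txt[seq_len(header_end)], collapse = " ")
  get_field <- function(name) {
    m <- regmatches(header,
                    regexpr(paste0(name, "\\s*=\\s*-?[0-9]+"), header,
                            ignore.case = TRUE))
    if (length(m) == 0L) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  n_orb <- get_field("NORB")
  n_elec <- get_field("NELEC")
  if (is.na(n_orb) || is.na(n_elec)) {
    stop("format error: header must declare NORB and NELEC", call. = FALSE)
  }

  body <- txt[-seq_len(header_end)]
  body <- body[nzchar(trimws(body))]
  np <- pair_dim(n_orb)
  m <- matrix(0, np, np)
  seen2 <- matrix(FALSE, np, np)
  h <- matrix(0, n_orb, n_orb)
  seen1 <- matrix(FALSE, n_orb, n_orb)
  e_nuc <- 0

  for (line in body) {
    f <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(f) != 5L) {
      stop("format error: expected 'value i j k l', got: ", line,
           call. = FALSE)
    }
    val <- as.numeric(f[1L])
    idx <- as.integer(f[2:5])
    if (anyNA(c(val, idx))) stop("format error: unparsable record: ", line,
                                 call. = FALSE)
    nz <- idx[idx != 0L]
    if (any(nz < 1L | nz > n_orb)) {
      stop("format error: index out of 1..", n_orb, " in record: ", line,
           call. = FALSE)
    }
    if (all(idx == 0L)) {
      e_nuc <- val
    } else if (idx[3L] == 0L && idx[4L] == 0L) {
      if (any(idx[1:2] == 0L)) {
        stop("format error: partial one-electron indices in record: ", line,
             call. = FALSE)
      }
      i <- idx[1L]; j <- idx[2L]
      if (seen1[i, j] && abs(h[i, j] - val) > 1e-12 * max(1, abs(val))) {
        stop("duplicate conflicting one-electron record for indices (",
             i, ",", j, ")", call. = FALSE)
      }
      h[i, j] <- h[j, i] <- val
      seen1[i, j] <- seen1[j, i] <- TRUE
    } else if (all(idx != 0L)) {
      ij <- pair_index(idx[1L], idx[2L])
      kl <- pair_index(idx[3L], idx[4L])
      if (seen2[ij, kl] && abs(m[ij, kl] - val) > 1e-12 * max(1, abs(val))) {
        stop("duplicate conflicting two-electron record for indices (",
             paste(idx, collapse = ","), ")", call. = FALSE)
      }
      m[ij, kl] <- m[kl, ij] <- val
      seen2[ij, kl] <- seen2[kl, ij] <- TRUE
    } else {
      stop("format error: mixed zero/nonzero indices in record: ", line,
           call. = FALSE)
    }
  }
  integral_set(h_core = h, eri = as_eri_pair(m, n_orb), n_elec = n_elec,
               e_nuc = e_nuc)
}

#' Write an integral set to an FCIDUMP file
#'
#' Emits only canonical unique integrals (8-fold symmetry reduced) with
#' deterministic ordering and 17 significant digits, so that
#' `read_fcidump(write_fcidump(x))` reproduces `x` exactly.  A
#' Cholesky-backed set is reconstructed to its dense representation first.
#'
#' @param integrals An [integral_set()].
#' @param path Output file path.
#' @param tol Magnitude below which integrals are not written.
#' @return Invisibly, `path`.
#' @export
write_fcidump <- function(integrals, path, tol = 0) {
  stopifnot(inherits(integrals, "integral_set"))
  n <- integrals$n_orb
  eri <- integrals$eri
  if (inherits(eri, "cholesky_factor")) {
    eri <- cd_reconstruct(eri)
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(
    sprintf("&FCI NORB=%d,NELEC=%d,MS2=0,", n, integrals$n_elec),
    paste0(" ORBSYM=", paste(rep("1", n), collapse = ","), ","),
    " ISYM=1,",
    "&END"), con)
  fmt <- function(v, i, j, k, l) sprintf("%.17e %d %d %d %d", v, i, j, k, l)
  tab <- pair_table(n)
  np <- nrow(tab)
  lines <- character(0)
  for (ij in seq_len(np)) {
    for (kl in seq_len(ij)) {
      v <- eri[ij, kl]
      if (abs(v) > tol) {
        lines <- c(lines, fmt(v, tab[ij, 1L], tab[ij, 2L],
                              tab[kl, 1L], tab[kl, 2L]))
      }
    }
  }
  for (ij in seq_len(np)) {
    v <- integrals$h_core[tab[ij, 1L], tab[ij, 2L]]
    if (abs(v) > tol) lines <- c(lines, fmt(v, tab[ij, 1L], tab[ij, 2L], 0L, 0L))
  }
  lines <- c(lines, fmt(integrals$e_nuc, 0L, 0L, 0L, 0L))
  writeLines(lines, con)
  invisible(path)
}
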