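# Spherical-harmonic basis-function accounting for common Gaussian basis
# sets.  Each entry lists the contracted shell composition per element; a
# shell of angular momentum l contributes 2l + 1 spherical functions.

# shells given as counts of (s, p, d, f) contracted shells
.basis_shells <- list(
  "cc-pvdz" = list(
    H = c(s = 2L, p = 1L, d = 0L, f = 0L),
    C = c(s = 3L, p = 2L, d = 1L, f = 0L),
    N = c(s = 3L, p = 2L, d = 1L, f = 0L),
    O = c(s = 3L, p = 2L, d = 1L, f = 0L),
    S = c(s = 4L, p = 3L, d = 1L, f = 0L)
  ),
  "cc-pvtz" = list(
    H = c(s = 3L, p = 2L, d = 1L, f = 0L),
    C = c(s = 4L, p = 3L, d = 2L, f = 1L),
    N = c(s = 4L, p = 3L, d = 2L, f = 1L),
    O = c(s = 4L, p = 3L, d = 2L, f = 1L),
    S = c(s = 5L, p = 4L, d = 2L, f = 1L)
  ),
  "6-31g" = list(
    H = c(s = 2L, p = 0L, d = 0L, f = 0L),
    C = c(s = 3L, p = 2L, d = 0L, f = 0L),
    N = c(s = 3L, p = 2L, d = 0L, f = 0L),
    O = c(s = 3L, p = 2L, d = 0L, f = 0L),
    S = c(s = 4L, p = 3L, d = 0L, f = 0L)
  )
)

.shell_sizes <- c(s = 1L, p = 3L, d = 5L, f = 7L)  # 2l + 1

#' Count spherical-harmonic basis functions for a molecular formula
#'
#' Returns the number of basis functions N_b a molecule has in a named
#' Gaussian basis set using spherical harmonics (each shell of angular
#' momentum l counts 2l + 1 functions).  For example, pyridine (C5H5N) in
#' cc-pVTZ has 250 functions.
#'
#' @param formula Named integer vector mapping element symbols to atom
#'   counts, e.g. `c(C = 5, H = 5, N = 1)`.
#' @param basis Basis-set name: `"cc-pVDZ"`, `"cc-pVTZ"` or `"6-31G"`
#'   (case-insensitive).
#' @return Integer basis-function count.
#' @examples
#' count_spherical_basis_functions(c(C = 5, H = 5, N = 1), "cc-pVTZ")  # 250
#' @export
count_spherical_basis_functions <- function(formula, basis) {
  key <- tolower(basis)
  if (!key %in% names(.basis_shells)) {
    stop("unknown basis set '", basis, "'; available: ",
         paste(names(.basis_shells), collapse = ", "), call. = FALSE)
  }
  table <- .basis_shells[[key]]
  elements <- names(formula)
  if (is.null(elements) || any(!nzchar(elements))) {
    stop("formula must be a named element -> count vector", call. = FALSE)
  }
  missing <- setdiff(elements, names(table))
  if (length(missing) > 0L) {
    stop("element(s) not tabulated for ", basis, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  total <- 0L
  for (el in elements) {
    per_atom <- sum(table[[el]] * .shell_sizes[names(table[[el]])])
    total <- total + as.integer(formula[[el]]) * per_atom
  }
  as.integer(total)
}
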