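---
title: "Methods: norm-extended CASSCF on Cholesky-decomposed integrals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: norm-extended CASSCF on Cholesky-decomposed integrals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascd)
```

## The wave-function model

CASSCF partitions the molecular orbitals into *internal* (always doubly
occupied), *active* (unrestricted occupation) and *external* (always empty)
classes, and minimizes the energy simultaneously over the full-CI expansion
in the active space and over orbital rotations.  Two parametrizations make
the optimization well posed:

* **CI part.**  The wave function is `|ψ(c)⟩ ∝ |0⟩ + P|c⟩` with
  `P = 1 − |0⟩⟨0|` projecting the correction onto the orthogonal complement
  of the current expansion point (CEP) `|0⟩`; the component of `c` along
  the CEP is redundant and is removed everywhere (CI gradients, trial
  vectors, steps).
* **Orbital part.**  `C ← C exp(κ)` with `κ` antisymmetric and restricted
  to the nonredundant inter-class blocks; the packed rotation vector has
  `N_rot = n_int·n_act + n_int·n_ext + n_act·n_ext` entries.
  Internal–internal and active–active rotations leave the energy invariant
  (the latter because the active CI is full), which the suite verifies
  numerically.

The energy is assembled from the inactive Fock matrix
`F^I = h + Σ_i (2(pq|ii) − (pi|iq))`, the inactive energy
`E_i = Σ_i (h_ii + F^I_ii) + E_nuc`, the active one- and two-body reduced
density matrices `γ`, `Γ` (spin-traced convention
`Γ_uvxy = ⟨E_uv E_xy − δ_vx E_uy⟩`), and the active ERIs:
`E = E_i + Σ γ_uv F^I_uv + ½ Σ Γ_uvxy (uv|xy)`.  First derivatives are the
projected CI gradient `g_ci = 2P(H − E)|0⟩` and the packed orbital gradient
`g_pq = 2(F_pq − F_qp)` built from the generalized Fock matrix with internal
rows `2(F^I + F^A)`, active rows `γF^I + Q`, `Q_up = Σ Γ_uvxy (pv|xy)`, and
zero external rows.  The overall sign convention is pinned by central finite
differences of the energy, which the test suite checks on every fixture; the
same oracle arbitrates the one-index-transform convention in the Hessian.

## The second-order step

The trust-region step is the lowest eigenvector of the gradient-scaled
bordered Hessian `L(α)`; rescaling its body by the border component and α
gives the step, which is a level-shifted Newton step with the shift equal to
the (non-positive) lowest eigenvalue of `L(α)`.  At `α = 1` and small
gradients the shift is `O(‖g‖²)`, so quadratic convergence is preserved;
raising α shrinks the step monotonically, and the step-length equation
`‖x(α)‖ = R_t` is solved by safeguarded log-bisection (relative tolerance
`1e-3`) on the current subspace, where every evaluation is a small dense
eigenproblem.

The eigenproblem itself is solved matrix-free: the four Hessian blocks act
as

* configuration–configuration: `2P(H − E₀)P` through the string-driven
  sigma build;
* orbital ← configuration: the transition gradient, i.e. the generalized
  Fock contraction evaluated with symmetrized transition density matrices
  between `|0⟩` and the projected trial vector (the inactive-row `F^I`
  contribution drops because the transition "inactive occupation" is zero);
* configuration ← orbital: the one-index-transformed active Hamiltonian
  (`F̃^I` active block plus transformed active ERIs) applied to `|0⟩` and
  projected;
* orbital–orbital: the gradient-like contraction of the one-index
  transformed Fock set plus the commutator correction `−½[A, κ]` with
  `A` the antisymmetric gradient matrix, which follows from symmetrizing
  the double-commutator expansion of the exponential and makes the map
  exactly symmetric (verified to `1e-10` on random vectors and against a
  double-finite-difference dense Hessian).

The subspace grows with configuration-only or orbital-only preconditioned
residuals — whichever part of the bordered residual is larger — which keeps
the two very differently scaled parameter sets from polluting each other's
preconditioning.  Preconditioners are `2(H_diag − E₀)` for the CI part and a
Fock-difference estimate `2(n_q − n_p)(F_pp − F_qq)` (occupations
`2/γ_uu/0`), floored at `0.05` hartree, for the orbital part.

One design choice deserves emphasis: **the CI problem is re-solved by
Davidson at every CEP**, warm-started from the step-updated CI vector, so
the CEP is always the ground state of the current active Hamiltonian and
the CI gradient at the CEP sits at the solver tolerance.  The NEO step still
couples the blocks through the full Hessian (the orbital step carries the
CI response), so quadratic convergence of the orbital gradient is retained;
what is given up is only the ability to converge onto excited CI roots,
which is out of scope here.  Consequently the microiteration tolerance is
tied to the larger of the two RMS gradient norms,
`tol_micro = max(1e-2 · max(rms g_orb, rms g_ci), 1e-10)` — tying it to the
smaller one would slave every micro solve to the already-converged CI
gradient.

Trust-radius policy (constants are conventional, exposed in
`trust_region_policy()`): start `R_t = 0.5`, bounds `[1e-4, 1]`; an energy
increase rejects the step and halves `R_t`; otherwise the
predicted/actual ratio `r` expands the radius by 1.2 for `r > 0.75`,
shrinks it by 0.7 for `r < 0.25`, and leaves it otherwise.  Accepted
macroiterations therefore descend strictly; an accepted energy rise is
trapped as an internal error.  The CI phase is fixed after each solve
(largest coefficient positive) to stabilize transition-RDM signs between
macroiterations.

## Cholesky machinery

The decomposition acts on the pair matrix over canonical lower-triangular
orbital pairs with full greedy pivoting on the residual diagonal.  Stopping
at threshold δ certifies `max |(pq|rs) − Σ L^K_pq L^K_rs| ≤ δ`
(Cauchy–Schwarz).  Numerical policy: residual diagonal entries in
`[−1e-10, 0)` are clipped to zero as roundoff; anything below `−1e-10` is a
hard error identifying the pivot (non-PSD input); `δ = 0` requests an
exact factorization and stops at a relative floor of `1e-12` times the
initial diagonal maximum so that accumulated roundoff is not factorized
into noise vectors.  Pivot-order differences can change the vector count by
a few, so the compression factor `f = N_b(N_b+1)/(2 N_ch)` is treated as a
diagnostic, never as an exact target.

MO transformation maps each vector independently (`L ← CᵀLC`), preserving
symmetry and the reconstruction guarantee; Fock, `Q` and all transformed
intermediates are per-vector contractions, so sums over vectors commute and
each vector could be processed independently.  Orbital trial vectors enter
through `L̃ = [L, κ]` (still symmetric), and the transformed Fock set
(`h̃`, `F̃^I`, `F̃^A`, `Q̃`, transformed active ERIs) follows by the product
rule over `(L, L̃)` pairs; the suite checks this pathway against a dense
one-index-transformed contraction to `1e-9`.

The default decomposition threshold is `1e-4`, and the convergence
criterion is RMS(g) `< 1e-7` for both gradient parts, with
RMS(v) = ‖v‖₂/√dim applied to each part separately (dimension-robust, since
the CI and orbital parts have very different lengths).

## Starting guesses

`restricted_scf` is a DIIS Roothaan solver over the same Cholesky
Coulomb/exchange builds.  The production guess follows the UNO protocol:
diagonalize the triplet stability matrix
`H_ia,jb = δδ(ε_a − ε_i) − (ij|ab) − (ib|ja)` (matrix-free through the
Cholesky vectors, Davidson for large rotation spaces, dense spectrum below
400 rotations so that *all* unstable directions are available); perturb the
orbitals along each negative eigenvector with opposite angles for the two
spins and converge an unrestricted SCF; form the charge density averaged
with equal weights over the distinct unrestricted solutions (an option
follows only the strongest instability); diagonalize it for natural
orbitals; and select as active the orbitals with occupation strictly inside
the window, default `(0.01, 1.99)`, with the active electron count the
rounded sum of the selected occupations.  The default symmetry-breaking
angle is 0.2 rad; because DIIS can relax a weakly perturbed determinant
back into the restricted saddle point, the angle escalates automatically
(0.4, 0.8, 1.2 rad) until the unrestricted energy actually drops, and a
solution that still collapses is reported and skipped.  On the Hubbard
dimer this machinery is exactly solvable: instability eigenvalue `2t − U`,
UNO occupations `1 ± 2t/U`.

## What the model systems do and do not emulate

The generators produce exactly representable physics with closed-form
references: Hubbard chains (diagonal pair matrix, known dimer spectrum),
PPP π systems (Ohno two-center repulsion with core attraction, benzene
ring and polyene chains), and seeded random low-rank ERI fixtures whose
pair-matrix spectrum decays geometrically — the only fixture class where
threshold truncation actually discards information, used for the
CD-threshold control checks.  They share the PSD pair-matrix structure,
the orbital-class coupling and the determinant combinatorics of molecular
CASSCF, but not the near-linear-dependence patterns of large Gaussian
basis sets, point-group degeneracies beyond the ring models, or
basis-set-scale Cholesky ranks; passing tests therefore demonstrate
algorithmic correctness and error control, not molecular-scale
performance.  Reproducing published molecular energies additionally
requires AO integrals from an external integral backend (ingested via
FCIDUMP), which no test here supplies.

Problem sizes in the suite were chosen desk-scale: up to 8 orbitals for
random fixtures, CAS(4,4)–CAS(6,6) determinant spaces (dimension ≤ 400),
and double-finite-difference Hessians on a 9-parameter fixture.  Energy
surfaces of active-space models generically carry several stationary
points; the convergence tests distinguish fixtures with a unique minimum
(the benzene CAS(4,4) ring) from those where different guesses legitimately
reach different stationary points, and the optimizer's contract is
convergence to the *closest* local minimum with monotone descent.

## Known limitations

Ground-state, Sz-conserving determinant CI only (singlet purity is
monitored via ⟨S²⟩, not enforced); no state averaging or excited-state
optimization; no point-group symmetry exploitation; no frozen core (all
orbitals, core included, are variationally optimized); integral generation
for Gaussian basis sets is delegated to external producers of FCIDUMP
files; and the dense-Hamiltonian oracle is capped at determinant dimension
4000 by design.
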