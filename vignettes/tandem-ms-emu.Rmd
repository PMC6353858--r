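---
title: "Simulating and correcting tandem MS data for 13C-MFA: methods"
author: "tandemEMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and correcting tandem MS data for 13C-MFA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemEMU)
```

## The measurement model

In ¹³C metabolic flux analysis, a cell culture is fed a positionally
¹³C-labeled substrate; at isotopic steady state every metabolite pool
carries a labeling pattern determined by the fluxes through the network.
Tandem MS selects a parent ion, fragments it, and records the mass of a
daughter ion, so the raw observable is a joint distribution over
(daughter mass shift m, parent mass shift M). Because the daughter is part
of the parent, cells with M < m, or with more label in the complement
(the parent minus the daughter) than the complement can hold, are
impossible. Shifting row m of that matrix left by m removes exactly these
cells and yields the **compact tandem MS matrix** `T[m, k]`, indexed by the
daughter shift m = 0..d and the complement shift k = 0..c, with M = m + k.
`compactTandemMatrix()` / `tandemMSMatrix()` implement the two forms and
`toCompact()` / `toFull()` the loss-free conversion; for a parent of four
carbons with a two-carbon daughter the full matrix is 3×5 and the compact
matrix 3×3.

All matrices in this package are fractional distributions (they sum to 1).
Intensity-space arithmetic, per-scan noise models and detector effects are
out of scope: the package starts where a normalized spectrum ends.

## Simulation by 2D-convolution

Labeling of independent atoms adds in mass-shift space, so a fragment's
matrix is the 2D discrete convolution of per-atom matrices: an atom's
isotope vector enters as a column (along the daughter axis) if the atom is
in the daughter fragment and as a row (along the complement axis)
otherwise (`conv2Atom()`). Convolution is commutative, so the atom order
is irrelevant; the test suite checks this property explicitly. Collapsing
the matrix to its parent marginal recovers the classical 1D MID
convolution, which is how the 2D machinery is validated against the 1D
one.

Core carbon atoms get tracer-defined vectors `[1 − p, p]` (purity p at
labeled positions). Unlabeled positions follow one of two **background
modes**: `"natural"` (the natural carbon isotope vector; the default,
realistic for biological material) or `"pure"` (exact ¹²C; useful for
didactic examples and for tests whose expected values must be exact
products of purities). Derivatization and heteroatoms are handled by the
fragment specification: from the parent and daughter elemental formulas
and the core-carbon bookkeeping, `otherAtomFormulas()` derives the
daughter's non-core formula Q and the complement's non-core formula S, and
`simulateMeasured()` convolves their natural-abundance MIDs onto the core
matrix. For the TBDMS-derivatized aspartate fragment pair m/z 418 > 244,
Q = C8H22O2NSi2 and S = C6H18O2Si.

The shipped isotope table (`extdata/isotopes.csv`) holds standard natural
abundances for C, H, N, O, Si, S; each element's vector must sum to 1
within 1e-9. Any table can be substituted (`readIsotopeTable()`), which is
also the extension point for further elements.

## Correction by 2D-deconvolution

Correction inverts the Q/S convolution. We deliberately do **not** divide
in the frequency domain: measured windows are truncated (an instrument
records a handful of mass shifts, not the ~40-shift support of a TBDMS
fragment) and spectral division can neither express truncation nor resist
noise amplification. Instead `correctTandem()` builds the truncated
lower-triangular Toeplitz operators C_Q ((d_meas+1) × (d_core+1)) and C_S
((c_meas+1) × (c_core+1)) whose columns are the shifted Q/S MIDs, and
solves

    min_X || C_Q · X · C_S' − M ||_F

as a linear least-squares problem via the QR factorization of
`kronecker(C_S, C_Q)`. When the measured window covers the full support
this is an exact inverse (the round-trip identity holds to 1e-10 on random
core matrices); when the window is truncated, the missing masses are
treated as unobserved rows and a warning reports the natural-abundance
weight lost. The leading entry of every operator column is the
monoisotopic abundance (> 0), so the operators have full column rank; rank
deficiency is still checked and reported.

Non-negativity is *not* imposed inside the solve — that would bias the
round-trip identity — so noisy data can produce small negative entries.
`clipAndRenormalize()` makes the cleanup explicit: entries in
[floor, 0) are zeroed with a warning, entries below the floor (default
−1e-3) raise an error because a violation that large indicates an
inconsistent fragment specification rather than noise.

## EMU decomposition with daughter-atom tracking

An elementary metabolite unit (EMU) is an atom subset of a metabolite
whose labeling suffices to simulate a measurement. For tandem MS the state
must also record *which* of the EMU's atoms sit in the daughter fragment,
so the state variable here is the triple (metabolite, atom set, daughter
subset) — `tandemEMU()` — and its value is a compact tandem MS matrix.

`decomposeTandem()` traces the target backwards breadth-first: for every
reaction producing the EMU's metabolite, the product atoms are mapped to
educt atoms through the reaction's atom-transition labels. Unimolecular
and cleavage reactions transfer the atom set (and its daughter marks) to
one educt; condensation reactions split it across educts, each inheriting
its own atoms' marks. EMUs are deduplicated by their full identity. One
convention removes redundant state: an EMU whose daughter set is its whole
atom set carries exactly the transposed matrix of the same EMU with an
empty daughter set, so such EMUs are stored once in complement orientation
and transposed at the point of use (`eductTransposed` on each EMU
reaction). This is why size-1 EMUs appear without daughter masks in the
decomposition listing, matching the usual presentation.

With an empty daughter set the decomposition degenerates to the classic
MID-only EMU decomposition — the test suite verifies this against an
independently written classic decomposer.

## Cascade solve

`solveCascade()` groups unknown EMUs by (size, daughter-atom count); all
members of a group share the matrix shape (d+1) × (k+1). Groups are solved
in increasing size: condensation educts are strictly smaller than their
product, and unimolecular transfers preserve the shape, so dependencies
never point upward. Per group the steady-state balances form `A·X = B·Y`:
`A[u,u]` accumulates minus the total flux producing EMU u, `A[u,e]` adds
the flux for each same-group educt e, and known contributions (input EMUs
and condensation products, the latter computed by 2D-convolution of the
educt matrices) accumulate on the right-hand side. Matrices are flattened
row-major (daughter index outer) into rows of X and Y — the fixed
flattening also defines the file I/O layout. The dense LU solve is guarded
by a reciprocal-condition estimate (error when rcond < 1e-12, e.g. for an
all-zero flux map); each solved matrix must come back normalized within
1e-9 and is then renormalized exactly. Because the balances are
homogeneous of degree one in the fluxes, scaling all fluxes leaves every
solution unchanged — a property test pins this down.

## The brute-force oracle

`simulateIsotopomers()` solves the same steady state in the uncompressed
isotopomer basis (2^n states per metabolite, capped at 12 carbons). The
condensation terms make the balance bilinear, so the solver iterates the
flux-weighted mixing map from the unlabeled state (Jacobi fixed point,
tolerance 1e-12, cap 10,000 iterations, no damping needed at the exchange
ratios of the packaged network). It shares no code with the EMU path —
marginals are taken by explicit bit enumeration — which makes
`verifyAgainstOracle()` a genuine cross-check: on the packaged network it
compares every (parent, daughter) pair up to 3 atoms of every metabolite
(114 EMU targets) and agrees with the cascade to better than 1e-9.

## The packaged study conditions

The fixture module defines the worked conditions once:

* **Network**: the five-reaction example network (A→B, B↔D, B→C+E,
  B+C→D+E+E, D→F), input A, outputs E and F. Atom labels are single
  lowercase letters scoped per reaction line (ample at ≤ 26 carbons per
  line for this domain).
* **Fluxes**: the figure source for this network does not print numeric
  fluxes, so `exampleFluxes()` *constructs* a steady-state map from the
  stoichiometric constraints with the input normalized to 100 and the two
  remaining degrees of freedom set to branch = 20 and exchange = 50 —
  values giving substantial flow through both the reversible isomerization
  and the cleavage/condensation loop, i.e. a regime in which tandem data
  are actually informative. The resulting map is
  {v1 = 100, v2f = 110, v2b = 50, v3 = 20, v4 = 20, v5 = 80}.
* **Tracers**: [2-¹³C]A at 100% purity with pure background (didactic
  setting for the network simulations), and [1,4-¹³C]aspartate at 99%
  purity for the correction workflow.
* **Fragment**: the aspartate 418 > 244 TBDMS pair described above.

`generateFixtures()` writes these as plain-text files with an MD5 manifest
and is byte-identical across runs. What the generator does *not* emulate:
measurement noise, detector saturation, imperfect fragmentation, or
chromatographic interference. Green tests therefore demonstrate the
correctness of the algebra (simulation, correction, balancing, fitting) on
exact distributions, not robustness to real instrument error — the
explicit truncation handling and the clipping step are the two places
where real-data pathologies surface, and they are tested with synthetic
truncation and synthetic negatives.

## Flux fitting

`fitFluxes()` is a minimal estimator meant for parameter-recovery tests,
not a full MFA workbench. With the input flux fixed at 100, the example
network retains exactly two degrees of freedom: the branch flux and the
exchange flux of the reversible reaction (the reversible reaction's net
flux is determined by the branch flux through the B balance, so it is not
an independent parameter). A bounded Levenberg–Marquardt solver
(minpack.lm) minimizes the unweighted entrywise residual between measured
and simulated compact matrices; flux maps whose derived fluxes go negative
return a large penalty residual instead of erroring, so the solver can
retreat from a bad step (a solver *started* deep in the infeasible region
sits on the flat penalty plateau — that is inherent to smooth local
optimization and the tests document it). Identity measurement weights are
a deliberate simplification; no χ² machinery or confidence intervals
beyond the local linearization in `fluxStandardErrors()`, which exists to
quantify how much the joint (tandem) measurement tightens flux precision
over the parent MID alone.

## Numerical conventions

* Normalization tolerance 1e-9 everywhere a distribution is asserted.
* Infeasible-cell tolerance 1e-9 in the full→compact conversion; smaller
  values are silently zeroed.
* Deconvolution: QR least squares; rank and (for the cascade) rcond
  guards; renormalization after the solve.
* Condensations with more than two educts reduce to pairwise
  2D-convolutions in a deterministic order (metabolite id, then atom
  indices).
* All file output prints 12 significant digits so CSV round trips are
  exact at working precision.

## Problem sizes

The full test suite (364 assertions) runs in ~7 s on one CPU: the oracle
sweep covers all ≤ 3-atom EMUs of the 6-metabolite network, the correction
round trip runs 100 random matrices through the 42 × 33 aspartate forward
model, and the flux fit recovers 2 free fluxes from one 3 × 2 target
matrix. These sizes were chosen because they exhaust the structural cases
(every reaction type, every orientation, truncation, transposition) while
keeping the brute-force oracle exact.

## Known limitations

* Steady-state labeling only; no isotopically non-stationary dynamics.
* Single-stage fragmentation only (no MS³ / multiple tandem).
* Fragments are user-specified; no fragmentation prediction.
* Nominal mass-shift space only; no isotopic fine structure or mass
  defects.
* No compartments, cofactor balancing, or thermodynamic feasibility in
  the network model.
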