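---
title: "Quadrupole-dipole resorption: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrupole-dipole resorption: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdrcharges)
```

## The model

A stockholder partition of a material's electron density assigns each
atom A a net charge $q_A$, a dipole vector $\mu_A$, a traceless
quadrupole tensor $\Theta_A$, and overlap populations $\mathrm{OP}_{Ab}$
with nearby atom images $b$. The polyatomic multipole expansion built
from all of these reproduces the electrostatic potential outside the
electron density essentially exactly; a point-charge-only model keeps
just the $q_A$ and pays for it. Quadrupole-dipole resorption (QDR)
re-expands the same multipole content: it moves charges $q_{Ab}$ between
overlapping pairs so that part of the atomic dipoles and quadrupoles is
absorbed into the monopole term, and the residual atomic moments shrink.

Three quantities are conserved *exactly*, by construction, about any
fixed origin: the net charge, the total dipole moment (point charges
plus atomic dipoles), and the total traceless quadrupole moment. For the
dipole-resorption (DR) step this works because the shift dipole
$q_{Ab}(\mathbf r_A - \mathbf r_b)$ generated by each transfer is
removed from the atomic dipoles half on each pair member; the algebra
cancels origin-dependence term by term, so conservation is an identity,
not a constraint we fit. For the quadrupole-resorption (QR) step the
compensating dipole $q_{Ab} R_{Ab} \hat R_{Ab}$ and the removed tensor
$q_{Ab} R_{Ab}^2 (\hat R_{Ab} \hat R_{Ab}^T - I/3)$ both sit on the
receiving atom, with the same cancellation. The package's invariant
suite asserts the triple at $10^{-10}$ a.u. about three different
origins after every stage on every fixture kind.

Hard constraints forcing the point charges to reproduce the molecular
dipole exactly are deliberately absent: they are unsatisfiable for some
geometries (a heteronuclear diatomic in a transverse field), break size
consistency, and ill-condition the equations. Resorption is soft — the
loss balances transfer size against residual moment.

### The loss functions and block systems

With $w_{Ab} = 2\tanh(2\,\mathrm{OP}_{Ab})$, DR minimizes

$$L^{DR} = \sum_{A,b} \frac{(q_{Ab}R_{Ab})^2}{w_{Ab}^2}
 + \sum_A \bigl\| \mu_A + \sum_b q_{Ab} R_{Ab} \hat R_{Ab} \bigr\|^2 .$$

The first term switches transfers off smoothly as the overlap vanishes
($q_{Ab} \propto w_{Ab}^2$ for small OP), which confines the adjustment
to bonded neighbors and makes the charges insensitive to conformational
noise in distant geometry. In the second term each transfer's *full*
pair dipole is credited to the owning atom: the mirrored transfer
$q_{Ba}$ is an independent unknown owned by atom B, and at the optimum
the two flows supply the two halves that the update actually applies.
This accounting is what makes the normal equations decouple into one
small system per atom,

$$M^{(A)} Y^{(A)} = T^{(A)}, \qquad
  M_{bd} = \delta_{bd} + w_{Ab} w_{Ad}\,(\hat R_{Ab} \cdot \hat R_{Ad}),
  \qquad T_b = -w_{Ab}\, (\mu_A \cdot \hat R_{Ab}),$$

with $q_{Ab} = w_{Ab} Y_b / R_{Ab}$. QR is analogous with an extra
$R_{Ab}^2$ in the first term so both terms carry quadrupole units; its
matrix has diagonal $1 + \tfrac23 w_{Ab}^2$ and off-diagonal
$w_{Ab} w_{Ad}\bigl((\hat R_{Ab}\cdot\hat R_{Ad})^2 - \tfrac13\bigr)$,
and its right-hand side is $-w_{Ab}\,\hat R_{Ab}^T \Theta_A \hat R_{Ab}$
(tracelessness of $\Theta_A$ removes the $I/3$ part).

For a two-atom molecule with both dipoles along the bond the DR system
solves in closed form: the resorbed fraction of the bond-projected
dipole is $f = w^2/(1+w^2)$, independent of bond length and dipole
magnitude because the loss is a homogeneous quadratic. This gives
69.88 % at OP = 0.5, 78.80 % at OP = 1, 13.48 % at OP = 0.1, 0.160 % at
OP = 0.01, and $1.6\times10^{-3}$ % at OP = 0.001 — the package's first
acceptance anchor, recomputed (not stored) by
`diatomic_recovery_fraction()`.

### Why QR before DR, and why two passes

QR touches dipoles and quadrupoles only on the receiving atom, and DR
never touches quadrupoles. Running QR first lets DR partly resorb the
compensating dipoles QR created; DR first would leave them stranded
(on a zero-dipole, nonzero-quadrupole input DR does nothing at all — the
suite checks this literally, and a `dr_first` flag exists purely for
that diagnostic). Each pass propagates charge changes roughly one bonded
shell. Two passes reach second neighbors — the atoms involved in bond
angles, which are nearly conformation-invariant — while staying
insensitive to rotatable dihedrals, which involve third neighbors. That
is the transferability argument behind `n_passes = 2` as the default;
1–3 are exposed.

## Solver and numerical choices

* Both block matrices are identity-plus-low-rank ($PP^T$ with 3 columns
  for DR, 5 effective columns for QR), hence symmetric positive definite
  with every eigenvalue in $[1,\,1 + 16\,\mathrm{SOP}_A^2]$ (DR; the QR
  bound carries the $2/3$ Frobenius factor of the traceless projector).
  Conjugate gradients with a zero initial guess therefore terminates in
  at most 4 (DR) / 8 (QR) matrix–vector products, each evaluated
  matrix-free at linear cost. The residual tolerance defaults to
  $10^{-10}$ relative — exact-arithmetic termination makes tightness
  free — and `max_matvecs = 50` exists only to diagnose corrupted
  inputs.
* Eigenvalue clustering in `eigen_diagnostics()` uses a relative gap of
  $10^{-8}$, matching the floating-point spread of the analytically
  degenerate families.
* Block solves are independent per atom and side-effect free; any
  execution order gives bitwise-identical results (the implementation is
  serial, so determinism is trivial, and the contract keeps it so for
  any future parallel schedule).
* Degenerate geometry (two slots with the same direction) needs no
  special-casing: the blocks stay SPD because the identity part never
  leaves.
* Internal units are atomic (bohr, e); files carry Å for coordinates and
  a.u. for moments, with 1 bohr = 0.529177210903 Å. The traceless
  quadrupole convention is the primitive one,
  $\sum q\,(rr^T - r^2 I/3)$; `to_buckingham()` is the exact $3/2$
  rescaling. Mixing the two conventions is the classic pitfall here, so
  the QR update computes the shift-generated tensor explicitly in the
  primitive convention and re-detraces it.

Key defaults (all exposed): pair cutoff sum 10 Å (two 5 Å density
cutoff radii), OP threshold $10^{-4}$ (results are insensitive to it —
omitted terms scale as $w^4$), valid-grid rules
$\rho < 10^{-4}\,e/\mathrm{bohr}^3$, inner 2 Å, outer 5 Å, ESP unit
conversion 627.5094740631 kcal mol⁻¹ e⁻¹ per hartree/e.

### Periodic cells

Pair enumeration covers every image whose distance can fall inside the
cutoff, so cutoffs larger than half the cell simply produce several
images of the same parent atom (the 3 Å single-atom cube with a 10 Å
cutoff is a test case, checked against a brute-force lattice search).
The point-charge ESP of a 3-D periodic cell uses Ewald summation in the
tinfoil gauge with an automatically balanced splitting parameter; it is
validated against the rocksalt Madelung constant (1.7475645946) and
checked for splitting-parameter independence. Periodic potentials carry
an arbitrary additive constant, so `esp_metrics()` offers mean-offset
alignment over valid points (on for periodic comparisons, off
otherwise). Dipole and cloud terms use real-space image sums within a
12 Å cutoff; 1-D and 2-D periodicity are declined by the potential
model, and system multipoles are defined only for nonperiodic systems.

## What the fixtures emulate — and what they do not

The generator produces the *inputs* a partitioning code would hand over:
geometries, charges, dipole vectors, exactly traceless quadrupoles, and
a symmetric OP table. Magnitudes are realistic (the water-like fixture
uses DDEC6-scale values: H 0.388 e, $|\mu_H|$ 0.042, O −0.776,
$|\Theta_O|$ 0.384 a.u.), but the *directions* of the water moments are
generator-defined C2v choices — so the package's water trace shows the
same structural patterns as a real DDEC6 run (quadrupole norms frozen
through DR, zero charges-plus-dipoles dipole error, monotone-ish RMSE
improvement) without claiming to reproduce any published per-step
numbers, which would require the unpublished tensors. Likewise the
rocksalt fixture is the symmetric ideal (all moments zero — QDR is
provably the identity on it), the ring fixture gives coherent radial
dipoles that no point-charge model can mimic (the inside/outside
mean-potential offset of the alternating ring is *exactly* zero for
every charge scaling, a symmetry fact the suite asserts), and the
random fixture exercises the solvers with no symmetry at all. Passing
tests on these fixtures validates the algebra, conservation, locality,
and scaling of the implementation; it says nothing about the chemical
accuracy of any particular partitioning method on real materials, which
is a property of the upstream charges, not of the re-expansion.

Oracle ESP grids are generated from the model's own ground-truth terms,
so closure tests (model reproduces its own grid to $10^{-10}$) separate
grid plumbing from physics. The density grid uses exponential clouds
with $b = 2$ bohr⁻¹ normalized to the electron counts, which lands the
$10^{-4}$ e/bohr³ isosurface between the 2 Å and 5 Å radii so that all
three valid-point rules actually bite.

## Problem sizes

The shipped tests run at desk scale, chosen to finish in seconds while
still being structurally honest: random fixtures of 5–12 atoms (200
seeded repetitions for the solver-contract and spectrum checks, 100 for
the statistical monotonicity checks), grids of roughly 20³–40³ points,
and rocksalt supercells of 8, 64, and 512 atoms for the linear-scaling
check, where pair counts and matrix–vector products must grow by exactly
the volume factor 8 between steps. The acceptance script's diatomic
anchors are closed-form and size-2 by definition.

## Known limitations

* The statistical design goal "moments usually shrink" is exactly that —
  per-instance increases are possible and expected (QR can raise the rms
  atomic dipole before DR claws it back; the suite asserts medians and
  majorities, not instances).
* Overlap populations are inputs; nothing here recomputes them from
  densities, and no importer for any particular partitioning code's
  native output format is provided — the versioned exchange schema is
  the boundary.
* Ewald support is charge-term and 3-D only; mixed periodicity would
  need specialized summation.
* `run_qdr` holds full deep-copy snapshots per stage for auditability;
  at millions of atoms one would stream the trace instead.
* Multiframe (ensemble-fitted) charge variants enter only as labels in
  the merit tables; the package evaluates charge sets, it does not fit
  them to potentials.
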