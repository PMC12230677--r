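# qdrcharges

Atom-centered point charges derived from electron-density partitioning
(DDEC6, Hirshfeld, MBIS, ...) come with residual atom-in-material dipole
and quadrupole moments. A point-charge-only forcefield throws those
moments away, which degrades how well the model reproduces the
electrostatic potential around a molecule or crystal. **qdrcharges**
implements quadrupole-dipole resorption (QDR): it re-expresses part of
each atomic dipole and quadrupole as adjustments to the point charges of
bonded atom pairs, while *exactly* preserving the system's net charge,
total dipole moment, and total traceless quadrupole moment about any
origin. It is a polyatomic multipole re-expansion, not a chemical
correction: the adjusted charges trade residual atomic moments for a more
faithful monopole term.

The package is aimed at forcefield developers and electronic-structure
practitioners who already have stockholder-partitioned charges, dipoles,
quadrupoles, and overlap populations (e.g. from Chargemol-style output)
and want transferable point charges plus the evaluation stack around
them.

## The method

For each atom A and nearby atom image b (within the 10 Å cutoff-radius
sum, or with overlap population OP_Ab ≥ 10⁻⁴), a charge q_Ab is moved
from b to A. Writing w_Ab = 2 tanh(2 OP_Ab), the dipole-resorption (DR)
transfers minimize the convex loss

    L_DR = Σ_{A,b} (q_Ab R_Ab)² / w_Ab²  +  Σ_A ‖ μ_A + Σ_b q_Ab R_Ab R̂_Ab ‖²

whose normal equations decouple into one small symmetric
positive-definite system per atom, M⁽ᴬ⁾ Y⁽ᴬ⁾ = T⁽ᴬ⁾, with
M = I + (rank ≤ 3), so M has at most four distinct eigenvalues, all in
[1, 1 + 16 SOP_A²], and a matrix-free conjugate-gradient solve terminates
in at most four matrix–vector products. Applying the transfers splits
each pair's shift dipole half/half between the two atoms, which is what
preserves the total quadrupole. Quadrupole resorption (QR) is analogous
(C = I + rank ≤ 5, at most eight distinct eigenvalues, eight products;
compensating dipole and quadrupole corrections live entirely on the
receiving atom). One QDR pass is QR then DR — QR first, so the dipoles it
generates can be partly resorbed — and the default 2-pass driver is
QR, DR, QR, DR, confining charge changes to roughly second bonded
neighbors. On a heterodiatomic the DR solve has the closed form
f = w²/(1 + w²) for the resorbed fraction of the bond-projected dipole:
69.9 % at OP = 0.5, 78.8 % at OP = 1, 13.5 % at OP = 0.1.

Around the solver the package provides: molecular multipole summaries and
error statistics under both traceless-quadrupole conventions
(primitive-traceless and Buckingham); grid-based ESP RMSE / RRMSE
(RRMSE = RMSE over the all-zero-charge null model, R² = 1 − RRMSE²) with
the three-rule valid-point mask (ρ < 10⁻⁴ e/bohr³, farther than 2 Å from
every atom, within 5 Å of some atom); point-charge, atomic-dipole, and
exponential cloud-penetration potential terms with Ewald summation for
3-D periodic cells; Gaussian cube and versioned exchange-file I/O;
conformational-ensemble figures of merit (rms charge transfer,
conformational sensitivity, method correlation/confluence); and a
synthetic-fixture generator that makes the whole stack testable offline.

## Worked example

```r
library(qdrcharges)

p <- make_fixture("water_like")      # DDEC6-like magnitudes, C2v geometry
tr <- run_qdr(p, n_passes = 2)
trace_report(tr)[, c("step", "q1", "q3", "rms_atomic_dipole", "mol_dipole_err_q")]
#>          step    q1     q3 rms_atomic_dipole mol_dipole_err_q
#> 1    Starting 0.388 -0.776            0.0857           0.1875
#> 2 After QR #1 0.369 -0.737            0.1021           0.2302
#> 3 After DR #1 0.437 -0.874            0.0442           0.0791
#> 4 After QR #2 0.428 -0.857            0.0498           0.0980
#> 5 After DR #2 0.457 -0.913            0.0332           0.0349
```

The H/O charges move from ±0.388/−0.776 to ±0.457/−0.913 while the rms
atomic dipole falls from 0.086 to 0.033 a.u. and the point-charge model's
molecular dipole error falls from 0.19 to 0.035 a.u. (the
charges-plus-dipoles model reproduces the molecular dipole exactly at
every step — that column stays 0). Against a synthetic reference
potential generated from the input charges *and* atomic dipoles:

```r
g    <- make_oracle_grids(p, spacing = 0.5, terms = c("charges", "atomic_dipoles"))
mask <- valid_grid_mask(g$density, p)
pts  <- grid_points(g$esp)
esp_metrics(model_potential(p, pts, "charges"), g$esp$values, mask)
#> esp_metrics: RMSE 1.1603 kcal/mol/e, RRMSE 0.1774, R^2 0.9685 (4554 valid points)
esp_metrics(model_potential(tr$final, pts, "charges"), g$esp$values, mask)
#> esp_metrics: RMSE 0.2236 kcal/mol/e, RRMSE 0.0342, R^2 0.9988 (4554 valid points)
```

so the resorbed charges cut the point-charge ESP error about fivefold on
this fixture.

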