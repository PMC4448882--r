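---
title: "Least-squares refinement of small-molecule crystal structures: models, restraints and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-squares refinement of small-molecule crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microrefine)
```

# The refinement model

A crystal-structure refinement fits a parametric model of the electron
density to observed diffraction amplitudes by minimising

$$ M \;=\; \sum_h w_h \,\bigl(Y_o(h) - Y_c(h)\bigr)^2, $$

where $Y$ is either $|F|$ or $|F|^2$ and the sum runs over the measured
reflections. This package refines against $F^2$ by default (the natural
scale of measured intensities) with weights $w = 1/\sigma^2(Y_o)$; a
unit-weight option exists, and refinement on $F$ obtains $|F_o| =
\sqrt{\max(F_o^2, 0)}$ with $\sigma(F) = \sigma(F^2)/(2F)$ guarded at weak
intensities.

The calculated structure factor is the kinematic sum over symmetry
operators $(R, t)$ and sites $j$,

$$ F_{c,\mathrm{mol}}(h) = k \sum_{(R,t)} \sum_j o_j\, f_j(s)\, T_j(h)\,
   g_j(h)\, e^{2\pi i\, h\cdot(Rx_j + t)}, $$

with overall scale $k$, occupancy $o_j$, a four-Gaussian atomic
scattering factor $f_j(s)$ at $s = \sin\theta/\lambda = 1/(2d)$, and the
Debye–Waller factor $T_j$: isotropic $\exp(-8\pi^2 U s^2)$ or
anisotropic $\exp(-2\pi^2 \sum_{ij} U_{ij} h_i h_j a^*_i a^*_j)$ in the
CIF $U$ convention. For symmetry copies the anisotropic form is
evaluated at $h' = R^{\mathsf T} h$, equivalent to rotating the tensor.
Anomalous scattering, extinction and absorption are out of scope, so
Friedel symmetry $F_c(-h) = \overline{F_c(h)}$ holds exactly and is
enforced by construction (and asserted by a property test).

A per-reflection complex **solvent contribution** — the output interface
of a void-density procedure such as SQUEEZE — is added to the *calculated*
structure factors before the modulus is taken:

$$ |F_c| = |F_{c,\mathrm{mol}} + F_{c,\mathrm{solv}}|. $$

Adding the term on the calculated side (rather than "correcting" $Y_o$)
keeps the observed data untouched and lets the atomic model and the
solvent estimate be improved alternately.

## Special shapes

Severely disordered groups are often better described by a continuous
density than by atoms. Three non-atomic parameterisations are
implemented, each carrying a centroid, an isotropic displacement
parameter, an element, a multiplicity (how many atoms are smeared onto
the shape) and an occupancy:

* **spherical shell** of radius $R$: transform $\mathrm{sinc}(|q|R)$,
  for e.g. the six fluorines of a freely reorienting PF$_6^-$;
* **line** of full length $L$ and axis $\hat n$: transform
  $\mathrm{sinc}(q\!\cdot\!\hat n\, L/2)$, for solvent smeared along a
  channel;
* **torus** (ideal ring) of radius $R$ and normal $\hat n$: transform
  $J_0(|q_\perp| R)$, for librating CF$_3$, cyclopentadienyl or benzene
  rings.

Here $q = 2\pi M^{-\mathsf T} h$ is the Cartesian scattering vector
($|q| = 2\pi/d$). The literature describing these shapes does not print
the closed forms, so they are derived here from the Fourier transform of
the ideal uniform density and validated against brute-force
point-scatterer averages (deterministic quadrature over $10^4$ points):
the package forms agree with the oracle to better than $10^{-7}$ over
100 random $q$ per shape. Every transform is 1 at $q = 0$ and the shape
density is additionally blurred by its own isotropic Debye–Waller
factor. Whether a real torus carries finite thickness beyond that
blurring is left open in the source material; the ideal-ring-plus-$U$
model is used. A six-point carbon ring and a torus of the same radius
agree in $|F_c|$ to about 1 % (aggregate) at $d \ge 2.5$ Å; the residual
is the genuine $J_6$ harmonic of a discrete hexagon, which the smeared
model intentionally drops.

**Orientation convention.** Declination is the angle between the shape
axis (line axis or torus normal) and the Cartesian $z$ axis; azimuth is
the angle between the axis' projection onto the $x$–$y$ plane and $x$.
The Cartesian frame is the PDB-style convention: $x$ along $a$, $y$ in
the $a$–$b$ plane, $z$ completing the right-handed set
(`orthogonalization_matrix()`). The program this engine is modelled
after does not document its own frame, so this explicit choice is part
of the package contract (it is written into the CIF metadata) and is
*not* claimed to match any other program bit-for-bit.

# Parameters, constraints and the parameter map

Refinable quantities are fractional coordinates, $U_{\mathrm{iso}}$ or
the six $U_{ij}$, occupancies (fixed by default), shape parameters
(magnitude, declination, azimuth) and the overall scale. A
`parameter_map` is a bijection between the free quantities and the
refinement vector; every constraint is a linear chain folded into a
matrix $T$, so design-matrix columns of constrained quantities
accumulate onto their carriers and shifts propagate back the same way:

* **fix / free** — last writer wins; fixing a parameter that a sharing
  constraint needs is a conflict error;
* **riding hydrogens** — H positional shifts chain 1:1 onto the parent
  (the X–H vector is exactly preserved under parent translation), and
  $U_{\mathrm{iso}}(\mathrm H) = m \times U_{eq}(\mathrm{parent})$ is
  re-derived every cycle ($m = 1.2$; $1.5$ for methyl); no H positional
  indices exist;
* **shared ADPs** — all members map onto the leader's six (or one)
  indices, the cure for ADPs of disorder components in near-coincident
  positions;
* **occupancy sums** — one member is eliminated with coefficient $-1$
  against the rest, removing the classic occupancy collinearity.

Chains must terminate on free parameters (riding on a riding atom is an
error).

## Floating origin

In P1 (and along polar axes such as the $b$ axis of P2$_1$) a uniform
translation of the whole model changes no $|F_c|$, so the data-only
normal matrix is *exactly* rank deficient. The engine detects the
floating directions as the common fixed subspace of the symmetry
rotations and, by default, adds one zero-residual restraint row per
direction pinning the scattering-power-weighted collective shift. The
residual is identically zero, so relative geometry is never biased; only
the origin drift is removed. This is standard crystallographic practice
and can be disabled (`refine_config(fix_origin = FALSE)`).

# Restraints

Restraints are soft observational equations appended to the data with
weight $1/\sigma^2$, sharing the single objective $M$; constraints are
exact eliminations. The grammar (see the README) covers:

* **DISTANCE / ANGLE** with explicit targets;
* **SAME** equivalences: the first group is the target, its
  connectivity determines which 1–2 (bonded) and 1–3 (angle-defining)
  pairs are restrained, and every following group is mapped member-wise.
  Angle equivalences are realised as 1–3 *distance* equivalences — with
  the 1–2 restraints present these determine the angles uniquely and
  keep every Jacobian row at most 12 entries wide. Mirror symmetry is
  expressed by supplying the mirror-permuted order as a mapped group;
  self-pairs that arise (e.g. C3–C5 mapping onto C5–C3) are retained in
  the count and are trivially satisfied. Under this convention the
  canonical two-ring scheme — second ring onto the first, mirrored first
  and mirrored second onto the first, mirrored second onto the second —
  yields $4 \times (6 + 6) = 48$ equivalences for a pair of
  six-membered rings, which the test suite asserts;
* **SIMU** thermal similarity: one difference equation per ADP
  component per pair (six for aniso–aniso, one for iso–iso; mixed pairs
  are an error unless `promote = TRUE` compares $U_{eq}$), default
  $\sigma = 0.04$ Å$^2$;
* **DELU** rigid-bond equations: the Hirshfeld difference
  $\Delta_{AB} = \hat z^{\mathsf T} U_A^{\mathrm{cart}} \hat z -
  \hat z^{\mathsf T} U_B^{\mathrm{cart}} \hat z$ along the unit bond
  vector $\hat z$, target 0, default $\sigma = 0.01$ Å$^2$;
* **LIMIT** shift-limiting: one damping equation per free parameter,
  algebraically identical to adding $1/\sigma^2$ to every diagonal of
  $N$ (Levenberg-style). This is the sanctioned brake for slowly
  converging refinements; no damping is applied by default;
* **asymmetric restraints** (`ASYM`): Jacobian entries on the reference
  group are zeroed, so the poorly defined group is pulled toward the
  reference while the reference — re-read every cycle — is never
  perturbed. This is a deliberate simplification of the published
  one-sided formulation: the reference acts purely as a guide.

All restraint Jacobians are analytic except two places where a hand
derivation would invite sign errors for no numerical benefit: the
dependence of the rigid-bond direction $\hat z$ on the positions (central
differences, step $10^{-6}$; the ADP part is exactly linear and handled
analytically) and the shape magnitude/declination/azimuth derivatives of
the structure factor (five-point central differences, step $10^{-5}$).
Both are covered by finite-difference property tests at $10^{-6}$
relative.

# The engine

Each cycle:

1. **Batched accumulation.** Design rows are computed per reflection
   into a block of `batch_size` rows (default 64) and accumulated into
   $N = A^{\mathsf T} W A$ and $g = A^{\mathsf T} W (Y_o - Y_c)$ with one
   symmetric product per block. All arithmetic is double precision; the
   result is independent of the batch size to $10^{-10}$ relative
   (asserted).
2. **Restraint accumulation**, one sparse rank-one update per equation
   — a distance restraint touches at most a $6\times6$ sub-block.
3. **Preconditioning.** $C_{ii} = 1/\sqrt{N_{ii}}$, $N' = C N C$ has
   unit diagonal, which bounds the dynamic range of the factorisation
   and rescues parameters whose raw curvatures differ by many orders of
   magnitude (positions vs ADPs vs scale). Parameters with $N_{ii} = 0$
   are flagged undetermined and excluded. The inverse is recovered as
   $N^{-1} = C N'^{-1} C$.
4. **Solve.** The default is an LDL$^{\mathsf T}$ factorisation without
   pivoting — safe here because it operates on the preconditioned
   unit-diagonal matrix — which raises a singular-matrix error naming
   the offending pivot's parameter. The alternative,
   `solver = "eigen_filter"`, discards eigenvalue contributions below
   `filter_tol` $\times\ \lambda_{\max}$ (default $10^{-8}$) and always
   returns finite shifts, leaving the degenerate combinations unshifted.
5. **Shift application** through the constraint chain, riding-hydrogen
   $U_{\mathrm{iso}}$ refresh, and statistics:
   $R1 = \sum\big||F_o| - |F_c|\big| / \sum|F_o|$, $wR$, and the
   goodness of fit.

**Convergence** is declared when max $|\mathrm{shift}|/\mathrm{esd} <$
`tol` (default 0.01) within `max_cycles` (default 20). A secondary guard
declares convergence when the absolute shifts vanish (relative
$10^{-9}$): at a numerically perfect fit the esds collapse with the
goodness of fit and shift/esd becomes 0/0. **Divergence** is reported
(with the full cycle history) when the objective rises for three
consecutive cycles by more than $10^{-6}$ relative.

**Esds** are $\mathrm{GoF}\times\sqrt{\mathrm{diag}(N^{-1})}$. The
exported `agreement_statistics()` follows the plain data-only
definition $\mathrm{GoF} = \sqrt{M/(n_{\mathrm{obs}} - n_{\mathrm{par}})}$;
inside `refine()` the restraint-augmented residual and count are used, so
restrained refinements with fewer reflections than parameters still have
a defined scale.

**Diagnostics.** `condition_diagnostics()` reports
$\lambda_{\max}/\lambda_{\min}$ of whatever matrix it is given (infinite
if $\lambda_{\min} \le 0$) and, for the smallest eigenpairs, the
parameter labels carrying the largest eigenvector components — the
near-collinear combination. On the shared-site fixture (Cl and K on one
site, both occupancies free) the smallest mode is the occupancy pair;
adding the occupancy-sum constraint drops the condition number of the
preconditioned matrix by two orders of magnitude.

# Hydrogens

Hydrogens are placed geometrically from the heavy-atom skeleton — linear
continuation (sp$^1$), in-plane external bisector (sp$^2$), tetrahedron
completion and staggered methyls (sp$^3$); a methyl without a reference
substituent on its neighbor receives a documented default torsion with a
warning. Default bond lengths are 0.95 Å (sp$^1$/sp$^2$) and 0.98 Å
(sp$^3$); the source workflow names no numbers, so standard
small-molecule X-ray values are used, all overridable through the plan.
An optional soft-restrained hydrogen cycle refines only the H positions
(heavy atoms fixed) under X–H distance restraints ($\sigma$ = 0.02 Å
default) plus 1–3 distances that preserve the placement angles, before
the final refinement rides the hydrogens on their parents.
Heteroatom-H placement from difference maps is out of scope (no
difference-map synthesis is implemented).

# The synthetic-data generator

`make_fixture()` builds ground-truth models mirroring the systems the
method is designed for: a pair of idealized pyridine rings in P1 (exact
1.34/1.39 Å bonds, constructed by a closed ring walk solved to machine
precision), a benzene disordered by libration modelled as two concentric
tori alongside its discrete 12-atom counterpart, a two-component CF$_3$
rotor (occupancies 0.7/0.3, tangentially elongated F tensors, asymmetric
SIMU pairing atoms related by the 180° rotation), a shared-site
occupancy-collinearity toy, and seeded random structures in P1,
P$\bar 1$, P2$_1$ or P2$_1$/c.

`simulate_observations()` enumerates the full hkl sphere to `d_min` and
applies multiplicative Gaussian noise,

$$ Y_o = |F_c|^2 (1 + \nu\,\varepsilon), \qquad
   \sigma = \max\bigl(\nu |F_c|^2,\; 0.05\,\nu\,\overline{|F_c|^2}\bigr), $$

with $\varepsilon \sim N(0,1)$ under a fixed seed. The $\sigma$ floor
plays the role of the additive background term in real counting
statistics. It matters: with a purely multiplicative $\sigma$ the
weakest reflections receive unbounded $1/\sigma^2$ weights, and the
weighted least-squares landscape develops spurious local minima that can
trap a refinement started 0.02 fractional units from the truth, even
though the global minimum is intact. With the floor, the true model
scores $\mathrm{GoF} \approx 0.93$–1.0 on 2 % noise and perturbed starts
recover the truth with calibrated esds (about 99 % of parameters within
3 esd over 20 seeds, asserted at $\ge$ 95 %).

What the generator does *not* emulate: Poisson counting statistics,
absorption, extinction, twinning, anomalous scattering, incompleteness
and systematic absences of real data sets, and diffractometer-specific
error models. Passing tests therefore demonstrate the correctness and
numerical behaviour of the estimator under its own assumptions, not
robustness to the full pathology of real measurements.

Two conventions worth noting. Restraint geometry uses direct (unimaged)
coordinate differences — fixtures keep bonded atoms within one cell.
Coordinate-recovery experiments use a P$\bar 1$ structure so the origin
is fixed by symmetry and refined coordinates are comparable to the truth
at $10^{-5}$; in P1 recovery is exact only up to the (pinned, but
arbitrary) collective translation.

# Problem sizes and runtimes

The test suite refines structures of 4–17 sites against 1 500–3 000
reflections (31–49 free parameters), sizes chosen so the entire suite
runs in well under a minute while every code path — symmetry summation,
aniso ADPs, shapes, riding H, all restraint kinds, both solvers — is
exercised. The esd-calibration experiment repeats a 31-parameter
refinement over 20 seeds. `scripts/acceptance.R` re-derives the headline
numbers from scratch in a few seconds.

# Known limitations

* No space-group symbol machinery: symmetry comes as explicit operator
  lists (CIF strings or the built-in P1, P$\bar 1$, P2$_1$, P2$_1$/c
  sets).
* No twinning, anomalous dispersion, extinction or absorption models.
* The LDL$^{\mathsf T}$ solver does not pivot; on the preconditioned
  matrix this is benign, and the eigenvalue-filtering path is the
  fallback for genuinely indefinite or rank-deficient systems.
* Restraint distances are not minimum-image; models spanning cell
  boundaries must be shifted into one connected image first.
* The restraint grammar is keyword-compatible with common usage but not
  byte-compatible with any existing program's input files.
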