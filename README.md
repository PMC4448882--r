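# microrefine

A least-squares refinement engine for small-molecule X-ray crystal
structures, written for crystallographers and methods developers who want
an inspectable, fully scriptable implementation of the machinery that
production refinement programs hide behind a GUI: structure-factor
calculation with anisotropic displacement parameters, geometric and
displacement restraints (including one-sided "asymmetric" restraints and
SAME-style equivalence decomposition), riding hydrogens, non-atomic
"special shape" scattering models for severely disordered groups, a
per-reflection complex disordered-solvent contribution, and a numerically
careful normal-equations solver.

## The model

Refinement minimises

```
M = sum_h  w_h (Y_o(h) - Y_c(h))^2
```

where `Y` is either `|F|` or `|F|^2` (default `F^2`, weights `1/sigma^2`),
and the calculated structure factor separates molecular and solvent
contributions:

```
|F_c| = | F_c,molecule + F_c,solvent |
F_c,molecule(h) = k * sum_sym sum_j occ_j f_j(s) T_j(h) g_j(h) exp(2 pi i h.(R x_j + t))
```

with `f_j` the atomic scattering factor, `T_j` the Debye-Waller factor
(isotropic `exp(-8 pi^2 U s^2)` or anisotropic
`exp(-2 pi^2 sum U_ij h_i h_j a*_i a*_j)`), and `g_j` a smearing factor
for special shapes: `sin(qR)/(qR)` for a spherical shell of radius R,
`J0(|q_perp| R)` for an ideal ring torus, `sinc(q.n L/2)` for a line of
length L. `F_c,solvent` is read per reflection from a SQUEEZE-style
`.fab` file and added to the *calculated* complex structure factors.

Each cycle builds the normal equations `N = A' W A` from batched design
blocks (restraints are accumulated one by one as sparse rank-one
updates), rescales `N` to unit diagonal with `C_ii = 1/sqrt(N_ii)`
(`N' = C N C`, inverse recovered as `N^-1 = C N'^-1 C`), solves by LDL'
factorisation (with a singular-matrix error naming the offending
parameter) or, on request, by an eigenvalue-filtering pseudo-inverse, and
applies the shifts through the constraint chain (riding hydrogens, shared
ADPs, occupancy sums). Parameter esds are `GoF * sqrt(diag(N^-1))`.

## Worked example

Two idealized pyridine rings in P1, 2 % Gaussian noise, restrained with
the four-line SAME scheme that decomposes into 48 distance/angle
equivalences:

```r
library(microrefine)

fx  <- make_fixture("pyridine_pair")
rs  <- simulate_observations(fx$model, d_min = 1.2, noise_frac = 0.02, seed = 42)
rset <- expand_restraint_set(
  parse_restraints(fx$restraints_text, labels = site_labels(fx$model)),
  fx$model, fx$conn)
rset
#> restraint set: 48 entries
#>    EQUIV_ANGLE EQUIV_DISTANCE
#>             24             24

start <- perturb_model(fx$model, amount = 0.01, seed = 7)
res   <- refine(start, rs, rset, refine_config(max_cycles = 10))
res
#> refinement: converged after 5 cycle(s)
#>   2420 observations, 48 restraints, 49 free parameters
#>   final R1 = 0.00784477, wR = 0.0197683, GoF(data) = 0.9635
#>   cycle log:
#>  cycle           M      M_data          R1        GoF max_shift_esd
#>      1 3292654.441 3284583.282 0.152439719 36.8710927   2.887819630
#>      2  273890.351  272919.329 0.053754070 10.6341136   5.844770769
#>      3    7073.236    7065.993 0.011571911  1.7089210  11.517263888
#>      4    2204.182    2204.088 0.007847537  0.9539743   0.348233686
#>      5    2200.951    2200.875 0.007844769  0.9532749   0.001060834
```

The perturbed coordinates return to the generator's values: the final
`R1` of 0.78 % reflects only the injected 2 % intensity noise (the
goodness of fit is 0.96, i.e. the model fully explains the data at the
stated uncertainties), and the esds are calibrated so that parameter
deviations from the truth are statistically consistent with
`3 sigma` bounds. With noiseless data the same run converges to
`R1 < 1e-15`.

Condition diagnostics name near-collinear parameter combinations; on the
shared-site occupancy fixture the smallest eigenvector of the
preconditioned normal matrix is dominated by the two occupancies, and
applying the occupancy-sum constraint drops the condition number by two
orders of magnitude:

```r
fx <- make_fixture("collinear_occupancy")
# see ?condition_diagnostics and the methods vignette
```

## File formats

* `read_hkl()` / `write_hkl()` — SHELX-style HKLF 4 (`3I4,2F8.2`,
  intensities, all-zero terminator).
* `read_fab()` / `write_fab()` — whitespace `h k l A B` solvent
  contributions, `!`/`#` comments, aligned to the reflection list by hkl.
* `read_cif()` / `write_cif()` — a minimal CIF dialect: cell,
  `_symmetry_equiv_pos_as_xyz`, `_atom_site_*` + `_atom_site_aniso_*`
  loops, and a documented custom `_microrefine_shape_*` loop for shell /
  line / torus sites.
* `parse_restraints()` — plain-text restraint grammar:

  ```
  DISTANCE 1.39, 0.01 = C1 TO C2
  ANGLE    120,  0.5  = C1 TO C2 TO C3
  SAME 0.01, 0.02 = N1 C2 C3 C4 C5 C6 AND N11 C12 C13 C14 C15 C16
  SIMU 0.04 = F1A F2A F3A AND F2B F3B F1B ASYM
  DELU 0.01 = C1 TO C2, C2 TO C3
  LIMIT 0.05
  ```

  `SAME` lines decompose through the first group's connectivity into
  per-bond and per-angle equivalences; the trailing `ASYM` flag makes a
  restraint one-sided (the first group is a reference that is read but
  never pulled).

## Command line

A thin wrapper over the package functions lives at
`inst/cli/microrefine.R`:

```sh
Rscript inst/cli/microrefine.R simulate --fixture pyridine_pair --d-min 1.2 --noise 0.02 --seed 42 --out sim
Rscript inst/cli/microrefine.R refine   --cif sim/start.cif --hkl sim/pyridine_pair.hkl \
        --restraints sim/pyridine_pair.restraints --out run
Rscript inst/cli/microrefine.R diagnose --cif model.cif --hkl data.hkl --out diag
```

`refine` writes the refined CIF, an fcf-like structure-factor table, a
cycle log, an esd table and a machine-readable `summary.json`; exit codes
distinguish convergence (0), stop at the cycle limit (4), divergence (2)
and a singular normal matrix (3).

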