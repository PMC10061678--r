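---
title: "Models and methods behind mlmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mlmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mlmm` predicts the electrostatic embedding energy of a neutral H/C/N/O/S
molecule in a mesh of MM point charges. This vignette is the package's own
account of the science: the models, their assumptions, every convention we
had to pin down, the numerical choices, and what the test suite does and
does not demonstrate.

## Energy decomposition and assumptions

The embedding energy is split into a static term, an induced interaction,
and a polarization cost:

$$\Delta E_{emb} = \sum_i q_i V^{static}(\mathbf r_i)
 + \sum_i q_i V^{ind}(\mathbf r_i) + E^{pol},$$

with the sums over MM charges. The decomposition assumes: (i) the molecular
charge distribution is well described atom-wise by a point core plus a
single Slater valence shell — adequate for ground-state organic molecules,
increasingly poor for systems needing atomic multipoles; (ii) the response
to the environment is pure linear dipole polarization — no charge flow
between atoms in response to external fields, no hyperpolarizability;
(iii) the QM and MM regions do not overlap (no charge penetration or
exchange effects, no link atoms). Everything is finite and non-periodic:
cutoffs are the caller's business, and the package never wraps coordinates.

Internally every computation is in Hartree atomic units; file I/O is in
Angstrom and elementary charges, and reported energies are kcal/mol
(1 Hartree = 627.509474 kcal/mol). The closed element set (H, C, N, O, S)
is enforced at construction time: extending it requires new core charges
and `k_Z` entries, so failing early beats extrapolating silently.

## Conventions fixed by oracles

Several pieces of this model family circulate in the literature with
incompatible conventions. We fixed each one and wrote an independent
numerical oracle that locks it in place; a misreading fails the test suite
loudly rather than shifting energies quietly.

* **Slater valence density.** $\rho_{val}(r) = N_{val}/(8\pi s^3)\,
  e^{-r/s}$, charge $q_{val} = -N_{val}$, potential
  $V(r) = q_{core}/r + q_{val}\left[1/r - e^{-r/s}(1/r + 1/(2s))\right]$.
  Oracle: shell-theorem adaptive quadrature of the density
  (`quadrature_potential`), agreement to 1e-8 over randomized $(s, r)$.
* **Atomic volume.** The third radial moment of the valence density *scaled
  by the electron count*: $V = \int r^3 \rho_{val}\, d^3r = 60\, N_{val}
  s^3$. The per-electron reading ($60 s^3$) is also defensible; we chose the
  $N_{val}$-scaled form because the volume of an empty shell should vanish,
  and the downstream $k_Z$ fit absorbs any constant convention factor
  anyway. The quadrature oracle is the normative definition.
* **QEq widths.** The Gaussian atomic charge is a *normal* distribution
  with standard deviation $\sigma$. Hardness is the full self-interaction
  integral $J = 1/(\sigma\sqrt\pi)$ — exactly the $R \to 0$ limit of the
  pair term $E_{ij}(R) = \mathrm{erf}\!\left(R/\sqrt{2(\sigma_i^2 +
  \sigma_j^2)}\right)/R$, so diagonal and off-diagonal elements of the
  hardness matrix come from one consistent convention and two coalescing
  atoms behave like one. The energy carries the usual ½ on the quadratic
  form.
* **Thole damping.** Cubic-exponential family:
  $\lambda_3 = 1 - e^{-au^3}$, $\lambda_5 = 1 - (1 + au^3)e^{-au^3}$,
  $u = r/(\alpha_i\alpha_j)^{1/6}$, applied to the $3rr^T/r^5$ and
  $I/r^3$ parts respectively. Gates: exact switch-off at large $u$,
  finiteness at coalescence, and agreement with an independent series
  expansion at $u = 0.01$ (a dedicated small-$x$ series in the
  implementation avoids the catastrophic cancellation of the naive
  expression there).
* **Induced energy bookkeeping.** The default induced component is
  literally $\sum_i q_i V^{ind}(\mathbf r_i) + E^{pol}$ with
  $E^{pol} = \sum |\mu|^2/(2\alpha)$. For interacting dipoles this is *not*
  the minimized induction objective $-\tfrac12\sum \mu\!\cdot\!E$ — the two
  differ by the dipole–dipole coupling energy, and the two readings coincide
  only for a single polarizable site. Both are available
  (`predict_embedding(..., induction = "variational")`), with the two-term
  sum as the default.
* **MM fields are undamped.** Thole damping applies only to the
  intramolecular dipole–dipole tensor; charge–dipole and charge–density
  interactions use bare Coulomb kernels.

QEq charges are computed in vacuo only: the static density is by definition
the non-polarized one, and environment-driven charge flow is deliberately
outside the model (see Limitations).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `r_cut` | 3.0 | Å | SOAP environment radius; deliberately short so QEq/Thole carry the long range |
| `n_max`, `l_max` | 4, 4 | — | radial/angular channels of the power spectrum |
| `sigma_atom` | 0.5 | Å | neighbour-density smearing |
| `zeta` | 2 | — | polynomial kernel exponent |
| `ivm_threshold` | 0.05 | — | posterior-variance stop for basis selection |
| `gpr_noise` | 1e-8 | — | observation-noise variance of the width GPR |
| `adam_lr`, `adam_iters` | 0.01, 1000 | — | electronegativity optimizer |
| `a_qeq_init`, `a_thole_init`, `k_z_init` | 1.2, 0.5, 0.2 | — | positive initial values for the physics scalars |
| clash distance | 0.3 | Å | molecule-construction sanity gate |
| site-distance guard | 1e-6 | Bohr | evaluation points this close to a nucleus are a hard error, never clamped |

The SOAP radial basis (Gaussians on an even radial grid, Löwdin
orthonormalized on a 64-point Gauss–Legendre rule) and `sigma_atom` are this
implementation's choices — descriptor literature leaves them open — and both
are recorded in every checkpoint so a trained model is self-describing; a
checkpoint also stores the schema version, kernel settings, jitters and
seeds.

## Training workflow choices

*Stage 3 (electronegativities + `a_QEq`)* is the only genuinely nonconvex
stage, and only through the single scalar `a_QEq`: for fixed `a_QEq` the QEq
charges are *linear* in the electronegativities, so the basis values have an
exact ridge least-squares solution. We exploit that structure for
initialization — profile the least-squares loss over $\log a_{QEq}$ with a
1-D minimizer — and then run Adam on the joint parameter vector as the
optimizer proper, using the analytic adjoint of the bordered KKT system for
gradients (verified against central finite differences to 1e-5). A global
constant shift of all electronegativities is absorbed by the Lagrange
multiplier and left to the tiny ridge; it never affects charges.
Non-convergence within the iteration cap keeps the best iterate and warns.

*Stage 4 (`k_Z`, `a_Thole`)* minimizes the componentwise tensor MSD (off-
diagonal components counted twice, matching the full 3×3 Frobenius loss)
with L-BFGS-B on log-parameters bounded to $[e^{-8}, e^{6}]$. The log
parameterization keeps everything positive; the box matters because
`a_Thole` becomes unidentifiable when no atom pair is close enough for
damping to act (for single-atom training sets it is reported at its initial
value with a warning, and the fit flags `identifiable = FALSE`). Geometries
that trip the polarization catastrophe during a line search are penalized,
not fatal.

*GPR intercepts.* Both property models use per-element mean functions so the
kernel learns deviations, but the intercepts are fitted *jointly* with the
kernel weights (universal-kriging style, one augmented least-squares solve
by QR — normal equations lose half the digits here). Fixing intercepts at
the raw element means instead leaves a per-element-constant residual that
the small kernel span cannot always absorb.

*Determinism.* IVM breaks ties by lowest index; every stage is a pure
function of (tables, config), and retraining with the same config reproduces
the checkpoint to 1e-12.

## The synthetic-data generator

`make_molecules` builds jittered tree-like H/C/N/O/S geometries
(covalent-radius bond lengths, valence-filling hydrogens, 2–10 atoms,
clash-free at 0.7 Å); `make_mesh` places charges of up to 1 e with
closest-atom distances in 3–12 Å, the shell a cutoff mesh around a solvated
ligand would occupy. `make_reference_tables` then fabricates reference data
from a known ground truth: per-element core charges ($Z$ minus noble-gas
core electrons), MBIS-scale widths, Mulliken-scale electronegativities in
a.u., polarizability/volume ratios chosen so molecular polarizabilities land
in the usual organic range, and Thole's exponential-form damping constant
0.572.

The environment dependence of the true $s^*$ and $\chi^*$ is a *basis-value
construction*: at representative environments (IVM at the same 0.05
threshold) the properties take coordination-modulated values
($\pm 4\%$ for $s$, $\pm 10\%$ for $\chi$, via $\tanh$ of a smooth
coordination count), and everywhere else they are the regular-GPR kernel
interpolation of those basis values. That makes the truth a smooth,
rotation-invariant function of the local environment that lies in the same
smoothness class the model learns, which is what a parameter-*recovery*
harness needs: at zero noise the only obstacles left are the optimizer and
the solver chain, so recovery failures indicate real defects rather than
representation error. Optional noise (reference-scale defaults: 0.003 Bohr
on $s$, 0.02 e on charges, the charge noise centred per molecule so sums
stay exact) restores realistic difficulty.

What the generator does **not** emulate: real DFT densities and their
partitioning noise structure, conformer ensembles, charge penetration at
short QM–MM contact, chemistry outside small neutral organics. Passing
recovery tests therefore demonstrates the correctness of the machinery, not
transferable accuracy on real systems — for that the same tables must come
from actual reference calculations.

## Numerical choices

* Dense direct solves everywhere: the bordered $(N{+}1)$ QEq system and the
  $3N$ Thole relay both use Cholesky/LU at $N \le$ a few hundred atoms —
  exactness over speed. Conditioning is checked (condition number $> 10^{12}$
  aborts with diagnostics); loss of positive definiteness in the relay is
  reported as a polarization catastrophe naming the closest reduced pair.
* Kernel factorizations start at jitter 1e-8 and escalate tenfold to 1e-4
  before a hard error.
* Special-function edges: `erf(u)/R` switches to its series below
  $u = 10^{-4}$; the Thole $\lambda_5$ uses a series below
  $a u^3 = 10^{-3}$; modified spherical Bessel functions are evaluated
  through exponentially scaled `besselI` so radial integrals stay finite at
  all separations.
* Degenerate inputs fail loudly by policy: unsupported elements, evaluation
  points on nuclei, non-positive widths or polarizabilities, count/row
  mismatches in files — each has a named error path, no silent clamping.

## Problem sizes

The test suite exercises 30–50 randomized parameter points per analytic
oracle, 200 random QEq systems for the invariance properties, and training
fixtures of 15–30 molecules; the end-to-end recovery run uses 200 molecules
(~1300 atomic environments, ~50 basis environments) and 40 evaluation
snapshots, the scale at which the recovery errors quoted in the README were
measured. These sizes were chosen as the smallest that leave every stage —
descriptor, basis selection, both GPR fits, both optimizers — genuinely
exercised.

## Limitations

* No charge-flow response to external fields: QEq runs in vacuo and the
  environment polarizes only the dipoles. Strongly polarizing environments
  (ions at contact) will be underserved.
* Atomic dipoles only — no higher static multipoles, no anisotropic atomic
  polarizabilities.
* Neutral-molecule scope; integer total charges other than zero are
  accepted by the solver but outside the trained model's domain.
* No forces: the engine predicts energies; differentiating through the
  pipeline is future work.
* The ζ = 2 kernel with a 3 Å cutoff caps model capacity deliberately;
  systems whose properties depend on mid-range structure need a larger
  cutoff and a retrained basis.
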