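---
title: "Training interatomic potentials on energies, forces, and Hessians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training interatomic potentials on energies, forces, and Hessians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Machine-learned interatomic potentials (MLIPs) are regressions from a
molecular geometry and its element labels to a potential energy. Training
them on energies alone leaves the *shape* of the potential energy surface
(PES) — its slopes and curvatures — unconstrained away from the training
points. Near reaction transition states this matters acutely: a model can
reproduce the energy of every stationary point it was shown and still place
spurious minima, wrong barriers, or unstable dynamics between them.

`hessnip` implements training of neural-network potentials whose loss
includes, besides the energy, the atomic forces (first derivatives) and the
full `3N x 3N` Cartesian Hessian (second derivatives) of each training
structure, and the evaluation protocols that measure what the extra
curvature information buys: off-path generalization, single-saddle
extrapolation, molecular-dynamics stability under a heating ramp,
nudged-elastic-band barriers, and harmonic vibrational spectra along
reaction paths.

Because reference Hessians from electronic structure are expensive, the
package ships a synthetic-data module: analytic reaction surfaces with
closed-form energies, gradients, and Hessians, so every benchmark runs
against exact labels.

## Model

Each atom's environment is encoded by a descriptor vector (an "atomic
environment vector", AEV) built from smooth symmetry functions of the
neighbor geometry:

* a **radial block** per neighbor element: Gaussian shells
  `sum_j exp(-eta_r (r_ij - R_s)^2) f_c(r_ij)` over a grid of shifts `R_s`,
  plus low-order **radial moments** `sum_j r_ij^k f_c(r_ij)` for
  `k = 0, 1, 2` (coordination count, bond-length sum, squared-length sum);
* an **angular block** per unordered neighbor element pair: Bernstein
  polynomials in `cos(theta_jik)` times a Gaussian in the mean pair distance
  and the two cutoff factors.

Two deliberate departures from the common Behler–Parrinello / ANI forms are
made because this package differentiates the model twice:

1. The angular shape functions are polynomials in `cos(theta)` rather than
   `(1 + cos(theta - theta_s))^zeta`. The trigonometric form contains
   `sin(theta)` factors whose second derivatives diverge at collinear
   geometries; polynomials in `cos(theta)` are smooth in the coordinates
   everywhere away from coincident atoms.
2. The default cutoff `f_c(r) = (1 - (r/R_c)^2)^3` has a continuous second
   derivative at `R_c`. The classic cosine cutoff is only C1 there, which
   injects curvature noise precisely into the quantity being trained; it is
   retained as an option for lineage comparison.

The radial moments exist for a conditioning reason that the package's own
benchmarks exposed: with Gaussian shells alone, representing the locally
quadratic shape of a PES (what a Hessian label prescribes) requires very
large readout coefficients, and those coefficients carry third-order terms
that destroy extrapolation just outside the fitted point. Moments make
locally quadratic behavior representable with small weights.

Each element has its own network: a block of `tanh` hidden units with
weights drawn once from the member seed and held fixed, a linear
(identity) block passing the standardized descriptor through, and a trained
linear output layer. Atomic outputs plus per-element reference (self)
energies sum to the molecular energy. Keeping the hidden layers fixed makes
energies, forces, and Hessians *linear in the trained weights*, so the loss
below is convex, training is deterministic given the seed, and ensembles
(members differing only in their hidden-layer seeds) provide honest spread
estimates. Descriptor standardization (per-element mean and scale over the
training set) is folded into the hidden weights at fit time; it is essential
to the conditioning of the random-feature basis.

## Derivatives

Forces and Hessians of the model are computed by writing out the nested
chain rule exactly: the AEV Jacobian (`L x 3n`) and the AEV second-derivative
stack (`L x 3n x 3n`) have closed forms — every term is a function of
interatomic distances, whose first and second Cartesian derivatives have one
uniform expression — and compose with the analytic first and second
derivatives of the network. These are the same quantities reverse-mode
automatic differentiation would produce; here they are explicit because
every ingredient is available in closed form. An independent
finite-difference oracle (`finite_difference_oracle()`) verifies both in the
test suite at 1e-5 (forces) and 1e-4 (Hessians) relative tolerance.

Predicted Hessians are symmetrized (`(H + H')/2`) before use; translation
invariance of the descriptors implies the acoustic sum rules (zero net
force; atom-summed Hessian blocks vanish), which the tests assert rather
than impose.

## Loss and training

For a batch of `M` molecules, with `n_F` unmasked force components and `n_H`
unmasked Hessian elements (both halves of the symmetric matrix are counted,
and padded entries are excluded):

```
eps_E = sqrt( sum_i (E_i^ref - E_i^pred)^2 / M )
eps_F = sqrt( sum   (F^ref   - F^pred  )^2 / n_F )
eps_H = sqrt( sum   (H^ref   - H^pred  )^2 / n_H )
L     = eps_E + eta_F * eps_F + eta_H * eps_H
```

Defaults `eta_F = 0.08`, `eta_H = 0.02`; `(0, 0)` defines an E model,
`(eta_F, 0)` an E–F model, both positive an E–F–H model.
`calibrate_weights()` re-derives the weights for any dataset by the
empirical balancing rule: train once with unit weights, then set each factor
to the ratio of the final energy RMSE to the final force (Hessian) RMSE.

Because predictions are affine in the readout weights, each loss term is the
square root of a quadratic form, accumulated once as Gram matrices; after
that, training cost is independent of dataset size. The optimizer is damped
iteratively-reweighted least squares: each epoch solves the weighted normal
equations of the majorizer `sqrt(q) <= (q/eps_t + eps_t)/2`, with two
numerical guards (each term's epsilon is floored at 1e-3 of its natural
scale, and the weight spread is capped at 1e6) against the corners where a
term's residual reaches zero — which happens structurally, since force
labels vanish at the critical points that make up an RTP dataset. The
returned model is the best-validation checkpoint (10% of molecules held out
by seed).

That checkpoint rule is load-bearing, not cosmetic. The loss's exact global
optimum is computable for this model class, and chasing it *hurts* off-path
generalization for E–F fits: zero-slope interpolation of critical points
makes the fit buy vanishing force residuals with excess curvature between
data points. Validation-checkpointed iterates — the analog of early-stopped
stochastic training of a deep network — avoid that regime, and the
qualitative orderings reported below depend on it. The recorded losses are
always the three RMSE terms exactly as defined above.

For datasets too small to hold out a validation molecule (up to three
structures, e.g. the single-saddle protocol), the terms are satisfied
hierarchically: energy and force rows are interpolated by the minimum-norm
readout — they are trivially satisfiable there, which is also the structure
of the loss optimum — and the Hessian residual is minimized in their null
space with a ridge calibrated to the Hessian design scale.

The ridge default (`lambda = 1e-3`, relative to the design scale) and the
default capacity (16 tanh units plus the linear block per element) are
deliberately modest: the benchmark datasets have ~100 structures, and the
comparison between loss variants is only meaningful when none of them can
trivially interpolate the data.

## The synthetic reaction family

`build_rtp_dataset()` emulates a reaction dataset with exact labels.
Reactions are shared-proton transfers `A-H...B -> A...H-B` on Morse bond
networks: donor and acceptor atoms from {N, O, S} held by a long stiff
scaffold bond, the proton bonded to both by Morse terms (which generically
produces two minima and one index-1 saddle), plus 0–2 bridging spectator
atoms ({C, O} with long coordination-style anchor bonds) that vary size and
composition, for molecules of 3–5 atoms. A fixed global table of bond
parameters per element pair makes the union of all reactions one consistent
surface, as a real PES is. A soft exponential repulsion acts between
non-bonded pairs; without it, bare pair networks let spectators collapse
onto other atoms during geometry searches.

Critical points are located by Newton searches with eigenvector following
(trust radius 0.1 A, gradient tolerance 1e-3 kcal/mol/A — far tighter than
typical electronic-structure criteria, since labels here are analytic).
Saddle searches pick the uphill mode by overlap with the donor-to-acceptor
proton direction and track it between iterations; always inverting the
lowest mode instead tends to mangle soft spectator modes. Searches retry
from deterministically perturbed starts, and reactions whose critical points
fail to converge, have the wrong Hessian index, or retain non-bonded
contacts below 1.1 A (H) / 1.6 A (heavy atoms) are skipped with a warning —
about 34 of the 42-member family survives. Reactant and product energies,
TS index, and label/finite-difference consistency are all asserted in tests.

Two low-dimensional surfaces complete the reference set: the quartic double
well `V = x^4 - 2x^2` (exact barrier 1, saddle curvature -4) for NEB and
IRC checks, and the Mueller–Brown surface for multi-basin saddle searches.

IRC paths are traced by fixed-step steepest descent in mass-weighted
coordinates (step 0.01 amu^1/2 A with backtracking, seeded 0.01 amu^1/2 A
along the unstable eigenvector), with the signed mass-weighted arc length
zeroed at the TS and the path tangent exported per image.

## Evaluation protocols and the package's own findings

All protocols run from `offpath_trend_experiment()`,
`single_ts_experiment()`, and `stability_experiment()`, which fix the study
conditions (40 requested reactions, compact descriptor, 16+L features per
element, ridge 1e-3, ensembles of 4, 5–7 seeds); the acceptance script and
the test suite call the same functions.

* **Off-path trend.** Models of all three variants are trained on the
  critical points only and evaluated on normal-mode-sampled perturbations of
  IRC *intermediate* images (300 K, path-tangent mode excluded). The
  evaluation set must be off-path in this sense: NMS around the trained
  critical points themselves does not separate E from E–F. Median energy
  RMSE orders E–F–H < E–F < E, and the E–F–H Hessian RMSE is 3–4x below
  E–F's, reproducing the qualitative finding that curvature information is
  what survives away from the data.
* **Single-saddle extrapolation.** Ensembles trained to one TS structure
  are asked for energies along the IRC within ±0.25 amu^1/2 A. Mean
  absolute error is lowest for E–F–H, and its ensemble spread is smallest;
  energy-only training pins a single number and learns no shape at all.
* **MD stability.** Langevin dynamics (BAOAB; friction 0.01 1/fs, time step
  0.5 fs) under an iterative heating ramp starting at 5 K with +5 K stages.
  A run fails when some monitored bonded pair's mean distance over the
  trailing 50 steps leaves (0.75, 1.5) times its equilibrium value (strict
  inequalities; the check slides every step; velocities persist across
  stages; monitored pairs are the force field's own bonds). At desk scale
  the stages are 0.5 ps and the cap 150 K. The exact surface reaches the
  cap; E–F–H models reach a higher median failure temperature than E
  models. The E vs E–F comparison is deliberately not asserted.
* **NEB.** Standard projected-force nudged elastic band with the
  energy-weighted upwind tangent and a climbing image, relaxed by FIRE
  (spring constant 50 eV/A^2 and 0.05 eV/A convergence threshold converted
  internally; the band optimizer is FIRE rather than a quasi-Newton scheme
  because projected NEB forces are not the gradient of any objective).
  The double-well barrier converges to 1.0 within 2% and the Mueller–Brown
  climbing image lands on the independently located saddle within 1%.
  Unconverged bands are returned flagged, and barrier extraction refuses
  them unless forced.
* **Vibrations.** Frequencies come from the eigenvalues of
  `M^-1/2 H M^-1/2` with *no* translational/rotational projection; all `3n`
  values are reported, imaginary modes as negative wavenumbers, no scaling
  factors. The harmonic diatomic closed form is reproduced to better than
  0.1 cm^-1; synthetic transition states show exactly one imaginary mode;
  spectra along an IRC show the reaction-coordinate mode passing through
  imaginary values at the TS.

## Numerical choices and degenerate inputs

* Internal units are kcal/mol, Angstrom, amu, fs, K everywhere; conversions
  (CODATA 2018) happen only at boundaries. `convert_quantity()` reproduces
  the conventional printed equivalences (4.5e-4 hartree/bohr = 0.53
  kcal/mol/A, etc.) without internal rounding.
* Hessian symmetry of labels is validated at 1e-8 relative on construction;
  predicted Hessians are symmetrized.
* Padding: species code 0, all label tensors exactly zero at padded
  positions, masks carried explicitly; `n_F`/`n_H` denominators exclude
  padding.
* NMS displacement law: per retained mode, `c_i = ±sqrt(3 kB T R / k_i)`
  with `R ~ U(0,1)`; modes below a stiffness floor (default 1
  kcal/mol/(amu A^2), which removes translations/rotations and free internal
  rotations) are skipped; a 0.5 A per-atom clip guards against unphysical
  draws (the clip, when active, can leave a small residual along an excluded
  mode).
* All randomness flows through explicit integer seeds; the RNG wrapper
  never disturbs the caller's random stream.

## What passing these tests does and does not show

The generator produces small gas-phase molecules with pairwise-plus-
repulsion interactions, exact labels, and reaction diversity from
composition and topology only. It does not emulate electronic effects,
label noise, conformational diversity at scale, or molecules beyond five
atoms, and the models here are linear-readout random-feature networks, not
deep trained networks. Passing benchmarks therefore demonstrate the
*information-content* claims (what Hessian labels add at fixed data volume,
at desk scale) and the correctness of the machinery — not that any
particular accuracy transfers to real chemical systems. The observed
orderings also depend on regularized, checkpointed training; a model class
flexible enough to interpolate its training set exactly will not show the
E–F < E leg.

## Known limitations

* Training is desk-scale by design; ensembles of ~100 members over tens of
  thousands of structures are out of scope on one CPU.
* The angular basis with few Bernstein functions limits angular resolution;
  configuration via `aev_spec()` allows denser grids at higher cost.
* Periodic systems, charges, and spin are not modeled.
* The `1e6` IRLS weight-spread cap and the epsilon floors are numerical
  guards; pathological datasets (e.g. exactly duplicated structures with
  conflicting labels) are not detected.
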