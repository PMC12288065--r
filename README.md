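# hessnip

Hessian-trained neural-network interatomic potentials on analytic
surfaces, in R.

## What this is for

Machine-learned interatomic potentials (MLIPs) regress molecular potential
energies from geometries. Trained on energies alone — or even energies and
forces — they learn little about the *curvature* of the potential energy
surface, which is exactly what transition states, vibrational spectra, and
dynamical stability depend on. `hessnip` is for researchers who want to
study what full `3N x 3N` Hessian labels add to MLIP training, with every
benchmark running against analytic reaction surfaces whose energies,
gradients, and Hessians are exact.

The package implements, end to end:

* per-element neural-network potentials on smooth symmetry-function
  descriptors (radial Gaussian shells + low-order radial moments +
  polynomial angular functions), with **exact nested chain-rule forces and
  Hessians**;
* the composite loss
  `L = eps_E + eta_F * eps_F + eta_H * eps_H`, where each term is a masked
  RMSE over energies, force components, and Hessian elements respectively
  (defaults `eta_F = 0.08`, `eta_H = 0.02`, re-derivable per dataset by the
  empirical balancing rule in `calibrate_weights()`);
* a synthetic reaction generator: shared-proton transfer reactions on Morse
  bond networks (3–5 atoms, elements H/C/N/O/S) with reactant, index-1
  saddle, and product per reaction, plus intrinsic-reaction-coordinate
  tracing and normal-mode sampling;
* the evaluation protocols: off-path error trends across loss variants,
  single-saddle extrapolation, Langevin temperature-ramp stability with a
  bond-distortion failure criterion, climbing-image nudged-elastic-band
  barriers, and unprojected mass-weighted vibrational spectra.

## Worked example

Train an energy–force–Hessian model on an O–H Morse bond and inspect what
it learned:

```r
library(hessnip)

ff <- reference_ff("morse_bond_network", species = c("O", "H"),
                   bonds = data.frame(i = 1, j = 2, D = 105, a = 2.8, r0 = 0.97))
train <- lapply(seq(0.75, 1.6, length.out = 25), function(r) {
  X <- rbind(c(0, 0, 0), c(r, 0, 0))
  ev <- eval_reference(ff, X)
  labeled_structure(c("O", "H"), X, energy = ev$energy,
                    forces = ev$forces, hessian = ev$hessian)
})

spec <- aev_spec(c("H", "O"), r_cut = 3.5,
                 radial_shifts = seq(0.6, 2.6, length.out = 8), eta_r = 12,
                 n_angular = 2, angular_r_shifts = c(1.0, 2.0), eta_a = 3)
fit <- fit_potential(train, loss_weights(0.08, 0.02), spec = spec,
                     n_hidden = 96, seed = 3, lambda = 1e-9,
                     epochs = 200, patience = 60)
fit$report
#> <fit_report: 57 epochs (best 27), final eps_E=3.782e-05 eps_F=0.001285 eps_H=0.004555>
```

The three numbers are the training RMSEs of the loss terms: energy in
kcal/mol, forces in kcal/mol/A, Hessian elements in kcal/mol/A^2 — a few
parts in 10^5 of the label scales for this one-bond system. The model's
Hessian at the equilibrium bond length then reproduces the analytic
vibrational fundamental:

```r
s <- train[[which.min(sapply(train, `[[`, "energy"))]]
nu_ref <- max(frequencies(s$hessian, s$masses))
nu_fit <- max(frequencies(predict_hessians(fit$model, list(s))[[1]], s$masses))
c(reference = nu_ref, model = nu_fit)
#> reference     model
#>  4668.599  4668.590
```

(wavenumbers, cm^-1). A climbing-image NEB on the quartic double well
`V = x^4 - 2x^2` recovers its unit barrier:

```r
dw <- reference_ff("quartic_double_well_1d")
r <- find_critical_point(dw, matrix(c(-0.8, 0, 0), 1, 3), "minimum")
p <- find_critical_point(dw, matrix(c(0.8, 0, 0), 1, 3), "minimum")
barrier_height(optimize_mep(dw, interpolate_path(r, p, 16)))
#> [1] 0.9911309
```

The headline comparison — what Hessian training buys off the reaction
path — is one call (a few minutes; 40 reactions, ensembles of 4 over 7
seeds):

```r
tr <- offpath_trend_experiment(seed = 11)
round(tr$medians, 2)
#>     energy forces hessian
#> E     6.12  38.98  414.72
#> EF    5.70  39.31  444.45
#> EFH   2.11  15.01  115.25
```

Median off-path energy RMSE (kcal/mol, on normal-mode-sampled perturbations
of IRC intermediate geometries) improves from the E to the E–F to the
E–F–H loss, and the Hessian RMSE of the Hessian-trained variant is ~3.9x
below the force-trained one.

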