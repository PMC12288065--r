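Package: hessnip
Title: Hessian-Trained Neural Network Interatomic Potentials on Analytic Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains neural-network interatomic potentials with energy, force,
    and full 3N x 3N Hessian loss terms, with forces and Hessians obtained by
    exact nested chain-rule differentiation of symmetry-function descriptors.
    Provides analytic reference potential-energy surfaces (Morse bond networks,
    a quartic double well, the Mueller-Brown surface) with closed-form labels,
    generators for reactant/transition-state/product datasets, intrinsic
    reaction coordinate paths and normal-mode-sampled perturbations, and the
    evaluation protocols that probe what curvature information buys: off-path
    error trends, single-saddle extrapolation, Langevin temperature-ramp
    stability with a bond-distortion failure criterion, climbing-image nudged
    elastic band barriers, and unprojected mass-weighted vibrational spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
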