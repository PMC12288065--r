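# Shared fixtures: tiny analytic systems with exact labels, built in code.

# O-H Morse diatomic force field (D, a, r0 as in the global pair table)
morse_oh_ff <- function() {
  reference_ff("morse_bond_network", species = c("O", "H"),
               bonds = data.frame(i = 1L, j = 2L, D = 105, a = 2.8, r0 = 0.97))
}

# labeled diatomic structure at separation r
morse_oh_at <- function(r, ff = morse_oh_ff()) {
  X <- rbind(c(0, 0, 0), c(r, 0, 0))
  ev <- eval_reference(ff, X)
  labeled_structure(c("O", "H"), X, energy = ev$energy, forces = ev$forces,
                    hessian = ev$hessian)
}

# diatomic training set spanning the well
morse_oh_dataset <- function(n = 25, lo = 0.75, hi = 1.6) {
  lapply(seq(lo, hi, length.out = n), morse_oh_at)
}

# compact descriptor for H/O systems
tiny_spec <- function(elements = c("H", "O")) {
  aev_spec(elements, r_cut = 3.5,
           radial_shifts = seq(0.6, 2.6, length.out = 6), eta_r = 8,
           n_angular = 2, angular_r_shifts = c(1.0, 2.0), eta_a = 3)
}

# a labeled 4-atom proton-transfer molecule (reactant of one family member)
pt_reaction <- function(seed = 7) {
  ds <- suppressWarnings(build_rtp_dataset(6, seed = seed))
  ds$reactions[[1]]
}

# random non-degenerate geometry for a species set (atoms kept > 0.8 A apart)
random_geometry <- function(species, scale = 1.6, seed = 1) {
  set.seed(seed)
  n <- length(species)
  repeat {
    X <- matrix(stats::runif(3 * n, -scale, scale), n, 3L)
    d <- stats::dist(X)
    if (n == 1L || min(d) > 0.8) return(X)
  }
}

# central-difference gradient/Hessian of a scalar function of a flat vector
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(m) {
    e <- numeric(length(x)); e[m] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
num_hess <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (m in seq_len(n)) for (q in m:n) {
    em <- numeric(n); em[m] <- h
    eq <- numeric(n); eq[q] <- h
    H[m, q] <- H[q, m] <-
      (f(x + em + eq) - f(x + em - eq) - f(x - em + eq) + f(x - em - eq)) /
      (4 * h^2)
  }
  H
}

# potential model with seeded random readout weights (for derivative tests)
random_readout_model <- function(spec, n_hidden = 12, seed = 3, w_sd = 0.3) {
  m <- init_potential_model(spec, n_hidden = n_hidden, seed = seed)
  rng_seed <- seed + 1000
  set.seed(rng_seed)
  for (e in names(m$nets)) {
    m$nets[[e]]$w <- stats::rnorm(m$n_feat, sd = w_sd)
  }
  m
}
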