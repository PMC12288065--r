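test_that("mass weighting is the similarity transform it claims to be", {
  H <- matrix(c(4, 1, 0, 1, 3, 0, 0, 0, 2), 3, 3)
  expect_equal(mass_weighted_hessian(H, 1), H)
  Hd <- diag(c(6, 6, 6))
  expect_equal(mass_weighted_hessian(Hd, 2), diag(c(3, 3, 3)))
  r <- pt_reaction(seed = 7)
  Hmw <- mass_weighted_hessian(r$ts$hessian, r$ts$masses)
  expect_lt(max(abs(Hmw - t(Hmw))), 1e-12 * max(abs(Hmw)))
  expect_error(mass_weighted_hessian(Hd, 0), "positive")
})

test_that("non-interacting atoms give all-zero frequencies", {
  expect_equal(frequencies(matrix(0, 6, 6), c(1, 12)), rep(0, 6))
})

test_that("the harmonic diatomic frequency matches the closed form", {
  k <- 500
  m1 <- 1.008; m2 <- 15.999
  B <- k * tcrossprod(c(1, 0, 0))
  H <- rbind(cbind(B, -B), cbind(-B, B))
  nu <- frequencies(H, c(m1, m2))
  expect_length(nu, 6L)
  expect_true(!is.unsorted(nu))
  # closed form assembled from independent constants:
  # nu = sqrt(k/mu)/(2 pi c), k in mdyn-free SI route
  mu_kg <- (m1 * m2 / (m1 + m2)) * 1.66053906660e-27
  k_si <- k * 4184 / 6.02214076e23 / 1e-20        # J/m^2
  closed <- sqrt(k_si / mu_kg) / (2 * pi * 2.99792458e10)
  expect_lt(abs(max(nu) - closed), 0.1)
  expect_equal(sum(abs(nu) < 1), 5L)              # five null modes
})

test_that("transition states show exactly one imaginary mode, minima none", {
  r <- pt_reaction(seed = 7)
  nu_ts <- frequencies(r$ts$hessian, r$ts$masses)
  expect_equal(sum(nu_ts < -1), 1L)
  nu_min <- frequencies(r$reactant$hessian, r$reactant$masses)
  expect_equal(sum(nu_min < -1), 0L)
  # unprojected translations: at least three near-zero modes everywhere
  expect_gte(sum(abs(nu_ts) < 1), 3L)
  expect_gte(sum(abs(nu_min) < 1), 3L)
})

test_that("frequencies are invariant under rigid rotation", {
  r <- pt_reaction(seed = 7)
  s <- r$reactant
  set.seed(12)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  ev <- eval_reference(r$ff, s$coordinates %*% R)
  nu0 <- frequencies(s$hessian, s$masses)
  nu1 <- frequencies(ev$hessian, s$masses)
  expect_lt(max(abs(nu0 - nu1)), 0.1)
})

test_that("spectra along a reaction path soften through the saddle", {
  dw <- reference_ff("quartic_double_well_1d")
  sad <- find_critical_point(dw, matrix(c(0.05, 0, 0), 1, 3), "saddle1")
  irc <- trace_irc(dw, sad, keep_every = 20L)
  spec <- spectrum_along_path(dw, irc)
  expect_equal(nrow(spec$frequencies), length(irc$images))
  expect_equal(ncol(spec$frequencies), 3L)
  # the reaction-coordinate mode is imaginary exactly at the saddle
  ts_row <- spec$frequencies[irc$ts_index, ]
  expect_equal(sum(ts_row < -1), 1L)
  # and real at the endpoints
  expect_equal(sum(spec$frequencies[1, ] < -1), 0L)
  # constant path gives identical rows
  same <- spectrum_along_path(dw, list(sad, sad, sad))
  expect_equal(same$frequencies[1, ], same$frequencies[3, ])
})

test_that("a well-trained model reproduces reference frequencies", {
  sp <- aev_spec(c("H", "O"), r_cut = 3.5,
                 radial_shifts = seq(0.6, 2.6, length.out = 8), eta_r = 12,
                 n_angular = 2, angular_r_shifts = c(1.0, 2.0), eta_a = 3)
  train <- morse_oh_dataset()
  f <- fit_potential(train, loss_weights(0.08, 0.02), spec = sp,
                     n_hidden = 96, seed = 3, lambda = 1e-9,
                     epochs = 200, patience = 60)
  s <- morse_oh_at(0.97)
  nu_ref <- frequencies(s$hessian, s$masses)
  nu_mod <- frequencies(predict_hessians(f$model, list(s))[[1]], s$masses)
  # stretch fundamental within a few percent
  expect_lt(abs(max(nu_mod) - max(nu_ref)) / max(nu_ref), 0.05)
})
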