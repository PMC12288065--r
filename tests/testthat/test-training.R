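test_that("loss terms equal their brute-force recomputation", {
  sp <- tiny_spec(c("H", "O"))
  m <- random_readout_model(sp, seed = 9)
  structs <- list(morse_oh_at(0.9), morse_oh_at(1.2))
  batch <- build_batch(structs)
  bundle <- predict_bundle(m, batch)
  terms <- loss_terms(bundle, batch)
  # brute force, straight from the definitions
  eE <- sqrt(mean((batch$energies - bundle$energies)^2))
  sf <- 0; sh <- 0
  for (i in 1:2) {
    sf <- sf + sum((batch$forces[i, 1:2, ] - bundle$forces[i, 1:2, ])^2)
    sh <- sh + sum((batch$hessians[i, 1:6, 1:6] - bundle$hessians[i, 1:6, 1:6])^2)
  }
  expect_equal(unname(terms["eps_E"]), eE, tolerance = 1e-12)
  expect_equal(unname(terms["eps_F"]), sqrt(sf / 12), tolerance = 1e-12)
  expect_equal(unname(terms["eps_H"]), sqrt(sh / 72), tolerance = 1e-12)
})

test_that("perfect predictions and single-residual cases are exact", {
  s <- morse_oh_at(1.0)
  batch <- build_batch(list(s))
  perfect <- structure(list(
    energies = s$energy, forces = array(s$forces, c(1, 2, 3)),
    hessians = array(s$hessian, c(1, 6, 6)), atom_mask = batch$atom_mask,
    n_atoms = batch$n_atoms), class = "derivative_bundle")
  expect_equal(unname(loss_terms(perfect, batch)), c(0, 0, 0))
  off <- perfect
  off$energies <- s$energy + 2
  expect_equal(unname(loss_terms(off, batch)), c(2, 0, 0))
})

test_that("total loss applies the calibrated weights exactly", {
  expect_equal(total_loss(c(1, 10, 50), loss_weights(0.08, 0.02)), 2.8)
  expect_equal(total_loss(c(5, 99, 99), loss_weights(0, 0)), 5)
  expect_equal(total_loss(c(0, 0, 0), loss_weights()), 0)
  expect_error(loss_weights(-0.1, 0), ">= 0")
})

test_that("weight calibration reproduces the ratio definition", {
  w <- calibrate_weights(c(1, 12.5, 50))
  expect_equal(w$eta_F, 0.08)
  expect_equal(w$eta_H, 0.02)
  w2 <- calibrate_weights(c(3, 3, 3))
  expect_equal(c(w2$eta_F, w2$eta_H), c(1, 1))
  w3 <- calibrate_weights(c(2, 4, 8))
  expect_equal(c(w3$eta_F, w3$eta_H), c(0.5, 0.25))
  expect_error(calibrate_weights(c(1, 0, 5)), "zero")
})

test_that("training demands the labels its weights require", {
  sp <- tiny_spec(c("H", "O"))
  no_h <- lapply(seq(0.8, 1.4, length.out = 6), function(r) {
    s <- morse_oh_at(r)
    labeled_structure(s$species, s$coordinates, energy = s$energy,
                      forces = s$forces)
  })
  expect_error(fit_potential(no_h, loss_weights(0.08, 0.02), spec = sp),
               "Hessian labels")
  no_f <- lapply(no_h, function(s) labeled_structure(s$species, s$coordinates,
                                                     energy = s$energy))
  expect_error(fit_potential(no_f, loss_weights(0.08, 0), spec = sp),
               "force labels")
})

test_that("fits are deterministic and recover a Morse diatomic", {
  sp <- aev_spec(c("H", "O"), r_cut = 3.5,
                 radial_shifts = seq(0.6, 2.6, length.out = 8), eta_r = 12,
                 n_angular = 2, angular_r_shifts = c(1.0, 2.0), eta_a = 3)
  train <- morse_oh_dataset()
  f1 <- fit_potential(train, loss_weights(0.08, 0.02), spec = sp,
                      n_hidden = 96, seed = 3, lambda = 1e-9,
                      epochs = 200, patience = 60)
  f2 <- fit_potential(train, loss_weights(0.08, 0.02), spec = sp,
                      n_hidden = 96, seed = 3, lambda = 1e-9,
                      epochs = 200, patience = 60)
  expect_identical(f1$report$history, f2$report$history)
  expect_identical(f1$model$nets, f2$model$nets)
  frms <- sqrt(mean(unlist(lapply(train, `[[`, "forces"))^2))
  hrms <- sqrt(mean(unlist(lapply(train, `[[`, "hessian"))^2))
  expect_lt(f1$report$final_rmse["eps_F"], 0.05 * frms)
  expect_lt(f1$report$final_rmse["eps_H"], 0.05 * hrms)
})

test_that("evaluation reports per-member statistics", {
  sp <- tiny_spec(c("H", "O"))
  train <- morse_oh_dataset(n = 12)
  f <- fit_potential(train, loss_weights(0.08, 0), spec = sp, n_hidden = 16,
                     seed = 2)
  ev <- evaluate_rmse(f$model, train)
  expect_setequal(ev$metric, c("energy", "forces", "hessian"))
  expect_true(all(is.na(ev$sd)))
  en <- init_ensemble(2, seed = 1, spec = sp, n_hidden = 8)
  en$members[[2]] <- en$members[[1]]   # identical members -> zero spread
  ev2 <- evaluate_rmse(en, train)
  expect_equal(ev2$sd, c(0, 0, 0))
})

test_that("learning curves use nested subsets and reproduce under a seed", {
  sp <- tiny_spec(c("H", "O"))
  pool <- morse_oh_dataset(n = 16)
  evalset <- lapply(c(0.85, 1.05, 1.35), morse_oh_at)
  variants <- list(EF = loss_weights(0.08, 0))
  lc1 <- learning_curve(pool, c(0.5, 1), variants, seed = 4,
                        eval_structures = evalset, spec = sp, n_hidden = 12)
  lc2 <- learning_curve(pool, c(0.5, 1), variants, seed = 4,
                        eval_structures = evalset, spec = sp, n_hidden = 12)
  expect_identical(lc1, lc2)
  expect_equal(lc1$n_train, c(8L, 16L))
  expect_error(learning_curve(pool, c(0.01), variants, seed = 4,
                              eval_structures = evalset, spec = sp),
               "< 1 structure")
})
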