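test_that("path interpolation is linear with exact endpoints", {
  r <- labeled_structure(c("O", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  p <- labeled_structure(c("O", "H"), rbind(c(0, 0, 0), c(2, 1, 0)))
  band <- interpolate_path(r, p, 3)
  expect_identical(band[[1]]$coordinates, r$coordinates)
  expect_identical(band[[3]]$coordinates, p$coordinates)
  expect_equal(band[[2]]$coordinates, (r$coordinates + p$coordinates) / 2)
  band5 <- interpolate_path(r, p, 5)
  f <- 0.25
  expect_equal(band5[[2]]$coordinates,
               (1 - f) * r$coordinates + f * p$coordinates)
  same <- interpolate_path(r, r, 4)
  for (img in same) expect_identical(img$coordinates, r$coordinates)
  p_bad <- labeled_structure(c("H", "O"), p$coordinates)
  expect_error(interpolate_path(r, p_bad, 3), "species")
})

test_that("climbing-image NEB recovers the quartic double-well barrier", {
  dw <- reference_ff("quartic_double_well_1d")
  r <- find_critical_point(dw, matrix(c(-0.8, 0, 0), 1, 3), "minimum")
  p <- find_critical_point(dw, matrix(c(0.8, 0, 0), 1, 3), "minimum")
  mep <- optimize_mep(dw, interpolate_path(r, p, 16))
  expect_true(mep$converged)
  b <- barrier_height(mep)
  expect_lt(abs(b - 1) / 1, 0.02)
  # symmetric potential: same barrier from either end
  expect_equal(barrier_height(mep, "product"), b, tolerance = 1e-6)
  # arc places the top image at zero
  expect_equal(mep$arc[which.max(mep$energies)], 0)
})

test_that("doubling the image count barely moves the converged barrier", {
  dw <- reference_ff("quartic_double_well_1d")
  r <- find_critical_point(dw, matrix(c(-0.8, 0, 0), 1, 3), "minimum")
  p <- find_critical_point(dw, matrix(c(0.8, 0, 0), 1, 3), "minimum")
  b1 <- barrier_height(optimize_mep(dw, interpolate_path(r, p, 16),
                                    fmax_tol = 0.01))
  b2 <- barrier_height(optimize_mep(dw, interpolate_path(r, p, 32),
                                    fmax_tol = 0.01))
  expect_lt(abs(b2 - b1) / b1, 0.005)
})

test_that("Mueller-Brown climbing image lands on the saddle", {
  mb <- reference_ff("mueller_brown_2d")
  m1 <- find_critical_point(mb, matrix(c(-0.5, 1.5, 0), 1, 3), "minimum")
  m2 <- find_critical_point(mb, matrix(c(0, 0.5, 0), 1, 3), "minimum")
  sad <- find_critical_point(mb, matrix(c(-0.8, 0.6, 0), 1, 3), "saddle1")
  mep <- optimize_mep(mb, interpolate_path(m1, m2, 16))
  expect_true(mep$converged)
  expect_lt(abs(max(mep$energies) - sad$energy) / abs(sad$energy), 0.01)
  # climbing image is a genuine index-1 point of the exact surface
  ci <- mep$images[[which.max(mep$energies)]]
  Hci <- eval_reference(mb, ci)$hessian
  expect_equal(hessian_index(Hci, neg_tol = 1e-3), 1L)
  gci <- eval_reference(mb, ci)$forces
  expect_lt(max(abs(gci)), 0.05 * codata_constants$ev_kcal + 1e-9)
})

test_that("unconverged bands are reported, not hidden", {
  mb <- reference_ff("mueller_brown_2d")
  m1 <- find_critical_point(mb, matrix(c(-0.5, 1.5, 0), 1, 3), "minimum")
  m2 <- find_critical_point(mb, matrix(c(0.62, 0.03, 0), 1, 3), "minimum")
  mep <- optimize_mep(mb, interpolate_path(m1, m2, 12), max_iter = 2L)
  expect_false(mep$converged)
  expect_error(barrier_height(mep), "not converged")
  expect_true(is.finite(barrier_height(mep, force_unconverged = TRUE)))
})

test_that("barrier heights are plain arithmetic on image energies", {
  dw <- reference_ff("quartic_double_well_1d")
  r <- find_critical_point(dw, matrix(c(-0.8, 0, 0), 1, 3), "minimum")
  p <- find_critical_point(dw, matrix(c(0.8, 0, 0), 1, 3), "minimum")
  mep <- optimize_mep(dw, interpolate_path(r, p, 10))
  expect_equal(barrier_height(mep, "reactant"),
               max(mep$energies) - mep$energies[1])
  expect_equal(barrier_height(mep, "product"),
               max(mep$energies) - mep$energies[length(mep$energies)])
})
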