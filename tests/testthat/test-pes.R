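test_that("Morse diatomic has its analytic minimum and stretch curvature", {
  ff <- reference_ff("morse_bond_network", species = c("X", "X"),
                     bonds = data.frame(i = 1L, j = 2L, D = 1, a = 1, r0 = 1),
                     repulsion_A = 0)
  ev <- eval_reference(ff, rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(ev$energy, 0)
  expect_equal(max(abs(ev$forces)), 0)
  expect_equal(ev$hessian[1, 1], 2, tolerance = 1e-12)  # 2 D a^2
})

test_that("quartic double well has the stated critical points", {
  dw <- reference_ff("quartic_double_well_1d")
  at0 <- eval_reference(dw, matrix(c(0, 0, 0), 1, 3))
  expect_equal(at0$energy, 0)
  expect_equal(max(abs(at0$forces)), 0)
  expect_equal(at0$hessian[1, 1], -4)
  mn <- find_critical_point(dw, matrix(c(0.5, 0, 0), 1, 3), "minimum")
  expect_equal(mn$coordinates[1, 1], 1, tolerance = 1e-4)
  expect_equal(mn$energy, -1, tolerance = 1e-8)
  sd1 <- find_critical_point(dw, matrix(c(0.1, 0, 0), 1, 3), "saddle1")
  expect_equal(sd1$coordinates[1, 1], 0, tolerance = 1e-4)
  expect_equal(sd1$energy, 0, tolerance = 1e-8)
})

test_that("Mueller-Brown minimum matches a dense-grid oracle", {
  mb <- reference_ff("mueller_brown_2d")
  # independent oracle: coarse grid scan + local quadratic refinement
  gx <- seq(-1.5, 1.2, length.out = 120)
  gy <- seq(-0.5, 2.2, length.out = 120)
  vals <- outer(gx, gy, function(x, y) {
    vapply(seq_along(x), function(i) {
      eval_reference(mb, matrix(c(x[i], y[i], 0), 1, 3))$energy
    }, numeric(1))
  })
  k <- which(vals == min(vals), arr.ind = TRUE)
  x0 <- matrix(c(gx[k[1]], gy[k[2]], 0), 1, 3)
  mn <- find_critical_point(mb, x0, "minimum", gtol = 1e-6)
  # literature-grade values emerge from the search itself; oracle agreement:
  expect_lt(abs(mn$energy - min(vals)), 0.5)
  expect_equal(mn$coordinates[1, 1:2], c(-0.5582, 1.4417), tolerance = 1e-3)
})

test_that("gradients and Hessians are finite-difference consistent", {
  r <- pt_reaction(seed = 7)
  set.seed(4)
  X <- r$ts$coordinates + matrix(rnorm(length(r$ts$coordinates), sd = 0.05),
                                 ncol = 3)
  ev <- eval_reference(r$ff, X)
  f <- function(v) eval_reference(r$ff, matrix(v, nrow(X), 3, byrow = TRUE))$energy
  xv <- as.numeric(t(X))
  g_num <- num_grad(f, xv)
  scale_g <- max(abs(g_num))
  expect_lt(max(abs(g_num + as.numeric(t(ev$forces)))) / scale_g, 1e-6)
  H_num <- num_hess(f, xv)
  expect_lt(max(abs(H_num - ev$hessian)) / max(abs(ev$hessian)), 1e-5)
})

test_that("critical point search reports convergence failures and wrong index", {
  dw <- reference_ff("quartic_double_well_1d")
  expect_error(find_critical_point(dw, matrix(c(0.5, 0, 0), 1, 3), "minimum",
                                   max_iter = 1L), "did not converge")
  expect_error(find_critical_point(dw, matrix(c(0.9, 0, 0), 1, 3), "saddle1"),
               "index")
})

test_that("IRC through the double-well saddle is symmetric with TS at zero", {
  dw <- reference_ff("quartic_double_well_1d")
  sad <- find_critical_point(dw, matrix(c(0.05, 0, 0), 1, 3), "saddle1")
  irc <- trace_irc(dw, sad)
  expect_equal(irc$arc[irc$ts_index], 0)
  expect_true(all(diff(irc$arc) > 0))
  e <- vapply(irc$images, `[[`, numeric(1), "energy")
  # monotone non-increasing away from the TS on both branches
  expect_true(all(diff(e[irc$ts_index:length(e)]) <= 1e-9))
  expect_true(all(diff(rev(e[1:irc$ts_index])) <= 1e-9))
  # end points reach the two minima at x = +/- 1, V = -1
  expect_equal(e[1], -1, tolerance = 1e-3)
  expect_equal(e[length(e)], -1, tolerance = 1e-3)
  # symmetric profile on the symmetric potential
  expect_equal(e[1], e[length(e)], tolerance = 1e-6)
  # the image at arc 0 is the input saddle
  expect_identical(irc$images[[irc$ts_index]]$coordinates, sad$coordinates)
})

test_that("IRC endpoints on Mueller-Brown match independently found minima", {
  mb <- reference_ff("mueller_brown_2d")
  sad <- find_critical_point(mb, matrix(c(-0.8, 0.6, 0), 1, 3), "saddle1")
  irc <- trace_irc(mb, sad, step = 0.005, gtol_end = 1e-2)
  m1 <- find_critical_point(mb, matrix(c(-0.5, 1.5, 0), 1, 3), "minimum")
  m2 <- find_critical_point(mb, matrix(c(-0.05, 0.47, 0), 1, 3), "minimum")
  ends <- sort(c(irc$images[[1]]$energy,
                 irc$images[[length(irc$images)]]$energy))
  expect_equal(ends, sort(c(m1$energy, m2$energy)), tolerance = 5e-3)
})

test_that("IRC energies are reparametrization-consistent under step halving", {
  dw <- reference_ff("quartic_double_well_1d")
  sad <- find_critical_point(dw, matrix(c(0.05, 0, 0), 1, 3), "saddle1")
  irc1 <- trace_irc(dw, sad, step = 0.01, keep_every = 5L)
  irc2 <- trace_irc(dw, sad, step = 0.005, keep_every = 5L)
  e1 <- vapply(irc1$images, `[[`, numeric(1), "energy")
  e2 <- vapply(irc2$images, `[[`, numeric(1), "energy")
  common <- seq(max(min(irc1$arc), min(irc2$arc)) + 1e-6,
                min(max(irc1$arc), max(irc2$arc)) - 1e-6, length.out = 41)
  i1 <- stats::approx(irc1$arc, e1, xout = common)$y
  i2 <- stats::approx(irc2$arc, e2, xout = common)$y
  expect_lt(max(abs(i1 - i2)), 1e-3)
})

test_that("RTP dataset generation is deterministic and physically consistent", {
  ds1 <- suppressWarnings(build_rtp_dataset(8, seed = 5,
                                            min_success_fraction = 0.5))
  ds2 <- suppressWarnings(build_rtp_dataset(8, seed = 5,
                                            min_success_fraction = 0.5))
  expect_identical(rtp_structures(ds1), rtp_structures(ds2))
  expect_gte(length(ds1$reactions), 4L)
  for (r in ds1$reactions) {
    expect_equal(hessian_index(r$ts$hessian), 1L)
    expect_equal(hessian_index(r$reactant$hessian), 0L)
    expect_equal(hessian_index(r$product$hessian), 0L)
    expect_lt(r$reactant$energy, r$ts$energy)
    expect_lt(r$product$energy, r$ts$energy)
    # forces at generated critical points lie below the search tolerance
    expect_lt(max(abs(r$ts$forces)), 1e-3 + 1e-9)
    # labels match an independent re-evaluation of the surface
    ev <- eval_reference(r$ff, r$ts$coordinates)
    expect_equal(ev$energy, r$ts$energy)
    expect_equal(ev$hessian, r$ts$hessian)
  }
})
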