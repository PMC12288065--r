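test_that("an isolated atom has an identically zero descriptor", {
  sp <- tiny_spec()
  res <- aev_structure(matrix(0, 1, 3), "H", sp)
  expect_true(all(res$G == 0))
})

test_that("radial terms vanish at and beyond the cutoff", {
  sp <- tiny_spec()
  res <- aev_structure(rbind(c(0, 0, 0), c(sp$r_cut, 0, 0)), c("H", "H"), sp)
  expect_true(all(res$G == 0))
  res2 <- aev_structure(rbind(c(0, 0, 0), c(sp$r_cut + 0.5, 0, 0)),
                        c("H", "H"), sp)
  expect_true(all(res2$G == 0))
})

test_that("a radial entry matches direct summation of the symmetry function", {
  sp <- tiny_spec(c("H", "O"))
  X <- rbind(c(0, 0, 0), c(1.0, 0.2, 0), c(-0.7, 0.6, 0.3))
  species <- c("O", "H", "H")
  res <- aev_structure(X, species, sp)
  # center = atom 1 (O); neighbors of element H at distances r2, r3
  r2 <- sqrt(sum(X[2, ]^2)); r3 <- sqrt(sum(X[3, ]^2))
  fc <- function(r) if (r < sp$r_cut) (1 - (r / sp$r_cut)^2)^3 else 0
  s_idx <- 3L  # third radial Gaussian of the H block
  Rs <- sp$radial_shifts[s_idx]
  expected <- exp(-sp$eta_r * (r2 - Rs)^2) * fc(r2) +
    exp(-sp$eta_r * (r3 - Rs)^2) * fc(r3)
  expect_equal(res$G[1, s_idx], expected, tolerance = 1e-12)
  # and a moment entry (k = 2) against the same direct sum
  k2 <- length(sp$radial_shifts) + 3L   # moments follow the Gaussian block
  expect_equal(res$G[1, k2], r2^2 * fc(r2) + r3^2 * fc(r3), tolerance = 1e-12)
})

test_that("descriptors are invariant to rotation, translation and H swaps", {
  sp <- tiny_spec(c("H", "O"))
  species <- c("O", "H", "H", "O")
  X <- random_geometry(species, seed = 5)
  G0 <- aev_structure(X, species, sp)$G
  # random rotation + translation
  set.seed(8)
  qr_R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(qr_R) < 0) qr_R[, 1] <- -qr_R[, 1]
  G1 <- aev_structure(X %*% qr_R + rep(1, 4) %o% c(3, -2, 5), species, sp)$G
  expect_lt(max(abs(G1 - G0)), 1e-10)
  # swapping the two hydrogens permutes rows only
  Xs <- X[c(1, 3, 2, 4), ]
  G2 <- aev_structure(Xs, species, sp)$G
  expect_lt(max(abs(G2 - G0[c(1, 3, 2, 4), ])), 1e-12)
})

test_that("analytic descriptor derivatives match finite differences", {
  sp <- tiny_spec(c("H", "O"))
  species <- c("O", "H", "H")
  X <- rbind(c(0, 0, 0), c(0.95, 0.1, 0), c(-0.3, 0.9, 0.1))
  res <- aev_structure(X, species, sp, deriv = 2L)
  xv <- as.numeric(t(X))
  worstJ <- 0; worstH <- 0
  for (a in 1:3) {
    live <- which(abs(res$G[a, ]) > 1e-10)
    for (l in live[seq(1, length(live), by = 3)]) {  # subsample features
      f <- function(v) aev_structure(matrix(v, 3, 3, byrow = TRUE),
                                     species, sp)$G[a, l]
      worstJ <- max(worstJ, max(abs(num_grad(f, xv) - res$J[[a]][l, ])))
      worstH <- max(worstH, max(abs(num_hess(f, xv) -
                                      matrix(res$H[[a]][l, ], 9, 9))))
    }
  }
  expect_lt(worstJ, 1e-7)
  expect_lt(worstH, 1e-5)
})

test_that("smooth_poly cutoff is C2 at the boundary, cosine is not", {
  for (variant in c("smooth_poly", "cosine")) {
    sp <- aev_spec("H", r_cut = 3.0, radial_shifts = c(1.0, 2.0), eta_r = 2,
                   radial_moments = integer(0), n_angular = 2,
                   angular_r_shifts = c(1.5), eta_a = 2, cutoff_fn = variant)
    # second derivative of one radial entry w.r.t. bond length across r_cut
    g_at <- function(r) aev_structure(rbind(c(0, 0, 0), c(r, 0, 0)),
                                      c("H", "H"), sp)$G[1, 2]
    h <- 1e-4
    d2 <- function(r) (g_at(r + h) - 2 * g_at(r) + g_at(r - h)) / h^2
    jump <- abs(d2(3.0 - 2 * h) - 0)  # value just inside vs identically 0 outside
    if (variant == "smooth_poly") expect_lt(jump, 1e-3)
    else expect_gt(jump, 1e-2)       # cosine retains a curvature kink
  }
})

test_that("unknown elements are reported by name", {
  sp <- tiny_spec(c("H", "O"))
  expect_error(aev_structure(matrix(0, 1, 3), "Kr", sp), "Kr")
  b <- build_batch(list(labeled_structure("N", matrix(0, 1, 3))))
  expect_error(compute_aev(b, sp), "N")
})

test_that("batched descriptors zero the padded rows", {
  sp <- tiny_spec(c("H", "O"))
  s2 <- labeled_structure(c("O", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  s3 <- labeled_structure(c("O", "H", "H"), random_geometry(rep("H", 3), seed = 9))
  ab <- compute_aev(build_batch(list(s2, s3)), sp)
  expect_true(all(ab$G[1, 3, ] == 0))
  expect_equal(dim(ab$G), c(2L, 3L, sp$length))
})
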