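test_that("labeled_structure validates its invariants", {
  s <- morse_oh_at(1.0)
  expect_s3_class(s, "labeled_structure")
  expect_equal(s$masses, c(15.999, 1.008))
  expect_error(labeled_structure(character(0), matrix(0, 0, 3)), "at least one")
  expect_error(labeled_structure("H", matrix(c(1, Inf, 0), 1, 3)), "finite")
  H_bad <- matrix(c(1, 2, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_error(labeled_structure("H", matrix(0, 1, 3), hessian = H_bad),
               "not symmetric")
})

test_that("batches pad with zeros and carry a consistent mask", {
  s2 <- morse_oh_at(1.0)
  ff3 <- reference_ff("morse_bond_network", species = c("O", "H", "H"),
                      bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L),
                                         D = 105, a = 2.8, r0 = 0.97))
  X3 <- rbind(c(0, 0, 0), c(0.97, 0, 0), c(-0.3, 0.92, 0))
  ev3 <- eval_reference(ff3, X3)
  s3 <- labeled_structure(c("O", "H", "H"), X3, energy = ev3$energy,
                          forces = ev3$forces, hessian = ev3$hessian)
  b <- build_batch(list(s2, s3))
  expect_equal(dim(b$species), c(2L, 3L))
  expect_equal(b$n_atoms, c(2L, 3L))
  expect_equal(b$atom_mask, rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE)))
  # molecule 1 padding: third atom slot and Hessian rows/cols 7-9 exactly zero
  expect_true(all(b$coordinates[1, 3, ] == 0))
  expect_true(all(b$forces[1, 3, ] == 0))
  expect_true(all(b$hessians[1, 7:9, ] == 0))
  expect_true(all(b$hessians[1, , 7:9] == 0))
  expect_equal(b$species[1, 3], 0L)
})

test_that("single molecule batches and copies behave trivially", {
  s <- morse_oh_at(1.1)
  b1 <- build_batch(list(s))
  expect_equal(drop(b1$coordinates[1, , ]), s$coordinates)
  bk <- build_batch(list(s, s, s))
  for (i in 2:3) {
    expect_identical(bk$coordinates[i, , ], bk$coordinates[1, , ])
    expect_identical(bk$hessians[i, , ], bk$hessians[1, , ])
  }
})

test_that("unbatching recovers every input structure bit-exactly", {
  structs <- list(morse_oh_at(0.9), morse_oh_at(1.2), morse_oh_at(1.5))
  back <- unbatch_structures(build_batch(structs))
  for (i in seq_along(structs)) {
    expect_identical(back[[i]]$coordinates, structs[[i]]$coordinates)
    expect_identical(back[[i]]$energy, structs[[i]]$energy)
    expect_identical(back[[i]]$forces, structs[[i]]$forces)
    expect_identical(back[[i]]$hessian, structs[[i]]$hessian)
    expect_identical(back[[i]]$species, structs[[i]]$species)
  }
})

test_that("mask counts exclude padding and ignore molecule order", {
  five <- labeled_structure(rep("H", 5), random_geometry(rep("H", 5), seed = 2))
  expect_equal(mask_counts(build_batch(list(five))),
               list(M = 1L, n_F = 15L, n_H = 225L))
  two_a <- labeled_structure(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  two_b <- labeled_structure(c("O", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(mask_counts(build_batch(list(two_a, two_b))),
               list(M = 2L, n_F = 12L, n_H = 72L))
  three <- labeled_structure(c("O", "H", "H"), random_geometry(rep("H", 3), seed = 3))
  m1 <- mask_counts(build_batch(list(two_a, three)))
  expect_equal(m1, list(M = 2L, n_F = 15L, n_H = 117L))  # 36 + 81
  m2 <- mask_counts(build_batch(list(three, two_a)))
  expect_equal(m1[c("n_F", "n_H")], m2[c("n_F", "n_H")])
})

test_that("inconsistent label availability is rejected", {
  with_e <- morse_oh_at(1.0)
  no_e <- labeled_structure(c("O", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(build_batch(list(with_e, no_e)), "present for some")
})
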