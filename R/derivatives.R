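# Forces and Hessians of the predicted energy by nested chain-rule
# differentiation.
#
# With per-atom features phi(G_a(x)) and linear readout w, the molecular
# energy is E = sum_a w' phi_a + const, so
#   dE/dx   = sum_a w' diag(phi') W1 J_a
#   d2E/dx2 = sum_a [ A' diag(w phi'') A  +  sum_l (w' diag(phi') W1)_l H_a[l] ]
# with A = W1 J_a, J_a and H_a[l] the exact AEV Jacobian/Hessians from
# aev_structure(), phi' = 1 - phi^2 and phi'' = -2 phi (1 - phi^2). These
# are the same quantities nested reverse-mode differentiation produces; here
# the chain rule is written out because the descriptors and networks have
# closed-form derivatives.

# per-structure energy/gradient/Hessian of the model; deriv in 0:2
.model_eval <- function(model, s, deriv = 2L, aev = NULL) {
  .check_alphabet(model, s$species)
  if (is.null(aev)) aev <- aev_structure(s, spec = model$spec, deriv = deriv)
  n <- length(s$species)
  phi <- .atomic_features(model, aev$G, s$species)
  E <- sum(vapply(seq_len(n), function(a) {
    net <- model$nets[[s$species[a]]]
    sum(net$w * phi[[a]]) + model$ref_energies[[s$species[a]]]
  }, numeric(1)))
  g <- NULL; H <- NULL
  if (deriv >= 1L) {
    g <- numeric(3 * n)
    for (a in seq_len(n)) {
      net <- model$nets[[s$species[a]]]
      ad <- .act_derivs(net, phi[[a]])
      c1 <- net$w * ad$p1
      v <- drop(crossprod(net$W1, c1))          # length L
      g <- g + drop(crossprod(aev$J[[a]], v))   # (3n)
    }
  }
  if (deriv >= 2L) {
    H <- matrix(0, 3 * n, 3 * n)
    for (a in seq_len(n)) {
      net <- model$nets[[s$species[a]]]
      ad <- .act_derivs(net, phi[[a]])
      c1 <- net$w * ad$p1
      c2 <- net$w * ad$p2
      A <- net$W1 %*% aev$J[[a]]                # n1 x 3n
      H <- H + t(A) %*% (A * c2)                # A' diag(c2) A
      v <- drop(crossprod(net$W1, c1))
      H <- H + matrix(drop(v %*% aev$H[[a]]), 3 * n, 3 * n)
    }
    H <- (H + t(H)) / 2                         # remove round-off asymmetry
  }
  list(energy = E, gradient = g, hessian = H)
}

#' Predict atomic forces
#'
#' Negative gradient of [predict_energy()] with respect to the Cartesian
#' coordinates, via the exact nested chain rule.
#'
#' @param model a `potential_model`.
#' @param batch a `padded_batch` or list of structures.
#' @return M x N x 3 array (padded entries zero) when given a batch; for a
#'   structure list, a list of n x 3 matrices. kcal/mol/A.
#' @export
predict_forces <- function(model, batch) {
  structs <- .as_structure_list(batch)
  per <- lapply(seq_along(structs), function(i) {
    ev <- .model_eval(model, structs[[i]], deriv = 1L)
    if (!all(is.finite(ev$gradient))) {
      stop(sprintf("non-finite force for molecule %d", i), call. = FALSE)
    }
    matrix(-ev$gradient, length(structs[[i]]$species), 3L, byrow = TRUE)
  })
  if (!inherits(batch, "padded_batch")) return(per)
  N <- ncol(batch$species)
  out <- array(0, c(length(structs), N, 3L))
  for (i in seq_along(per)) out[i, seq_len(nrow(per[[i]])), ] <- per[[i]]
  out
}

#' Predict full Hessian matrices
#'
#' Second derivative of the predicted energy with respect to each pair of
#' Cartesian coordinates, symmetrized to remove round-off asymmetry. For a
#' padded batch, each molecule's 3n x 3n block sits in the top-left of its
#' 3N x 3N slice with zero padding.
#'
#' @param model a `potential_model`.
#' @param batch a `padded_batch` or list of structures.
#' @return M x 3N x 3N array, or list of 3n x 3n matrices. kcal/mol/A^2.
#' @export
predict_hessians <- function(model, batch) {
  structs <- .as_structure_list(batch)
  per <- lapply(seq_along(structs), function(i) {
    ev <- .model_eval(model, structs[[i]], deriv = 2L)
    if (!all(is.finite(ev$hessian))) {
      stop(sprintf("non-finite Hessian for molecule %d", i), call. = FALSE)
    }
    ev$hessian
  })
  if (!inherits(batch, "padded_batch")) return(per)
  N <- ncol(batch$species)
  out <- array(0, c(length(structs), 3L * N, 3L * N))
  for (i in seq_along(per)) {
    m <- seq_len(nrow(per[[i]]))
    out[i, m, m] <- per[[i]]
  }
  out
}

#' Predict energies, forces and Hessians together
#'
#' @param model a `potential_model`.
#' @param batch a `padded_batch`.
#' @return list of class `derivative_bundle`: `energies` (M), `forces`
#'   (M x N x 3), `hessians` (M x 3N x 3N), `atom_mask`.
#' @export
predict_bundle <- function(model, batch) {
  stopifnot(inherits(batch, "padded_batch"))
  structs <- unbatch_structures(batch)
  N <- ncol(batch$species)
  M <- length(structs)
  energies <- numeric(M)
  forces <- array(0, c(M, N, 3L))
  hessians <- array(0, c(M, 3L * N, 3L * N))
  for (i in seq_len(M)) {
    ev <- .model_eval(model, structs[[i]], deriv = 2L)
    n <- length(structs[[i]]$species)
    energies[i] <- ev$energy
    forces[i, seq_len(n), ] <- matrix(-ev$gradient, n, 3L, byrow = TRUE)
    m <- seq_len(3L * n)
    hessians[i, m, m] <- ev$hessian
  }
  structure(list(energies = energies, forces = forces, hessians = hessians,
                 atom_mask = batch$atom_mask, n_atoms = batch$n_atoms),
            class = "derivative_bundle")
}

#' Central finite-difference derivative oracle
#'
#' Independent check used in tests and diagnostics: forces from central
#' differences of an energy function, and the Hessian from central
#' differences applied twice, symmetrized as (H + H')/2. A warning is
#' emitted when the raw Hessian asymmetry exceeds 1e-3 (relative), the
#' signature of a cancellation-prone step size.
#'
#' @param energy_fn function taking an n x 3 coordinate matrix, returning a
#'   scalar energy.
#' @param structure a [labeled_structure()] or n x 3 coordinate matrix.
#' @param step finite-difference step, A.
#' @return list `forces` (n x 3), `hessian` (3n x 3n).
#' @export
finite_difference_oracle <- function(energy_fn, structure, step = 1e-4) {
  stopifnot(step > 0)
  X <- if (inherits(structure, "labeled_structure")) structure$coordinates
       else as.matrix(structure)
  n <- nrow(X)
  nc <- 3L * n
  xv <- as.numeric(t(X))
  f <- function(v) energy_fn(matrix(v, n, 3L, byrow = TRUE))
  g <- numeric(nc)
  for (m in seq_len(nc)) {
    e <- numeric(nc); e[m] <- step
    g[m] <- (f(xv + e) - f(xv - e)) / (2 * step)
  }
  # rows of H from central differences of the gradient, so that the raw
  # matrix carries the asymmetry signal of a cancellation-prone step
  grad_at <- function(v) {
    gg <- numeric(nc)
    for (m in seq_len(nc)) {
      e <- numeric(nc); e[m] <- step
      gg[m] <- (f(v + e) - f(v - e)) / (2 * step)
    }
    gg
  }
  H <- matrix(0, nc, nc)
  for (q in seq_len(nc)) {
    e <- numeric(nc); e[q] <- step
    H[, q] <- (grad_at(xv + e) - grad_at(xv - e)) / (2 * step)
  }
  asym <- max(abs(H - t(H))) / max(abs(H), 1e-300)
  if (asym > 1e-3) {
    warning(sprintf(
      "finite-difference Hessian asymmetry %.2e suggests a cancellation-prone step",
      asym), call. = FALSE)
  }
  list(forces = matrix(-g, n, 3L, byrow = TRUE), hessian = (H + t(H)) / 2)
}
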