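# Per-element neural network potential.
#
# Each element has a single-hidden-layer network acting on that atom's AEV:
# a block of tanh units with seeded random weights plus a block of linear
# (identity) units passing the descriptor through directly. Atomic outputs
# are summed with per-element reference (self) energies to give the
# molecular energy. The hidden layer is drawn once from the member's seed
# and held fixed; the linear output layer is the trained parameter vector.
# This random-feature form keeps energies, forces and Hessians linear in
# the trainable weights, so the energy/force/Hessian loss is convex and
# training is deterministic. Descriptor standardization (per-element mean /
# scale over the training set) is folded into the hidden weights by
# fit_potential(), which conditions the feature basis. Ensemble members
# differ by their hidden-layer seeds.

#' Initialize a potential model
#'
#' @param spec an [aev_spec()]; one network per element in its alphabet.
#' @param n_hidden tanh hidden units per element network.
#' @param seed integer seed for the hidden-layer draw.
#' @param ref_energies named per-element reference energies, kcal/mol
#'   (default all zero; normally set by [fit_potential()]).
#' @param linear_units include an identity block passing the (standardized)
#'   descriptor through alongside the tanh block.
#' @return object of class `potential_model`; each element net has
#'   `n_hidden + L` (or `n_hidden`) features.
#' @export
init_potential_model <- function(spec, n_hidden = 48L, seed = 1L,
                                 ref_energies = NULL, linear_units = TRUE) {
  stopifnot(inherits(spec, "aev_spec"), n_hidden >= 1L)
  L <- spec$length
  if (is.null(ref_energies)) {
    ref_energies <- stats::setNames(rep(0, length(spec$elements)), spec$elements)
  }
  stopifnot(all(spec$elements %in% names(ref_energies)))
  rng <- .seeded_rng(seed)
  nets <- list()
  n_feat <- n_hidden + if (linear_units) L else 0L
  for (e in spec$elements) {
    W1 <- matrix(rng$norm(n_hidden * L, sd = 2 / sqrt(L)), n_hidden, L)
    b1 <- rng$unif(n_hidden, -1, 1)
    act <- rep("tanh", n_hidden)
    if (linear_units) {
      W1 <- rbind(W1, diag(L))
      b1 <- c(b1, numeric(L))
      act <- c(act, rep("id", L))
    }
    nets[[e]] <- list(W1 = W1, b1 = b1, act = act, w = numeric(n_feat))
  }
  structure(
    list(spec = spec, nets = nets, n_hidden = as.integer(n_hidden),
         n_feat = n_feat, activation = "tanh+id",
         ref_energies = ref_energies[spec$elements],
         seed = as.integer(seed), provenance = list()),
    class = "potential_model"
  )
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("<potential_model: %d element nets (%s), %d hidden units, seed %d>\n",
              length(x$nets), paste(names(x$nets), collapse = " "),
              x$n_hidden, x$seed))
  invisible(x)
}

# small self-contained RNG wrapper that never touches the global stream
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  run <- function(f) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, envir = globalenv())
    out <- f()
    env$state <- get(".Random.seed", envir = globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
    out
  }
  list(
    norm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    unif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    sample = function(x, size) run(function() sample(x, size))
  )
}

#' Initialize an ensemble of potential models
#'
#' Member i is reproducible from `(seed, i)`: its hidden layers are drawn
#' with seed `seed * 10000 + i`.
#'
#' @param n_members number of members (>= 1).
#' @param seed base seed.
#' @param spec an [aev_spec()].
#' @param n_hidden hidden units per element network.
#' @return object of class `potential_ensemble` (list of models + seeds).
#' @export
init_ensemble <- function(n_members, seed, spec, n_hidden = 48L) {
  stopifnot(n_members >= 1L)
  member_seeds <- seed * 10000L + seq_len(n_members)
  members <- lapply(member_seeds, function(s) {
    init_potential_model(spec, n_hidden = n_hidden, seed = s)
  })
  structure(list(members = members, member_seeds = member_seeds, seed = seed),
            class = "potential_ensemble")
}

#' @export
print.potential_ensemble <- function(x, ...) {
  cat(sprintf("<potential_ensemble: %d members (base seed %d)>\n",
              length(x$members), x$seed))
  invisible(x)
}

# per-atom hidden activations for one structure's AEV matrix (n x L)
.atomic_features <- function(model, G, species) {
  n <- nrow(G)
  lapply(seq_len(n), function(a) {
    net <- model$nets[[species[a]]]
    z <- drop(net$W1 %*% G[a, ]) + net$b1
    tt <- net$act == "tanh"
    z[tt] <- tanh(z[tt])
    z
  })
}

# elementwise first/second activation derivatives given activations phi
.act_derivs <- function(net, phi) {
  tt <- net$act == "tanh"
  p1 <- rep(1, length(phi))
  p2 <- numeric(length(phi))
  p1[tt] <- 1 - phi[tt]^2
  p2[tt] <- -2 * phi[tt] * p1[tt]
  list(p1 = p1, p2 = p2)
}

.check_alphabet <- function(model, species) {
  bad <- setdiff(unique(species), model$spec$elements)
  if (length(bad) > 0L) {
    stop(sprintf("element(s) outside model alphabet: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Predict molecular energies for a batch
#'
#' E(molecule) = sum over atoms of the element network output plus the
#' per-element reference energies. Padded atoms contribute exactly zero.
#'
#' @param model a `potential_model`.
#' @param batch a `padded_batch` (or list of [labeled_structure()]).
#' @return numeric vector of per-molecule energies, kcal/mol.
#' @export
predict_energy <- function(model, batch) {
  structs <- .as_structure_list(batch)
  vapply(structs, function(s) {
    .check_alphabet(model, s$species)
    aev <- aev_structure(s, spec = model$spec, deriv = 0L)
    phi <- .atomic_features(model, aev$G, s$species)
    e <- 0
    for (a in seq_along(phi)) {
      net <- model$nets[[s$species[a]]]
      e <- e + sum(net$w * phi[[a]]) + model$ref_energies[[s$species[a]]]
    }
    e
  }, numeric(1))
}

.as_structure_list <- function(batch) {
  if (inherits(batch, "padded_batch")) unbatch_structures(batch)
  else if (inherits(batch, "labeled_structure")) list(batch)
  else if (is.list(batch)) batch
  else stop("expected a padded_batch or list of structures", call. = FALSE)
}

#' Ensemble mean and standard deviation of predicted energies
#'
#' @param ensemble a `potential_ensemble` with >= 2 members.
#' @param batch a `padded_batch` or structure list.
#' @return list `mean`, `sd` (sample standard deviation over members),
#'   and `per_member` (members x molecules matrix).
#' @export
ensemble_stats <- function(ensemble, batch) {
  stopifnot(inherits(ensemble, "potential_ensemble"))
  if (length(ensemble$members) < 2L) {
    stop("ensemble standard deviation requires at least 2 members", call. = FALSE)
  }
  per <- do.call(rbind, lapply(ensemble$members,
                               function(m) predict_energy(m, batch)))
  list(mean = colMeans(per), sd = apply(per, 2, stats::sd), per_member = per)
}
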