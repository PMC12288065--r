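# Langevin molecular dynamics with the iterative heating protocol and the
# bond-distortion stability failure criterion.
#
# Dynamics: BAOAB splitting of Langevin dynamics (friction gamma, target
# temperature T). Internal units: A, fs, amu, kcal/mol; accelerations use
# the kcal/mol/A/amu -> A/fs^2 conversion from codata_constants.
#
# Failure criterion: the run fails at the first step where, for some
# monitored pair (i, j), the mean distance over the trailing 50-step window
# exceeds 1.5 * d_eq or falls below 0.75 * d_eq (strict inequalities);
# d_eq is the pair distance in the geometry-optimized starting structure.
# Monitored pairs default to the bonded pairs of the molecule.

#' Temperature-ramp protocol
#'
#' Iterative heating: stages of `stage_ps` picoseconds at fixed target
#' temperature, starting at `t_start` K and increasing by `t_step` K per
#' stage until failure or `t_cap`.
#'
#' @param t_start starting temperature, K (default 5).
#' @param t_step per-stage increment, K (default 5).
#' @param stage_ps stage length, ps (default 5; 10,000 steps at 0.5 fs).
#' @param dt time step, fs (default 0.5).
#' @param friction Langevin friction, 1/fs (default 0.01).
#' @param t_cap stop temperature when no failure occurs, K.
#' @param seed seed for thermostat noise and initial velocities.
#' @export
ramp_protocol <- function(t_start = 5, t_step = 5, stage_ps = 5, dt = 0.5,
                          friction = 0.01, t_cap = 2500, seed = 1L) {
  stopifnot(t_start > 0, t_step > 0, stage_ps > 0, dt > 0, friction > 0,
            t_cap >= t_start)
  structure(list(t_start = t_start, t_step = t_step, stage_ps = stage_ps,
                 dt = dt, friction = friction, t_cap = t_cap,
                 seed = as.integer(seed),
                 stage_steps = round(stage_ps * 1000 / dt)),
            class = "ramp_protocol")
}

# force provider: function(X) -> list(energy, forces) for a fixed molecule
#' Force function of a model or reference surface for one molecule
#'
#' @param model a `potential_model` or `reference_ff`.
#' @param species element symbols of the molecule.
#' @return function mapping an n x 3 coordinate matrix to
#'   `list(energy, forces)`.
#' @export
force_function <- function(model, species) {
  if (inherits(model, "reference_ff")) {
    function(X) {
      ev <- eval_reference(model, X)
      list(energy = ev$energy, forces = ev$forces)
    }
  } else if (inherits(model, "potential_model")) {
    .check_alphabet(model, species)
    nets <- model$nets[species]
    ref_sum <- sum(model$ref_energies[species])
    spec <- model$spec
    n <- length(species)
    function(X) {
      aev <- aev_structure(X, species, spec, deriv = 1L)
      E <- ref_sum
      g <- numeric(3L * n)
      for (a in seq_len(n)) {
        net <- nets[[a]]
        phi <- drop(net$W1 %*% aev$G[a, ]) + net$b1
        tt <- net$act == "tanh"
        phi[tt] <- tanh(phi[tt])
        E <- E + sum(net$w * phi)
        ad <- .act_derivs(net, phi)
        v <- drop(crossprod(net$W1, net$w * ad$p1))
        g <- g + drop(crossprod(aev$J[[a]], v))
      }
      list(energy = E, forces = matrix(-g, n, 3L, byrow = TRUE))
    }
  } else stop("model must be a potential_model or reference_ff", call. = FALSE)
}

#' One Langevin stage at fixed target temperature
#'
#' BAOAB integration; velocities persist across stages via the returned
#' state. Seed-reproducible through the supplied RNG.
#'
#' @param force_fn from [force_function()].
#' @param state list `X` (n x 3), `V` (n x 3, A/fs), `masses`.
#' @param temperature target temperature, K.
#' @param protocol a [ramp_protocol()].
#' @param rng seeded RNG (internal); when NULL a fresh one from
#'   `protocol$seed` is used.
#' @param n_steps number of steps (defaults to the protocol stage length).
#' @param record_every store every k-th frame (0 = none).
#' @return list `state` (final), `distances` (steps x n_pairs matrix of all
#'   pair distances), `temperature_trace` (instantaneous kinetic T per step),
#'   `frames` (optional list of coordinate matrices).
#' @export
langevin_stage <- function(force_fn, state, temperature, protocol,
                           rng = NULL, n_steps = protocol$stage_steps,
                           record_every = 0L) {
  stopifnot(all(state$masses > 0))
  if (is.null(rng)) rng <- .seeded_rng(protocol$seed)
  X <- state$X; V <- state$V
  n <- nrow(X)
  m <- state$masses
  acc_f <- codata_constants$acc_factor
  kB <- codata_constants$kB_kcal
  dt <- protocol$dt
  c1 <- exp(-protocol$friction * dt)
  sig <- sqrt(kB * temperature * acc_f / m * (1 - c1^2))  # per atom, A/fs
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dists <- matrix(0, n_steps, nrow(pair_idx))
  ttrace <- numeric(n_steps)
  frames <- if (record_every > 0L) list()
  fr <- force_fn(X)
  A <- fr$forces * acc_f / m                              # A/fs^2
  for (step in seq_len(n_steps)) {
    V <- V + 0.5 * dt * A
    X <- X + 0.5 * dt * V
    xi <- matrix(rng$norm(3 * n), n, 3L)
    V <- c1 * V + sig * xi
    X <- X + 0.5 * dt * V
    fr <- force_fn(X)
    if (!all(is.finite(fr$forces))) {
      stop(sprintf("force evaluation failed at step %d", step), call. = FALSE)
    }
    A <- fr$forces * acc_f / m
    V <- V + 0.5 * dt * A
    d <- X[pair_idx[, 1], , drop = FALSE] - X[pair_idx[, 2], , drop = FALSE]
    dists[step, ] <- sqrt(rowSums(d^2))
    ke <- 0.5 * sum(m * rowSums(V^2)) / acc_f             # kcal/mol
    ttrace[step] <- 2 * ke / (3 * n * kB)
    if (record_every > 0L && step %% record_every == 0L) {
      frames[[length(frames) + 1L]] <- X
    }
  }
  list(state = list(X = X, V = V, masses = m), distances = dists,
       pair_index = pair_idx, temperature_trace = ttrace, frames = frames)
}

#' Bond-distortion failure check
#'
#' Applies the distortion criterion to one trailing window of pair
#' distances: failure iff some monitored pair's window-mean distance exceeds
#' 1.5 d_eq (stretch) or falls below 0.75 d_eq (compression), strictly.
#'
#' @param window 50 x n_pairs matrix of distances (the trailing window),
#'   columns ordered as `ref_bonds` rows.
#' @param ref_bonds data frame `i`, `j`, `d_eq` from the optimized geometry.
#' @return list `failed`, and when failed: `pair` (i, j), `direction`
#'   (`"stretch"`/`"compression"`), `ratio`.
#' @export
failure_check <- function(window, ref_bonds) {
  window <- as.matrix(window)
  if (nrow(window) != 50L) {
    stop("failure window must contain exactly 50 steps", call. = FALSE)
  }
  stopifnot(ncol(window) == nrow(ref_bonds))
  mu <- colMeans(window)
  ratio <- mu / ref_bonds$d_eq
  if (any(ratio > 1.5)) {
    k <- which.max(ratio)
    return(list(failed = TRUE, pair = c(ref_bonds$i[k], ref_bonds$j[k]),
                direction = "stretch", ratio = ratio[k]))
  }
  if (any(ratio < 0.75)) {
    k <- which.min(ratio)
    return(list(failed = TRUE, pair = c(ref_bonds$i[k], ref_bonds$j[k]),
                direction = "compression", ratio = ratio[k]))
  }
  list(failed = FALSE)
}

#' Iterative heating stability run
#'
#' Geometry-optimizes the molecule on the supplied model surface, defines
#' equilibrium distances for the monitored pairs, then runs Langevin stages
#' with rising target temperature until the distortion criterion fires or
#' the cap is reached. The check is evaluated every step once 50 steps
#' exist, over the trailing 50-step window; velocities carry over between
#' stages.
#'
#' @param model `potential_model` or `reference_ff` (the ground-truth
#'   control).
#' @param structure starting [labeled_structure()] (a reference minimum).
#' @param protocol a [ramp_protocol()].
#' @param bonds data frame `i`, `j` of monitored (bonded) pairs; default
#'   pairs within 1.3x the sum of covalent radii in the optimized geometry.
#' @param all_pairs monitor every pair instead (the "close contacts"
#'   reading).
#' @param opt_gtol max-force convergence for the pre-run optimization,
#'   kcal/mol/A.
#' @return `stability_result`: `failure_temperature` (K; the stage during
#'   which failure occurred, NA when the cap was reached or optimization
#'   failed), `total_time_ps`, `status` (`"failed"`, `"cap_reached"`,
#'   `"failed_optimization"`), `failing_pair`, `direction`.
#' @export
temperature_ramp <- function(model, structure, protocol = ramp_protocol(),
                             bonds = NULL, all_pairs = FALSE, opt_gtol = 1) {
  stopifnot(inherits(structure, "labeled_structure"))
  ffun <- force_function(model, structure$species)
  n <- length(structure$species)
  # optimize on the model surface before the run
  opt <- stats::optim(
    as.numeric(t(structure$coordinates)),
    fn = function(v) ffun(matrix(v, n, 3L, byrow = TRUE))$energy,
    gr = function(v) -as.numeric(t(ffun(matrix(v, n, 3L, byrow = TRUE))$forces)),
    method = "L-BFGS-B", control = list(maxit = 500)
  )
  X0 <- matrix(opt$par, n, 3L, byrow = TRUE)
  gmax <- max(abs(ffun(X0)$forces))
  if (!is.finite(opt$value) || gmax > opt_gtol) {
    return(structure(list(failure_temperature = NA_real_, total_time_ps = 0,
                          status = "failed_optimization", failing_pair = NULL,
                          direction = NULL, protocol = protocol),
                     class = "stability_result"))
  }
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d0 <- sqrt(rowSums((X0[pair_idx[, 1], , drop = FALSE] -
                        X0[pair_idx[, 2], , drop = FALSE])^2))
  if (is.null(bonds)) {
    if (all_pairs) {
      keep <- seq_len(nrow(pair_idx))
    } else {
      rad <- .covalent_radii(structure$species)
      keep <- which(d0 < 1.3 * (rad[pair_idx[, 1]] + rad[pair_idx[, 2]]))
    }
  } else {
    keep <- vapply(seq_len(nrow(bonds)), function(b) {
      which((pair_idx[, 1] == min(bonds$i[b], bonds$j[b]) &
               pair_idx[, 2] == max(bonds$i[b], bonds$j[b])) |
              (pair_idx[, 2] == min(bonds$i[b], bonds$j[b]) &
                 pair_idx[, 1] == max(bonds$i[b], bonds$j[b])))
    }, integer(1))
  }
  if (length(keep) == 0L) stop("no monitored pairs", call. = FALSE)
  ref_bonds <- data.frame(i = pair_idx[keep, 1], j = pair_idx[keep, 2],
                          d_eq = d0[keep])

  rng <- .seeded_rng(protocol$seed)
  kB <- codata_constants$kB_kcal
  acc_f <- codata_constants$acc_factor
  masses <- structure$masses
  V0 <- matrix(rng$norm(3 * n), n, 3L) *
    sqrt(kB * protocol$t_start * acc_f / masses)
  state <- list(X = X0, V = V0, masses = masses)
  temps <- seq(protocol$t_start, protocol$t_cap, by = protocol$t_step)
  hist_buf <- NULL   # trailing distances across stage boundaries
  elapsed_steps <- 0L
  for (Tt in temps) {
    st <- langevin_stage(ffun, state, Tt, protocol, rng = rng)
    state <- st$state
    dists <- st$distances[, keep, drop = FALSE]
    combined <- rbind(hist_buf, dists)
    for (step in seq_len(nrow(dists))) {
      endrow <- nrow(combined) - nrow(dists) + step
      if (endrow < 50L) next
      verdict <- failure_check(combined[(endrow - 49L):endrow, , drop = FALSE],
                               ref_bonds)
      if (verdict$failed) {
        elapsed_steps <- elapsed_steps + step
        return(structure(
          list(failure_temperature = Tt,
               total_time_ps = elapsed_steps * protocol$dt / 1000,
               status = "failed", failing_pair = verdict$pair,
               direction = verdict$direction, protocol = protocol),
          class = "stability_result"))
      }
    }
    elapsed_steps <- elapsed_steps + nrow(dists)
    hist_buf <- combined[max(1L, nrow(combined) - 48L):nrow(combined), ,
                         drop = FALSE]
  }
  structure(list(failure_temperature = NA_real_,
                 total_time_ps = elapsed_steps * protocol$dt / 1000,
                 status = "cap_reached", failing_pair = NULL,
                 direction = NULL, protocol = protocol),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  if (x$status == "failed") {
    cat(sprintf("<stability_result: failed at %g K after %.2f ps (%s of pair %d-%d)>\n",
                x$failure_temperature, x$total_time_ps, x$direction,
                x$failing_pair[1], x$failing_pair[2]))
  } else {
    cat(sprintf("<stability_result: %s after %.2f ps>\n", x$status,
                x$total_time_ps))
  }
  invisible(x)
}

.covalent_radii <- function(species) {
  tab <- c(X = 0.8, H = 0.31, C = 0.76, N = 0.71, O = 0.66,
           F = 0.57, S = 1.05, Cl = 1.02)
  unknown <- setdiff(unique(species), names(tab))
  if (length(unknown) > 0L) {
    stop(sprintf("no covalent radius for: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  unname(tab[species])
}
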