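# Normal mode sampling: random displacement of a geometry along its
# mass-weighted vibrational normal modes, excluding a designated
# reaction-coordinate mode (and, by default, the trans/rot null space via a
# stiffness floor).
#
# Displacement law (declared; the magnitude rule follows the ANI-lineage NMS
# recipe): per retained mode i with mass-weighted force constant k_i, the
# coefficient is c_i = +/- sqrt(3 kB T R / k_i) with R ~ Uniform(0,1) and a
# random sign, so the mean harmonic potential energy per mode is
# (3/4) kB T. Cartesian displacement = M^(-1/2) sum_i c_i q_i.

#' Normal-mode-sampling configuration
#'
#' @param temperature sampling temperature, K.
#' @param n_samples draws per structure.
#' @param seed integer seed.
#' @param excluded_mode optional reaction-coordinate mode to suppress: a
#'   3n-long mass-weighted vector (normalized internally) or a mode index
#'   into the ascending-eigenvalue order.
#' @param k_floor modes with mass-weighted force constant below this are
#'   skipped (removes the trans/rot null space), kcal/mol/(amu A^2).
#' @param max_disp per-atom displacement safety clip, A.
#' @export
nms_config <- function(temperature = 300, n_samples = 10L, seed = 1L,
                       excluded_mode = NULL, k_floor = 1, max_disp = 0.5) {
  stopifnot(temperature > 0, n_samples >= 1L, k_floor >= 0, max_disp > 0)
  structure(list(temperature = temperature, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), excluded_mode = excluded_mode,
                 k_floor = k_floor, max_disp = max_disp),
            class = "nms_config")
}

#' Sample perturbed structures by normal mode sampling
#'
#' @param structure a [labeled_structure()] (labels are not copied: outputs
#'   are coordinates-only, to be relabeled by [eval_reference()] or a model).
#' @param hessian 3n x 3n Hessian at the structure, kcal/mol/A^2 (defaults
#'   to the structure's own label).
#' @param config an [nms_config()].
#' @return list of unlabeled [labeled_structure()] objects.
#' @export
sample_nms <- function(structure, hessian = structure$hessian,
                       config = nms_config()) {
  stopifnot(inherits(structure, "labeled_structure"),
            inherits(config, "nms_config"))
  if (is.null(hessian)) stop("a Hessian is required", call. = FALSE)
  n <- length(structure$species)
  masses <- structure$masses
  stopifnot(all(masses > 0))
  sqm <- sqrt(rep(masses, each = 3L))
  Hmw <- hessian / tcrossprod(sqm)
  Hmw <- (Hmw + t(Hmw)) / 2
  es <- eigen(Hmw, symmetric = TRUE)   # ascending after reverse
  lam <- rev(es$values)
  Q <- es$vectors[, rev(seq_along(es$values)), drop = FALSE]

  excl <- config$excluded_mode
  excl_vec <- NULL
  if (!is.null(excl)) {
    if (length(excl) == 1L && is.numeric(excl) && excl == round(excl)) {
      if (excl < 1 || excl > 3 * n) {
        stop(sprintf("excluded mode index %d outside 1..%d", excl, 3 * n),
             call. = FALSE)
      }
      excl_vec <- Q[, excl]
    } else {
      excl <- as.numeric(excl)
      if (length(excl) != 3 * n) {
        stop("excluded_mode vector must have length 3n", call. = FALSE)
      }
      nrm <- sqrt(sum(excl^2))
      if (nrm < 1e-12) stop("excluded_mode vector is zero", call. = FALSE)
      excl_vec <- excl / nrm
    }
  }

  retained <- which(lam > config$k_floor)
  kB <- codata_constants$kB_kcal
  rng <- .seeded_rng(config$seed)
  out <- vector("list", config$n_samples)
  for (s in seq_len(config$n_samples)) {
    disp_mw <- numeric(3 * n)
    if (length(retained) > 0L) {
      R <- rng$unif(length(retained))
      sgn <- sign(rng$unif(length(retained)) - 0.5)
      ci <- sgn * sqrt(3 * kB * config$temperature * R / lam[retained])
      disp_mw <- drop(Q[, retained, drop = FALSE] %*% ci)
    }
    if (!is.null(excl_vec)) {
      disp_mw <- disp_mw - sum(disp_mw * excl_vec) * excl_vec
    }
    dx <- matrix(disp_mw / sqm, n, 3L, byrow = TRUE)
    per_atom <- sqrt(rowSums(dx^2))
    over <- per_atom > config$max_disp
    if (any(over)) {
      dx[over, ] <- dx[over, ] * (config$max_disp / per_atom[over])
    }
    out[[s]] <- labeled_structure(structure$species,
                                  structure$coordinates + dx)
  }
  out
}
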