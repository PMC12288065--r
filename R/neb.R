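# Nudged elastic band with climbing image.
#
# Standard projected NEB forces: the spring force acts along the local
# tangent, the true force perpendicular to it; the climbing image feels the
# full true force with its parallel component inverted and no springs.
# Tangents use the energy-weighted upwind ("improved") estimate. The band is
# relaxed with FIRE; convergence is the max per-atom projected-force norm.

#' Linear interpolation between two endpoint geometries
#'
#' @param reactant,product [labeled_structure()] with identical species
#'   sequences.
#' @param n_images total number of images including the endpoints (>= 3).
#' @return list of structures; endpoints are exact copies.
#' @export
interpolate_path <- function(reactant, product, n_images) {
  stopifnot(inherits(reactant, "labeled_structure"),
            inherits(product, "labeled_structure"), n_images >= 3L)
  if (!identical(reactant$species, product$species)) {
    stop("endpoint species sequences differ", call. = FALSE)
  }
  fr <- seq(0, 1, length.out = n_images)
  lapply(fr, function(f) {
    labeled_structure(reactant$species,
                      (1 - f) * reactant$coordinates + f * product$coordinates)
  })
}

#' Optimize a minimum-energy path by (CI-)NEB
#'
#' @param model `potential_model` or `reference_ff` supplying energies and
#'   forces.
#' @param images initial band from [interpolate_path()] (endpoints assumed
#'   pre-optimized on the model surface; they stay fixed).
#' @param spring_k spring constant in eV/A^2 (converted internally; default
#'   50).
#' @param climb enable climbing image for the highest-energy interior image.
#' @param fmax_tol convergence threshold on the max per-atom projected-force
#'   norm, eV/A (converted internally; default 0.05).
#' @param max_iter FIRE iteration cap.
#' @return object of class `mep`: `images` (with model energies), `energies`
#'   (kcal/mol), `arc` (mass-weighted, highest image at 0), `converged`,
#'   `fmax` (kcal/mol/A), `climb_index`.
#' @export
optimize_mep <- function(model, images, spring_k = 50, climb = TRUE,
                         fmax_tol = 0.05, max_iter = 2000L) {
  stopifnot(length(images) >= 3L)
  species <- images[[1]]$species
  n <- length(species)
  ni <- length(images)
  ffun <- force_function(model, species)
  k_int <- spring_k * codata_constants$ev_kcal          # kcal/mol/A^2
  ftol_int <- fmax_tol * codata_constants$ev_kcal       # kcal/mol/A
  R <- lapply(images, function(s) s$coordinates)

  band_forces <- function(R) {
    ev <- lapply(R, ffun)
    E <- vapply(ev, `[[`, numeric(1), "energy")
    imax <- if (climb) which.max(E[2:(ni - 1)]) + 1L else -1L
    Fproj <- vector("list", ni)
    for (i in 2:(ni - 1)) {
      dplus <- R[[i + 1]] - R[[i]]
      dminus <- R[[i]] - R[[i - 1]]
      # energy-weighted upwind tangent
      if (E[i + 1] > E[i] && E[i] > E[i - 1]) {
        tau <- dplus
      } else if (E[i + 1] < E[i] && E[i] < E[i - 1]) {
        tau <- dminus
      } else {
        dEmax <- max(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        dEmin <- min(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        tau <- if (E[i + 1] > E[i - 1]) dplus * dEmax + dminus * dEmin
               else dplus * dEmin + dminus * dEmax
      }
      tau <- tau / sqrt(sum(tau^2))
      Ftrue <- ev[[i]]$forces
      fpar <- sum(Ftrue * tau)
      if (i == imax) {
        Fproj[[i]] <- Ftrue - 2 * fpar * tau            # climbing image
      } else {
        fperp <- Ftrue - fpar * tau
        fspring <- k_int * (sqrt(sum(dplus^2)) - sqrt(sum(dminus^2)))
        Fproj[[i]] <- fperp + fspring * tau
      }
    }
    list(F = Fproj, E = E, imax = imax)
  }

  # FIRE parameters (standard defaults)
  dt <- 0.05; dt_max <- 0.5; a_start <- 0.1
  a <- a_start; n_up <- 0L
  V <- lapply(seq_len(ni), function(i) matrix(0, n, 3L))
  converged <- FALSE
  fmax <- Inf
  bf <- band_forces(R)
  for (it in seq_len(max_iter)) {
    fmax <- max(vapply(2:(ni - 1), function(i) {
      sqrt(max(rowSums(bf$F[[i]]^2)))
    }, numeric(1)))
    if (fmax <= ftol_int) { converged <- TRUE; break }
    P <- sum(vapply(2:(ni - 1), function(i) sum(V[[i]] * bf$F[[i]]), numeric(1)))
    vnorm <- sqrt(sum(vapply(2:(ni - 1), function(i) sum(V[[i]]^2), numeric(1))))
    fnorm <- sqrt(sum(vapply(2:(ni - 1), function(i) sum(bf$F[[i]]^2), numeric(1))))
    if (P > 0) {
      for (i in 2:(ni - 1)) {
        V[[i]] <- (1 - a) * V[[i]] + a * vnorm * bf$F[[i]] / max(fnorm, 1e-300)
      }
      n_up <- n_up + 1L
      if (n_up > 5L) { dt <- min(dt * 1.1, dt_max); a <- a * 0.99 }
    } else {
      for (i in 2:(ni - 1)) V[[i]][] <- 0
      a <- a_start; dt <- dt * 0.5; n_up <- 0L
    }
    for (i in 2:(ni - 1)) {
      V[[i]] <- V[[i]] + dt * bf$F[[i]]
      step <- dt * V[[i]]
      snorm <- sqrt(max(rowSums(step^2)))
      if (snorm > 0.2) step <- step * (0.2 / snorm)     # per-iteration clip
      R[[i]] <- R[[i]] + step
    }
    bf <- band_forces(R)
  }
  E <- bf$E
  out_images <- lapply(seq_len(ni), function(i) {
    labeled_structure(species, R[[i]], energy = E[i])
  })
  # mass-weighted arc length, highest-energy image at zero
  sqm <- sqrt(rep(images[[1]]$masses, each = 3L))
  seg <- vapply(2:ni, function(i) {
    sqrt(sum(((as.numeric(t(R[[i]])) - as.numeric(t(R[[i - 1]]))) * sqm)^2))
  }, numeric(1))
  arc <- c(0, cumsum(seg))
  arc <- arc - arc[which.max(E)]
  structure(list(images = out_images, energies = E, arc = arc,
                 spring_k = spring_k, converged = converged,
                 fmax = fmax, climb_index = bf$imax,
                 climb = climb),
            class = "mep")
}

#' @export
print.mep <- function(x, ...) {
  cat(sprintf("<mep: %d images, barrier %.3f kcal/mol from reactant, %s (fmax %.3g)>\n",
              length(x$images), max(x$energies) - x$energies[1],
              if (x$converged) "converged" else "NOT converged", x$fmax))
  invisible(x)
}

#' Barrier height of an optimized path
#'
#' @param mep an `mep` from [optimize_mep()].
#' @param reference_end `"reactant"` (first image) or `"product"` (last).
#' @param force_unconverged evaluate even if the band did not converge.
#' @return max image energy minus the chosen endpoint energy, kcal/mol.
#' @export
barrier_height <- function(mep, reference_end = c("reactant", "product"),
                           force_unconverged = FALSE) {
  stopifnot(inherits(mep, "mep"))
  reference_end <- match.arg(reference_end)
  if (!mep$converged && !force_unconverged) {
    stop("band is not converged (use force_unconverged = TRUE to override)",
         call. = FALSE)
  }
  eref <- if (reference_end == "reactant") mep$energies[1]
          else mep$energies[length(mep$energies)]
  max(mep$energies) - eref
}
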