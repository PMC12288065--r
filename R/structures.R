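# Structure and batch data model.
#
# A labeled_structure holds one molecule with optional energy / force /
# Hessian labels (kcal/mol, kcal/mol/A, kcal/mol/A^2). A padded_batch packs M
# molecules into dense tensors padded to the largest atom count N, with an
# explicit atom mask; label entries at padded positions are exactly zero.

#' Create a labeled molecular structure
#'
#' @param species character vector of element symbols (length n).
#' @param coordinates n x 3 numeric matrix, Angstrom.
#' @param energy optional scalar potential energy, kcal mol^-1.
#' @param forces optional n x 3 matrix, kcal mol^-1 A^-1 (negative gradient).
#' @param hessian optional 3n x 3n symmetric matrix, kcal mol^-1 A^-2.
#' @return object of class `labeled_structure` with derived per-atom `masses`.
#' @export
labeled_structure <- function(species, coordinates, energy = NULL,
                              forces = NULL, hessian = NULL) {
  species <- as.character(species)
  n <- length(species)
  if (n < 1L) stop("structure must contain at least one atom", call. = FALSE)
  coordinates <- as.matrix(coordinates)
  if (!all(dim(coordinates) == c(n, 3L))) {
    stop(sprintf("coordinates must be %d x 3", n), call. = FALSE)
  }
  if (!all(is.finite(coordinates))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (!is.null(energy)) {
    stopifnot(length(energy) == 1L, is.finite(energy))
    energy <- as.numeric(energy)
  }
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    if (!all(dim(forces) == c(n, 3L)) || !all(is.finite(forces))) {
      stop(sprintf("forces must be a finite %d x 3 matrix", n), call. = FALSE)
    }
  }
  if (!is.null(hessian)) {
    hessian <- as.matrix(hessian)
    if (!all(dim(hessian) == c(3L * n, 3L * n)) || !all(is.finite(hessian))) {
      stop(sprintf("hessian must be a finite %d x %d matrix", 3 * n, 3 * n),
           call. = FALSE)
    }
    asym <- max(abs(hessian - t(hessian)))
    scale <- max(abs(hessian), 1e-300)
    if (asym / scale > 1e-8) {
      stop(sprintf("hessian not symmetric (relative asymmetry %.2e)", asym / scale),
           call. = FALSE)
    }
  }
  structure(
    list(species = species, coordinates = coordinates, energy = energy,
         forces = forces, hessian = hessian, masses = atomic_masses(species)),
    class = "labeled_structure"
  )
}

#' @export
print.labeled_structure <- function(x, ...) {
  lab <- c(if (!is.null(x$energy)) "E", if (!is.null(x$forces)) "F",
           if (!is.null(x$hessian)) "H")
  cat(sprintf("<labeled_structure: %d atoms [%s]%s>\n",
              length(x$species), paste(x$species, collapse = " "),
              if (length(lab)) paste0(", labels: ", paste(lab, collapse = "+"))
              else ", unlabeled"))
  invisible(x)
}

n_atoms <- function(s) length(s$species)

#' Pack structures into a zero-padded batch
#'
#' Pads M molecules to the common atom count N (the batch maximum). Species
#' use the reserved padding code 0 in an integer grid over the batch element
#' alphabet; all label tensors are zero at padded positions, and an explicit
#' logical `atom_mask` records which slots are real atoms. Each label kind
#' (energy, forces, hessian) must be present for all structures or absent for
#' all.
#'
#' @param structures list of [labeled_structure()] objects.
#' @return object of class `padded_batch` with fields `species` (M x N integer,
#'   0 = padding), `elements` (alphabet), `coordinates` (M x N x 3),
#'   `energies` (M or NULL), `forces` (M x N x 3 or NULL), `hessians`
#'   (M x 3N x 3N or NULL), `atom_mask` (M x N logical), `n_atoms`.
#' @export
build_batch <- function(structures) {
  if (!is.list(structures) || length(structures) == 0L) {
    stop("structures must be a nonempty list", call. = FALSE)
  }
  ok <- vapply(structures, inherits, logical(1), "labeled_structure")
  if (!all(ok)) stop("all elements must be labeled_structure objects", call. = FALSE)
  M <- length(structures)
  nat <- vapply(structures, n_atoms, integer(1))
  N <- max(nat)
  has <- function(field) vapply(structures, function(s) !is.null(s[[field]]), logical(1))
  for (field in c("energy", "forces", "hessian")) {
    h <- has(field)
    if (any(h) && !all(h)) {
      stop(sprintf("label '%s' present for some structures but not all", field),
           call. = FALSE)
    }
  }
  elements <- sort(unique(unlist(lapply(structures, `[[`, "species"))))
  species <- matrix(0L, M, N)
  coords <- array(0, c(M, N, 3L))
  mask <- matrix(FALSE, M, N)
  energies <- if (has("energy")[1]) numeric(M) else NULL
  forces <- if (has("forces")[1]) array(0, c(M, N, 3L)) else NULL
  hessians <- if (has("hessian")[1]) array(0, c(M, 3L * N, 3L * N)) else NULL
  for (i in seq_len(M)) {
    s <- structures[[i]]
    n <- nat[i]
    species[i, seq_len(n)] <- match(s$species, elements)
    coords[i, seq_len(n), ] <- s$coordinates
    mask[i, seq_len(n)] <- TRUE
    if (!is.null(energies)) energies[i] <- s$energy
    if (!is.null(forces)) forces[i, seq_len(n), ] <- s$forces
    if (!is.null(hessians)) hessians[i, seq_len(3 * n), seq_len(3 * n)] <- s$hessian
  }
  structure(
    list(species = species, elements = elements, coordinates = coords,
         energies = energies, forces = forces, hessians = hessians,
         atom_mask = mask, n_atoms = nat),
    class = "padded_batch"
  )
}

#' @export
print.padded_batch <- function(x, ...) {
  cat(sprintf("<padded_batch: M=%d molecules, N=%d (padded), elements: %s>\n",
              nrow(x$species), ncol(x$species), paste(x$elements, collapse = " ")))
  invisible(x)
}

#' Recover the individual structures from a padded batch
#'
#' Inverse of [build_batch()]: strips padding and rebuilds each
#' [labeled_structure()] bit-exactly.
#'
#' @param batch a `padded_batch`.
#' @return list of `labeled_structure`.
#' @export
unbatch_structures <- function(batch) {
  stopifnot(inherits(batch, "padded_batch"))
  lapply(seq_len(nrow(batch$species)), function(i) {
    n <- batch$n_atoms[i]
    idx <- seq_len(n)
    labeled_structure(
      species = batch$elements[batch$species[i, idx]],
      coordinates = matrix(batch$coordinates[i, idx, ], n, 3L),
      energy = batch$energies[i],
      forces = if (!is.null(batch$forces)) matrix(batch$forces[i, idx, ], n, 3L),
      hessian = if (!is.null(batch$hessians)) {
        m <- seq_len(3L * n)
        batch$hessians[i, m, m, drop = TRUE]
      }
    )
  })
}

#' Count molecules and unmasked force / Hessian elements
#'
#' Returns the denominators of the force and Hessian RMSE loss terms:
#' `n_F` = 3 * sum of atom counts, `n_H` = sum over molecules of (3 n_i)^2.
#' Padded elements are excluded from both counts.
#'
#' @param batch a `padded_batch`.
#' @return named list `(M, n_F, n_H)`.
#' @export
mask_counts <- function(batch) {
  stopifnot(inherits(batch, "padded_batch"))
  nat <- batch$n_atoms
  list(M = length(nat), n_F = sum(3L * nat), n_H = sum((3L * nat)^2))
}
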