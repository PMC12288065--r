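# File formats: multi-frame extended-XYZ for geometries/forces, a JSON
# dataset container for full labeled datasets (extended-XYZ has no 3Nx3N
# Hessian convention), and YAML run configs.
#
# Units are fixed package-wide (kcal/mol, A) and asserted through a
# mandatory units key on every extended-XYZ frame.

.xyz_units_key <- "kcal_per_mol,angstrom"

#' Write structures to extended-XYZ
#'
#' Multi-frame extended-XYZ: per-frame comment line carries
#' `Properties=...`, a mandatory `units` key, and `energy` when present;
#' forces become per-atom columns. Hessians are not representable here (use
#' [write_dataset()]).
#'
#' @param structures list of [labeled_structure()] (or a single one).
#' @param path output file.
#' @export
write_extxyz <- function(structures, path) {
  structures <- .as_structure_list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    n <- length(s$species)
    props <- "species:S:1:pos:R:3"
    if (!is.null(s$forces)) props <- paste0(props, ":forces:R:3")
    header <- sprintf('Properties=%s units="%s"', props, .xyz_units_key)
    if (!is.null(s$energy)) {
      header <- sprintf("%s energy=%.17g", header, s$energy)
    }
    writeLines(as.character(n), con)
    writeLines(header, con)
    for (a in seq_len(n)) {
      line <- sprintf("%-3s %.17g %.17g %.17g", s$species[a],
                      s$coordinates[a, 1], s$coordinates[a, 2],
                      s$coordinates[a, 3])
      if (!is.null(s$forces)) {
        line <- sprintf("%s %.17g %.17g %.17g", line,
                        s$forces[a, 1], s$forces[a, 2], s$forces[a, 3])
      }
      writeLines(line, con)
    }
  }
  invisible(path)
}

#' Read structures from extended-XYZ
#'
#' @param path file written by [write_extxyz()] (or compatible).
#' @return list of [labeled_structure()]; forces/energy set when present.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]),
           call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop(sprintf("line %d: frame of %d atoms truncated", i, n), call. = FALSE)
    }
    header <- lines[i + 1L]
    if (!grepl("units=", header, fixed = TRUE)) {
      stop(sprintf("line %d: missing mandatory units key", i + 1L), call. = FALSE)
    }
    um <- regmatches(header, regexec('units="([^"]*)"', header))[[1]][2]
    if (!identical(um, .xyz_units_key)) {
      stop(sprintf("line %d: unsupported units '%s' (expected '%s')",
                   i + 1L, um, .xyz_units_key), call. = FALSE)
    }
    has_forces <- grepl("forces:R:3", header, fixed = TRUE)
    energy <- NULL
    em <- regmatches(header, regexec("energy=([-+0-9.eE]+)", header))[[1]]
    if (length(em) == 2L) energy <- as.numeric(em[2])
    species <- character(n)
    coords <- matrix(0, n, 3L)
    forces <- if (has_forces) matrix(0, n, 3L)
    for (a in seq_len(n)) {
      tok <- strsplit(trimws(lines[i + 1L + a]), "\\s+")[[1]]
      need <- if (has_forces) 7L else 4L
      if (length(tok) < need) {
        stop(sprintf("line %d: expected %d fields, got %d", i + 1L + a,
                     need, length(tok)), call. = FALSE)
      }
      species[a] <- tok[1]
      coords[a, ] <- as.numeric(tok[2:4])
      if (has_forces) forces[a, ] <- as.numeric(tok[5:7])
    }
    out[[length(out) + 1L]] <- labeled_structure(species, coords,
                                                 energy = energy,
                                                 forces = forces)
    i <- i + 2L + n
  }
  out
}

#' Write a labeled dataset container
#'
#' JSON container with a manifest (counts, units, provenance) and
#' full-precision per-structure records including flattened Hessians with
#' shape metadata. Numbers are serialized with 17 significant digits so
#' every record round-trips bit-exactly.
#'
#' @param structures list of [labeled_structure()].
#' @param path output `.json` file.
#' @param provenance optional list (seed, generator parameters, ...).
#' @export
write_dataset <- function(structures, path, provenance = list()) {
  structures <- .as_structure_list(structures)
  records <- lapply(structures, function(s) {
    rec <- list(species = s$species,
                coordinates = as.numeric(t(s$coordinates)))
    if (!is.null(s$energy)) rec$energy <- s$energy
    if (!is.null(s$forces)) rec$forces <- as.numeric(t(s$forces))
    if (!is.null(s$hessian)) {
      rec$hessian <- as.numeric(s$hessian)
      rec$hessian_dim <- nrow(s$hessian)
    }
    rec
  })
  obj <- list(
    manifest = list(
      format = "hessnip-dataset-v1",
      n_structures = length(structures),
      units = list(energy = "kcal_per_mol", length = "angstrom",
                   forces = "kcal_per_mol/angstrom",
                   hessian = "kcal_per_mol/angstrom^2"),
      provenance = provenance
    ),
    records = records
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a labeled dataset container
#'
#' @param path file from [write_dataset()].
#' @return list with `structures` and `manifest`.
#' @export
read_dataset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$manifest$format, "hessnip-dataset-v1")) {
    stop("not a hessnip dataset container", call. = FALSE)
  }
  structures <- lapply(obj$records, function(rec) {
    n <- length(rec$species)
    labeled_structure(
      rec$species,
      matrix(rec$coordinates, n, 3L, byrow = TRUE),
      energy = rec$energy,
      forces = if (!is.null(rec$forces)) matrix(rec$forces, n, 3L, byrow = TRUE),
      hessian = if (!is.null(rec$hessian)) {
        matrix(rec$hessian, rec$hessian_dim, rec$hessian_dim)
      }
    )
  })
  if (length(structures) != obj$manifest$n_structures) {
    stop("manifest count does not match records", call. = FALSE)
  }
  list(structures = structures, manifest = obj$manifest)
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Save / load a potential model checkpoint
#'
#' Self-describing JSON checkpoint: AEV spec, architecture, all parameters,
#' reference energies and training provenance.
#'
#' @param model a `potential_model`.
#' @param path `.json` file.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "potential_model"))
  sp <- model$spec
  obj <- list(
    format = "hessnip-checkpoint-v1",
    aev_spec = list(elements = sp$elements, r_cut = sp$r_cut,
                    radial_shifts = sp$radial_shifts, eta_r = sp$eta_r,
                    n_angular = sp$n_angular,
                    angular_r_shifts = sp$angular_r_shifts, eta_a = sp$eta_a,
                    cutoff_fn = sp$cutoff_fn),
    n_hidden = model$n_hidden, n_feat = model$n_feat,
    activation = model$activation,
    seed = model$seed, ref_energies = as.list(model$ref_energies),
    provenance = model$provenance,
    nets = lapply(model$nets, function(net) {
      list(W1 = as.numeric(net$W1), b1 = net$b1, w = net$w, act = net$act)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "hessnip-checkpoint-v1")) {
    stop("not a hessnip checkpoint", call. = FALSE)
  }
  a <- obj$aev_spec
  spec <- aev_spec(elements = unlist(a$elements), r_cut = a$r_cut,
                   radial_shifts = unlist(a$radial_shifts), eta_r = a$eta_r,
                   n_angular = a$n_angular,
                   angular_r_shifts = unlist(a$angular_r_shifts),
                   eta_a = a$eta_a, cutoff_fn = a$cutoff_fn)
  nf <- if (is.null(obj$n_feat)) obj$n_hidden else obj$n_feat
  model <- init_potential_model(spec, n_hidden = obj$n_hidden, seed = obj$seed,
                                ref_energies = unlist(obj$ref_energies),
                                linear_units = nf > obj$n_hidden)
  for (e in names(obj$nets)) {
    net <- obj$nets[[e]]
    model$nets[[e]]$W1 <- matrix(unlist(net$W1), nf, spec$length)
    model$nets[[e]]$b1 <- unlist(net$b1)
    model$nets[[e]]$w <- unlist(net$w)
    model$nets[[e]]$act <- unlist(net$act)
  }
  model$provenance <- obj$provenance
  model
}
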