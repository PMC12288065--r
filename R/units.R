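# Unit system and physical constants.
#
# Internal unit system everywhere in this package: kcal mol^-1 (energy),
# Angstrom (length), amu (mass), fs (time), K (temperature). All file formats
# and label tensors carry these units; conversion happens only at boundaries.

#' Physical constants (CODATA 2018)
#'
#' A named list of the constants the package relies on, in one place.
#' Values are CODATA 2018 recommended values; derived factors are computed,
#' not rounded.
#'
#' @format Named list with elements:
#' \describe{
#'   \item{hartree_kcal}{1 hartree in kcal mol^-1 (627.5094740631...)}
#'   \item{bohr_angstrom}{1 bohr in Angstrom (0.529177210903)}
#'   \item{ev_kcal}{1 eV in kcal mol^-1 (23.060547830619...)}
#'   \item{kB_kcal}{Boltzmann constant in kcal mol^-1 K^-1}
#'   \item{acc_factor}{converts kcal mol^-1 A^-1 amu^-1 to A fs^-2}
#'   \item{c_cm_s}{speed of light in cm s^-1}
#'   \item{freq_factor}{converts kcal mol^-1 A^-2 amu^-1 to s^-2}
#' }
#' @export
codata_constants <- local({
  # primary CODATA 2018 values
  E_h   <- 4.3597447222071e-18   # hartree, J
  a_0   <- 0.529177210903        # bohr, Angstrom
  e_C   <- 1.602176634e-19       # elementary charge, C (exact)
  N_A   <- 6.02214076e23         # Avogadro, mol^-1 (exact)
  k_B   <- 1.380649e-23          # Boltzmann, J K^-1 (exact)
  cal   <- 4.184                 # thermochemical calorie, J (exact)
  c_cm  <- 2.99792458e10         # speed of light, cm s^-1 (exact)
  kcal_J <- 1000 * cal
  list(
    hartree_kcal  = E_h * N_A / kcal_J,
    bohr_angstrom = a_0,
    ev_kcal       = e_C * N_A / kcal_J,
    kB_kcal       = k_B * N_A / kcal_J,
    # 1 kcal mol^-1 A^-1 / amu = kcal_J / (N_A * 1 g/mol / N_A ...) ->
    # kcal_J [J/mol] / (1e-3 kg/mol) / (1e-10 m) = m s^-2; to A fs^-2
    # multiply by 1e10 A/m * (1e-15 s/fs)^2
    acc_factor    = kcal_J / 1e-3 / 1e-10 * 1e10 * 1e-30,
    c_cm_s        = c_cm,
    # 1 kcal mol^-1 A^-2 / amu in s^-2
    freq_factor   = kcal_J / 1e-3 / 1e-20
  )
})

# Recognized unit atoms: value = factor to internal (kcal/mol for energies,
# Angstrom for lengths).
.energy_units <- function() c(
  hartree      = codata_constants$hartree_kcal,
  kcal_per_mol = 1,
  eV           = codata_constants$ev_kcal
)

.length_units <- function() c(
  bohr     = codata_constants$bohr_angstrom,
  angstrom = 1
)

# Parse a unit string into (energy power, length power, factor-to-internal).
# Grammar: ATOM ( "/" ATOM ("^" INT)? )? | ATOM "^" INT ... e.g.
# "hartree/bohr", "eV/angstrom^2", "kcal_per_mol", "bohr".
parse_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || is.na(unit)) {
    stop("unit must be a single character string", call. = FALSE)
  }
  eu <- .energy_units(); lu <- .length_units()
  parts <- strsplit(unit, "/", fixed = TRUE)[[1]]
  if (length(parts) < 1L || length(parts) > 2L || any(!nzchar(parts))) {
    stop(sprintf("cannot parse unit '%s'", unit), call. = FALSE)
  }
  e_pow <- 0L; l_pow <- 0L; factor <- 1
  consume <- function(atom, sign) {
    m <- regmatches(atom, regexec("^([A-Za-z_]+)(\\^([0-9]+))?$", atom))[[1]]
    if (length(m) == 0L) stop(sprintf("cannot parse unit '%s'", unit), call. = FALSE)
    name <- m[2]
    pow <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    if (name %in% names(eu)) {
      e_pow <<- e_pow + sign * pow
      factor <<- factor * eu[[name]]^(sign * pow)
    } else if (name %in% names(lu)) {
      l_pow <<- l_pow + sign * pow
      factor <<- factor * lu[[name]]^(sign * pow)
    } else {
      stop(sprintf("unknown unit atom '%s' in '%s'", name, unit), call. = FALSE)
    }
  }
  consume(parts[1], 1L)
  if (length(parts) == 2L) consume(parts[2], -1L)
  list(e_pow = e_pow, l_pow = l_pow, factor = factor)
}

#' Convert a physical quantity between units
#'
#' Exact CODATA-2018-based conversion between energy, length, force
#' (energy/length) and curvature (energy/length^2) units. No rounding is
#' performed inside the conversion.
#'
#' @param value numeric vector of values in `from_unit`.
#' @param from_unit,to_unit unit strings, e.g. `"hartree/bohr"`,
#'   `"kcal_per_mol/angstrom"`, `"eV/angstrom^2"`, `"bohr"`, `"angstrom"`.
#' @return numeric vector in `to_unit`.
#' @examples
#' convert_quantity(4.5e-4, "hartree/bohr", "kcal_per_mol/angstrom") # ~0.53
#' convert_quantity(1.8e-3, "bohr", "angstrom")                      # ~9.5e-4
#' @export
convert_quantity <- function(value, from_unit, to_unit) {
  from <- parse_unit(from_unit)
  to <- parse_unit(to_unit)
  if (from$e_pow != to$e_pow || from$l_pow != to$l_pow) {
    stop(sprintf(
      "incompatible dimensions: '%s' (E^%d L^%d) vs '%s' (E^%d L^%d)",
      from_unit, from$e_pow, from$l_pow, to_unit, to$e_pow, to$l_pow
    ), call. = FALSE)
  }
  value * (from$factor / to$factor)
}

#' Atomic masses
#'
#' Isotopically averaged atomic masses (amu) for the elements handled by the
#' synthetic surfaces, from the IUPAC 2021 standard atomic weights. `"X"` is
#' the reserved abstract particle (unit mass) used by the low-dimensional
#' model surfaces.
#'
#' @param species character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
atomic_masses <- function(species) {
  tab <- c(
    X = 1.0,
    H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998403163,
    S = 32.06, Cl = 35.45
  )
  unknown <- setdiff(unique(species), names(tab))
  if (length(unknown) > 0L) {
    stop(sprintf("no mass for element(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  unname(tab[species])
}
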