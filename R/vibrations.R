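# Vibrational analysis from unprojected mass-weighted Hessians.
#
# Frequencies come from diagonalizing M^(-1/2) H M^(-1/2) without removing
# translational or rotational modes, so every geometry yields all 3n values;
# negative eigenvalues map to negative ("imaginary") wavenumbers. No
# frequency scaling factors are applied.

#' Mass-weight a Hessian
#'
#' @param H 3n x 3n symmetric Hessian, kcal/mol/A^2.
#' @param masses per-atom masses, amu (length n).
#' @return 3n x 3n mass-weighted Hessian, kcal/mol/(A^2 amu).
#' @export
mass_weighted_hessian <- function(H, masses) {
  H <- as.matrix(H)
  n3 <- nrow(H)
  stopifnot(ncol(H) == n3, n3 == 3L * length(masses))
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  sqm <- sqrt(rep(masses, each = 3L))
  Hmw <- H / tcrossprod(sqm)
  (Hmw + t(Hmw)) / 2
}

#' Harmonic frequencies from a Hessian
#'
#' Eigenvalues lambda of the mass-weighted Hessian are mapped to wavenumbers
#' sign(lambda) * sqrt(|lambda|) / (2 pi c) after conversion of
#' kcal/mol/(A^2 amu) to s^-2. All 3n values are returned, sorted ascending;
#' imaginary modes appear as negative numbers.
#'
#' @param H 3n x 3n Hessian, kcal/mol/A^2.
#' @param masses per-atom masses, amu.
#' @return numeric vector of 3n wavenumbers, cm^-1.
#' @export
frequencies <- function(H, masses) {
  Hmw <- mass_weighted_hessian(H, masses)
  lam <- eigen(Hmw, symmetric = TRUE, only.values = TRUE)$values
  omega2 <- lam * codata_constants$freq_factor           # s^-2
  nu <- sign(omega2) * sqrt(abs(omega2)) / (2 * pi * codata_constants$c_cm_s)
  sort(nu)
}

#' Vibrational spectrum along a reaction path
#'
#' Computes all-3n frequency lists for every image of an IRC or MEP, from
#' either the reference surface or a trained model.
#'
#' @param model `potential_model` or `reference_ff` (Hessian source).
#' @param images list of [labeled_structure()], or an `irc_path` / `mep`
#'   object (arc coordinates are then carried over).
#' @param arc optional per-image arc coordinates (overrides).
#' @return object of class `vibrational_spectrum`: `frequencies` (images x
#'   3n matrix, each row sorted ascending), `arc`, `source`.
#' @export
spectrum_along_path <- function(model, images, arc = NULL) {
  if (inherits(images, "irc_path") || inherits(images, "mep")) {
    if (is.null(arc)) arc <- images$arc
    images <- images$images
  }
  stopifnot(length(images) >= 1L)
  src <- if (inherits(model, "reference_ff")) "reference" else "model"
  freq <- t(vapply(images, function(s) {
    H <- if (src == "reference") eval_reference(model, s)$hessian
         else .model_eval(model, s, deriv = 2L)$hessian
    frequencies(H, s$masses)
  }, numeric(3L * length(images[[1]]$species))))
  if (is.null(arc)) arc <- seq_along(images) - 1
  structure(list(frequencies = freq, arc = arc, source = src),
            class = "vibrational_spectrum")
}

#' @export
print.vibrational_spectrum <- function(x, ...) {
  cat(sprintf("<vibrational_spectrum: %d geometries x %d modes (%s), %d imaginary>\n",
              nrow(x$frequencies), ncol(x$frequencies), x$source,
              sum(x$frequencies < -1)))
  invisible(x)
}
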