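#' Analytic isotropic harmonic reference system
#'
#' A single particle in a `dims`-dimensional well `U(x) = k/2 * |x|^2`
#' (kcal/mol with x in Angstrom). Closed forms used as oracles:
#' mean energy `dims * kT / 2` (equipartition), log density of states
#' `ln n(E) = (dims/2 - 1) ln E + const`, and PMF `k/2 * x^2` along any
#' coordinate.
#'
#' @param k force constant, kcal/mol/A^2.
#' @param dims dimensionality, 1, 2 or 3.
#' @return object of class `harmonic_reference`.
#' @export
make_harmonic_reference <- function(k, dims = 1) {
  stopifnot(k > 0, dims %in% 1:3)
  structure(list(k = k, dims = as.integer(dims)), class = "harmonic_reference")
}

#' @export
print.harmonic_reference <- function(x, ...) {
  cat(sprintf("Harmonic reference: U = %.3g/2 * |x|^2 kcal/mol, %dD\n", x$k, x$dims))
  invisible(x)
}

#' Analytic mean potential energy of the harmonic reference
#' @param ref a `harmonic_reference`.
#' @param T temperature, K.
#' @return `dims * kT / 2` in kcal/mol.
#' @export
harmonic_mean_energy <- function(ref, T) ref$dims * .kT(T) / 2

#' Analytic log density of states of the harmonic reference
#'
#' `ln n(E) = (dims/2 - 1) * ln(E)` up to an additive constant
#' (flat in E for 2D).
#'
#' @param ref a `harmonic_reference`.
#' @param E energies, kcal/mol (> 0).
#' @export
harmonic_ln_dos <- function(ref, E) (ref$dims / 2 - 1) * log(E)

#' Analytic PMF of the harmonic reference along one coordinate
#' @param ref a `harmonic_reference`.
#' @param x coordinate values, Angstrom.
#' @export
harmonic_pmf <- function(ref, x) ref$k / 2 * x^2
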