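#' Physical constants and unit conventions
#'
#' All energies are in kcal/mol, distances in Angstrom, temperatures in
#' Kelvin, charges in units of the elementary charge e, and angles in
#' radians unless stated otherwise.
#'
#' @format `kB` is the Boltzmann constant in kcal/mol/K
#'   (0.0019872041). `COULOMB_CONST` is the electrostatic conversion factor
#'   332.0637 kcal A / (mol e^2), so that two unit charges 1 A apart have a
#'   Coulomb energy of 332.0637 kcal/mol. `STANDARD_VOLUME` is the volume
#'   per molecule at the 1 M standard state, 1660.539 A^3.
#' @name constants
NULL

#' @rdname constants
#' @export
kB <- 0.0019872041

#' @rdname constants
#' @export
COULOMB_CONST <- 332.0637

#' @rdname constants
#' @export
STANDARD_VOLUME <- 1660.5391
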