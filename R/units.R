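#' Unit conventions
#'
#' The simulation uses reduced units: energy in kcal/mol, temperature in
#' kcal/mol/k_B, length in Angstrom and a simulation time unit (tu).
#' One temperature unit corresponds to 1 kcal/mol divided by the Boltzmann
#' constant, about 503 K ("about 500 K"); one tu corresponds to about 50 fs,
#' so 500 tu are about 25 ps and 1e6 tu about 50 ns.
#'
#' @name polyqdmd-units
NULL

#' Boltzmann constant in kcal/mol/K
#' @keywords internal
.kB_kcal_mol_K <- 0.0019872041

#' Kelvin per reduced temperature unit (exact 1 kcal/mol / k_B)
#' @export
kelvin_per_unit <- function() 1 / .kB_kcal_mol_K

#' Convert reduced temperature to Kelvin
#'
#' @param t_reduced temperature in kcal/mol/k_B units
#' @param rounded use the rounded 500 K/unit convention instead
#'   of the exact 1 kcal/mol / k_B = 503.2 K/unit
#' @return temperature in Kelvin
#' @export
temperature_to_kelvin <- function(t_reduced, rounded = FALSE) {
  t_reduced * (if (rounded) 500 else kelvin_per_unit())
}

#' Femtoseconds per simulation time unit (500 tu ~ 25 ps)
#' @export
fs_per_tu <- function() 50

#' Convert simulation time units to nanoseconds
#' @param tu time in simulation time units
#' @export
tu_to_ns <- function(tu) tu * fs_per_tu() * 1e-6
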