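#' Physical constants used throughout the package
#'
#' Energies are handled internally in molar units (J/mol) with the gas
#' constant `R`, which is the convention in which experimental gating
#' enthalpies and entropies for TRP channels are reported.  The equivalent
#' per-molecule convention (J per molecule with the Boltzmann constant
#' `kB`) differs by a factor of Avogadro's number; both constants are
#' exposed here so users can convert either way.
#'
#' @return A data frame with columns `symbol`, `value`, `unit` and
#'   `description` listing the gas constant, Boltzmann constant and
#'   Avogadro's number.
#' @examples
#' gating_constants()
#' @export
gating_constants <- function() {
  data.frame(
    symbol = c("R", "kB", "NA"),
    value = c(.R_GAS, .K_BOLTZ, .N_AVOGADRO),
    unit = c("J/(mol K)", "J/K", "1/mol"),
    description = c(
      "molar gas constant (R = kB * NA)",
      "Boltzmann constant (per-molecule energies)",
      "Avogadro constant (converts J/molecule to J/mol)"
    ),
    stringsAsFactors = FALSE
  )
}

# CODATA 2018 exact values
.R_GAS <- 8.314462618     # J / (mol K)
.K_BOLTZ <- 1.380649e-23  # J / K
.N_AVOGADRO <- 6.02214076e23

#' Convert temperatures between Celsius and kelvin
#'
#' All internal computations use kelvin; Celsius is accepted only at I/O
#' boundaries (e.g. when reading experimental tables with a
#' `temperature_C` column).
#'
#' @param x numeric vector of temperatures.
#' @return Converted temperatures.
#' @examples
#' celsius_to_kelvin(25)
#' kelvin_to_celsius(310.15)
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15
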