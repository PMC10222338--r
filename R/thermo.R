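#' Thermodynamic state
#'
#' Bundles the temperature with the Boltzmann constant and the inverse
#' temperature \eqn{\beta = 1/(k_B T)} in the package's energy units
#' (kcal/mol), so that every estimator and sampler agrees on the meaning of
#' one unit of work.
#'
#' @param temperature Absolute temperature in Kelvin (must be > 0).
#' @return An object of class `thermo_state` with fields `temperature`
#'   (Kelvin), `kB` (kcal/(mol K)) and `beta` (mol/kcal).
#' @examples
#' th <- thermo_state(300)
#' th$beta * th$kB * th$temperature  # == 1
#' @export
thermo_state <- function(temperature = 300) {
  check_number(temperature, "temperature", positive = TRUE)
  structure(
    list(temperature = temperature, kB = .kB,
         beta = 1 / (.kB * temperature)),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %g K, kB*T = %.6g kcal/mol, beta = %.6g mol/kcal\n",
              x$temperature, 1 / x$beta, x$beta))
  invisible(x)
}

# thermo state fixed by the thermal energy instead of the temperature
# (convenient for closed-form checks where kB*T is a round number)
#' Thermodynamic state from thermal energy
#'
#' Convenience constructor fixing \eqn{k_B T} directly (kcal/mol) rather than
#' the temperature.
#'
#' @param kT Thermal energy in kcal/mol.
#' @return A [thermo_state()].
#' @export
thermo_state_kT <- function(kT) {
  check_number(kT, "kT", positive = TRUE)
  thermo_state(kT / .kB)
}
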