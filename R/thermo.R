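#' Thermodynamic state
#'
#' Bundles the temperature with the inverse temperature
#' \eqn{\beta = 1/(k_B T)} used throughout the free-energy bookkeeping.
#' The default 300 K is the package-wide reference temperature; it is
#' configurable everywhere a `thermo` argument appears.
#'
#' @param temperature temperature in kelvin (> 0)
#' @return object of class `thermo_state` with fields `temperature`, `beta`
#'   (1/(kcal/mol)) and `kB` (kcal/(mol K))
#' @examples
#' th <- thermo_state(300)
#' th$beta * th$kB * th$temperature  # == 1
#' @export
thermo_state <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  structure(list(temperature = temperature,
                 beta = 1 / (KB_KCAL * temperature),
                 kB = KB_KCAL),
            class = "thermo_state")
}

as_thermo <- function(x) {
  if (inherits(x, "thermo_state")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(thermo_state(x))
  stop("expected a thermo_state or a temperature in kelvin")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("thermo_state: T = %g K, beta = %.6f mol/kcal, kT = %.6f kcal/mol\n",
              x$temperature, x$beta, 1 / x$beta))
  invisible(x)
}
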