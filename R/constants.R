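#' Physical constants and unit conventions
#'
#' All internal energies are in kcal/mol.  Temperatures are in Kelvin,
#' distances in Angstrom, angles in degrees at the user surface and radians
#' internally.  Gradient strengths enter in gauss/cm and are converted to
#' T/m (x 1e-2) before any Stejskal-Tanner arithmetic.
#'
#' @format `KB_KCAL` is the Boltzmann constant in kcal/(mol K);
#'   `DEFAULT_TEMPERATURE` is the production temperature (298 K);
#'   `STANDARD_VOLUME_A3` is the standard-state volume per molecule at
#'   1 mol/L, in cubic Angstrom; `GAMMA_1H` is the 1H gyromagnetic ratio in
#'   rad s^-1 T^-1.
#' @name cdbind-constants
NULL

#' @rdname cdbind-constants
#' @export
KB_KCAL <- 1.987204e-3

#' @rdname cdbind-constants
#' @export
DEFAULT_TEMPERATURE <- 298

#' @rdname cdbind-constants
#' @export
STANDARD_VOLUME_A3 <- 1660.539

#' @rdname cdbind-constants
#' @export
GAMMA_1H <- 2.6752218744e8

# thermal energy in kcal/mol
kT <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive, finite number of Kelvin")
  KB_KCAL * temperature
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angles (degrees) to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
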