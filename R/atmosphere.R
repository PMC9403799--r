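# International Standard Atmosphere, troposphere layer only (0-11 km).
# Shared by the simulator (altitude -> pressure) and the flight-state module
# (pressure -> altitude) so the two directions are exact mutual inverses.
.isa <- list(
  T0 = 288.15,    # K, sea-level standard temperature
  L  = 0.0065,    # K/m, temperature lapse rate
  g  = 9.80665,   # m/s^2
  M  = 0.0289644, # kg/mol, molar mass of dry air
  R  = 8.31446    # J/(mol K)
)
.isa$expo <- .isa$g * .isa$M / (.isa$R * .isa$L) # ~5.2558

#' Barometric pressure at altitude
#'
#' Standard-atmosphere (troposphere) pressure at a given altitude above the
#' reference level. Exact inverse of [barometric_altitude()].
#'
#' @param altitude Altitude in metres above the reference level.
#' @param reference Pressure (Pa) at zero altitude. Defaults to the standard
#'   sea-level pressure 101325 Pa; pass a daily sea-level pressure to adjust.
#' @return Pressure in Pa.
#' @seealso [barometric_altitude()]
#' @export
pressure_from_altitude <- function(altitude, reference = 101325) {
  stopifnot(is.numeric(altitude), is.numeric(reference), reference > 0)
  reference * (1 - .isa$L * altitude / .isa$T0)^.isa$expo
}

#' Altitude from barometric pressure
#'
#' Inverts the standard-atmosphere pressure formula: altitude is 0 at the
#' reference pressure and strictly decreasing in pressure.
#'
#' @param pressure Pressure in Pa (must be positive).
#' @param reference Reference (sea-level) pressure in Pa.
#' @return Altitude in metres.
#' @examples
#' barometric_altitude(101325)        # 0
#' barometric_altitude(95000)         # ~540 m
#' @export
barometric_altitude <- function(pressure, reference = 101325) {
  stopifnot(is.numeric(pressure), is.numeric(reference), reference > 0)
  if (any(pressure <= 0)) stop("pressure must be positive")
  (.isa$T0 / .isa$L) * (1 - (pressure / reference)^(1 / .isa$expo))
}
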