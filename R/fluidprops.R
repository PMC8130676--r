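# Temperature- and pressure-dependent properties of the suspension medium,
# and the hydrodynamics of the rectangular flow chamber.

# Fourth-order polynomial constants for air-saturated water.
# Rows: density [kg m^-3], isothermal compressibility [1/kPa].
.water_poly <- list(
  density = c(A = 999.84847, B = 6.337563e-2, C = -8.523829e-3,
              D = 6.943248e-5, E = -3.821216e-7),
  compressibility = c(A = 50.83101e-8, B = -3.68293e-9, C = 7.263725e-11,
                      D = -6.597702e-13, E = 2.87767e-15)
)

# Modified Andrade constants for water viscosity; the exponential yields mPa s.
.andrade <- c(A_G = -3.63148, B_G = 542.05, C_G = 129.0)

.P_REF_KPA <- 101.325

# The polynomials are stated for T in [5, 40] degC. 0 degC is admitted (the
# constant term A is the 0 degC value) but flagged with a warning.
.check_temperature <- function(T_C, what = "temperature") {
  if (any(!is.finite(T_C))) {
    stop("non-finite ", what, " supplied", call. = FALSE)
  }
  if (any(T_C < 0 | T_C > 40)) {
    stop(what, " out of the supported range [0, 40] degC (valid domain 5-40 degC)",
         call. = FALSE)
  }
  if (any(T_C < 5)) {
    warning(what, " below the stated 5-40 degC validity domain; ",
            "extrapolating the 0-5 degC corner", call. = FALSE)
  }
  invisible(T_C)
}

.eval_poly4 <- function(T_C, k) {
  k[["A"]] + k[["B"]] * T_C + k[["C"]] * T_C^2 + k[["D"]] * T_C^3 +
    k[["E"]] * T_C^4
}

#' Density of air-saturated water
#'
#' Fourth-order polynomial parameterization of the density of air-saturated
#' water as a function of temperature, valid on 5--40 degC (0--5 degC is
#' admitted with a warning).
#'
#' @param T_C Temperature in degrees Celsius.
#' @return Density in kg m^-3.
#' @examples
#' water_density_air_saturated(20)
#' @export
water_density_air_saturated <- function(T_C) {
  .check_temperature(T_C)
  .eval_poly4(T_C, .water_poly$density)
}

#' Isothermal compressibility of water
#'
#' @inheritParams water_density_air_saturated
#' @return Isothermal compressibility in kPa^-1.
#' @export
water_compressibility <- function(T_C) {
  .check_temperature(T_C)
  .eval_poly4(T_C, .water_poly$compressibility)
}

#' Compressibility-corrected water density
#'
#' Corrects the air-saturated density for ambient pressure:
#' rho_m = rho_AS(T) * (1 + kappa(T) * (P - 101.325 kPa)). At the reference
#' pressure 101.325 kPa the correction vanishes exactly.
#'
#' @inheritParams water_density_air_saturated
#' @param P_kPa Ambient pressure in kPa (> 0).
#' @return Density in kg m^-3.
#' @export
corrected_density <- function(T_C, P_kPa = .P_REF_KPA) {
  .check_temperature(T_C)
  if (any(!is.finite(P_kPa)) || any(P_kPa <= 0)) {
    stop("ambient pressure must be a positive, finite value in kPa", call. = FALSE)
  }
  water_density_air_saturated(T_C) *
    (1 + water_compressibility(T_C) * (P_kPa - .P_REF_KPA))
}

#' Water viscosity from the modified Andrade equation
#'
#' eta(T) = exp(A_G + B_G / (C_G + T)) in mPa s, returned in Pa s, with
#' A_G = -3.63148, B_G = 542.05 degC, C_G = 129.0 degC. Reproduces about
#' 1.0 mPa s at 20 degC.
#'
#' @inheritParams water_density_air_saturated
#' @param viscosity_factor Multiplicative factor for media other than pure
#'   water (serum-containing culture medium is about 5% more viscous).
#' @return Dynamic viscosity in Pa s.
#' @export
water_viscosity <- function(T_C, viscosity_factor = 1) {
  .check_temperature(T_C)
  stopifnot(viscosity_factor > 0)
  eta_mPas <- exp(.andrade[["A_G"]] + .andrade[["B_G"]] / (.andrade[["C_G"]] + T_C))
  eta_mPas * 1e-3 * viscosity_factor
}

#' Speed of sound in water (Newton--Laplace)
#'
#' c = 1 / sqrt(kappa * rho_m) with the isothermal compressibility converted
#' to Pa^-1 and the compressibility-corrected density.
#'
#' @inheritParams corrected_density
#' @return Speed of sound in m s^-1.
#' @export
speed_of_sound <- function(T_C, P_kPa = .P_REF_KPA) {
  kappa_Pa <- water_compressibility(T_C) * 1e-3  # kPa^-1 -> Pa^-1
  1 / sqrt(kappa_Pa * corrected_density(T_C, P_kPa))
}

#' Medium state at a given temperature and pressure
#'
#' Bundles the temperature- and pressure-dependent medium properties used
#' throughout calibration and simulation. All members are SI.
#'
#' @inheritParams corrected_density
#' @inheritParams water_viscosity
#' @param medium Free-text label of the medium.
#' @return An object of class \code{fluid_state}: a list with elements
#'   \code{temperature_C}, \code{pressure_kPa}, \code{density_air_saturated}
#'   (kg m^-3), \code{compressibility_kPa} (kPa^-1), \code{density} (kg m^-3),
#'   \code{viscosity} (Pa s), \code{speed_of_sound} (m s^-1), \code{medium}.
#' @examples
#' fluid_state(36)
#' @export
fluid_state <- function(T_C, P_kPa = .P_REF_KPA, viscosity_factor = 1,
                        medium = "water") {
  out <- list(
    temperature_C = T_C,
    pressure_kPa = P_kPa,
    density_air_saturated = water_density_air_saturated(T_C),
    compressibility_kPa = water_compressibility(T_C),
    density = corrected_density(T_C, P_kPa),
    viscosity = water_viscosity(T_C, viscosity_factor),
    viscosity_factor = viscosity_factor,
    speed_of_sound = speed_of_sound(T_C, P_kPa),
    medium = medium
  )
  structure(out, class = "fluid_state")
}

#' @export
print.fluid_state <- function(x, ...) {
  cat(sprintf(
    "<fluid_state> %s at %.2f degC, %.3f kPa\n  density %.3f kg/m^3 | viscosity %.4g Pa s | c %.1f m/s\n",
    x$medium, x$temperature_C, x$pressure_kPa, x$density, x$viscosity,
    x$speed_of_sound))
  invisible(x)
}

#' Rectangular flow-chamber geometry
#'
#' @param height_um Chamber height in micrometres (default 100).
#' @param width_mm Chamber width in millimetres (default 2).
#' @param flow_ul_per_min Volumetric flow rate in microlitres per minute.
#' @return An object of class \code{channel_geometry} with SI fields
#'   \code{height}, \code{width} (m) and \code{flow_rate} (m^3 s^-1).
#' @export
channel_geometry <- function(height_um = 100, width_mm = 2,
                             flow_ul_per_min = 0) {
  if (height_um <= 0 || width_mm <= 0) {
    stop("chamber height and width must be positive", call. = FALSE)
  }
  if (flow_ul_per_min < 0) stop("flow rate must be non-negative", call. = FALSE)
  structure(list(
    height = height_um * 1e-6,
    width = width_mm * 1e-3,
    flow_rate = flow_ul_per_min * 1e-9 / 60
  ), class = "channel_geometry")
}

#' Wall shear stress at the centre of a rectangular channel
#'
#' tau_w = 6 mu Q / (h^2 w) for fully developed laminar flow in a wide
#' rectangular channel.
#'
#' @param fluid A \code{\link{fluid_state}} (its viscosity is used).
#' @param channel A \code{\link{channel_geometry}}.
#' @return Wall shear stress in Pa.
#' @examples
#' wall_shear_stress(fluid_state(36), channel_geometry(flow_ul_per_min = 1.66))
#' @export
wall_shear_stress <- function(fluid, channel) {
  stopifnot(inherits(fluid, "fluid_state"), inherits(channel, "channel_geometry"))
  6 * fluid$viscosity * channel$flow_rate / (channel$height^2 * channel$width)
}
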