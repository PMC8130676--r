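# Acoustic force profile, effective gravity, and the overdamped equation of
# motion for a bead near the chamber bottom. The integrator serves both the
# calibration fitter and the synthetic-data generator.

.G_ACC <- 9.81  # m s^-2

#' Bead specification
#'
#' @param radius_um Bead radius in micrometres (default 5, i.e. 10 um beads).
#' @param density Bead material density in kg m^-3 (default 1050,
#'   polystyrene).
#' @param compressibility_Pa Optional bead compressibility in Pa^-1 (metadata
#'   only; not used by the Stokes force calibration).
#' @param coating Free-text coating label.
#' @return An object of class \code{bead_spec} with SI field \code{radius}.
#' @export
bead_spec <- function(radius_um = 5, density = 1050,
                      compressibility_Pa = NA_real_, coating = "collagen") {
  stopifnot(radius_um > 0, density > 0)
  structure(list(radius = radius_um * 1e-6, density = density,
                 compressibility_Pa = compressibility_Pa, coating = coating),
            class = "bead_spec")
}

#' Acoustic force-profile parameters
#'
#' The force profile along z is F_ac(z) = f0 * k_p * sin(2 * (k_p z + phi_p)).
#' The triple (f0, k_p, phi_p) is the unit of calibration; f0 absorbs the
#' acoustic radiation prefactor so no material compressibilities are needed.
#'
#' @param f0_pN_um Force-profile prefactor in pN um.
#' @param k_p_per_um Acoustic wave number in um^-1 (> 0).
#' @param phi_p_rad Phase of the standing wave in rad, in [0, pi).
#' @param amplitude_pct Drive amplitude (%) this profile was calibrated at.
#' @param p0_Pa Optional pressure amplitude metadata.
#' @param correction_method Wall-drag method used during calibration.
#' @return An object of class \code{acoustic_force_params}; fields are stored
#'   in SI (\code{f0} in N m, \code{k_p} in m^-1).
#' @examples
#' acoustic_force_params(488.189, 0.046, 0.799)
#' @export
acoustic_force_params <- function(f0_pN_um, k_p_per_um, phi_p_rad,
                                  amplitude_pct = NA_real_, p0_Pa = NA_real_,
                                  correction_method = "brenner") {
  stopifnot(f0_pN_um >= 0, k_p_per_um > 0,
            phi_p_rad >= 0, phi_p_rad < pi)
  structure(list(
    f0 = f0_pN_um * 1e-18,       # pN um -> N m
    k_p = k_p_per_um * 1e6,      # um^-1 -> m^-1
    phi_p = phi_p_rad,
    amplitude_pct = amplitude_pct,
    p0_Pa = p0_Pa,
    correction_method = correction_method
  ), class = "acoustic_force_params")
}

#' @export
print.acoustic_force_params <- function(x, ...) {
  cat(sprintf(
    "<acoustic_force_params> f0 = %.3f pN um, k_p = %.4f /um, phi_p = %.4f rad (%s)\n",
    x$f0 * 1e18, x$k_p * 1e-6, x$phi_p, x$correction_method))
  invisible(x)
}

#' Acoustic force at height z
#'
#' F_ac(z) = f0 k_p sin(2 (k_p z + phi_p)); positive values pull the bead up,
#' away from the bottom surface.
#'
#' @param z Height above the chamber bottom in m (>= 0); vectorized.
#' @param params An \code{\link{acoustic_force_params}}.
#' @return Force in N.
#' @export
acoustic_force <- function(z, params) {
  stopifnot(inherits(params, "acoustic_force_params"))
  if (any(z < 0)) stop("z must be non-negative", call. = FALSE)
  params$f0 * params$k_p * sin(2 * (params$k_p * z + params$phi_p))
}

#' Height of the first acoustic node
#'
#' Smallest z > 0 where the force crosses zero from pull-up to push-down,
#' i.e. z = (pi/2 - phi_p) / k_p for phi_p < pi/2 (the node sits at z = 0
#' when phi_p = pi/2, and shifts by half a period for larger phases).
#'
#' @param params An \code{\link{acoustic_force_params}}.
#' @return Node height in m.
#' @export
node_position <- function(params) {
  stopifnot(inherits(params, "acoustic_force_params"))
  if (params$k_p <= 0) stop("k_p must be positive", call. = FALSE)
  z <- (pi / 2 - params$phi_p) / params$k_p
  if (z < 0) z <- z + pi / params$k_p  # phases past pi/2: next sign change
  z
}

#' Buoyancy-corrected bead weight
#'
#' (rho_p - rho_m) * (4/3) pi R^3 * g; positive values point downward
#' (a bead denser than the medium sinks).
#'
#' @param bead A \code{\link{bead_spec}}.
#' @param fluid A \code{\link{fluid_state}}.
#' @return Effective gravitational force in N (positive down).
#' @export
effective_gravity <- function(bead, fluid) {
  stopifnot(inherits(bead, "bead_spec"), inherits(fluid, "fluid_state"))
  (bead$density - fluid$density) * (4 / 3) * pi * bead$radius^3 * .G_ACC
}

#' Integrate the overdamped equation of motion
#'
#' Solves dz/dt = (F_ac(z) - F_grav) / (6 pi R eta_eff(z)) on the supplied
#' time grid, with the wall-corrected drag eta_eff(z) = lambda(z) eta. No
#' inertia: bead Reynolds and Stokes numbers are both vanishingly small.
#' Integration stops if the bead reaches the surface cutoff z_min; remaining
#' samples are held at z_min and flagged as landed.
#'
#' @param params An \code{\link{acoustic_force_params}}, or \code{NULL} for
#'   zero acoustic force (gravity-only fall).
#' @param bead A \code{\link{bead_spec}}.
#' @param fluid A \code{\link{fluid_state}}.
#' @param drag A \code{\link{wall_drag_spec}}.
#' @param z0 Initial height in m (>= drag z_min).
#' @param t Strictly increasing time grid in s.
#' @param method deSolve integration method: \code{"lsoda"} (adaptive,
#'   default) or \code{"rk4"} (fixed-step fallback).
#' @return A tibble with columns \code{t_s}, \code{z_um} and logical
#'   \code{landed}.
#' @export
integrate_motion <- function(params, bead, fluid, drag, z0, t,
                             method = c("lsoda", "rk4")) {
  method <- match.arg(method)
  stopifnot(inherits(bead, "bead_spec"), inherits(fluid, "fluid_state"),
            inherits(drag, "wall_drag_spec"))
  if (!is.null(params)) stopifnot(inherits(params, "acoustic_force_params"))
  if (is.unsorted(t, strictly = TRUE)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  if (z0 < drag$z_min) stop("z0 must be at least the surface cutoff z_min",
                            call. = FALSE)
  R <- bead$radius
  eta <- fluid$viscosity
  f_grav <- effective_gravity(bead, fluid)
  rhs <- function(tt, y, parms) {
    z <- max(y[1], drag$z_min)
    f_ac <- if (is.null(params)) 0 else acoustic_force(z, params)
    v <- (f_ac - f_grav) / (6 * pi * R * effective_viscosity(eta, drag, z, R))
    list(v)
  }
  # Root: stop when the bead reaches the surface cutoff while moving down.
  rootfun <- function(tt, y, parms) y[1] - drag$z_min
  t_solve <- t
  sol <- if (method == "lsoda") {
    deSolve::lsoda(c(z = z0), t_solve, rhs, parms = NULL,
                   rtol = 1e-9, atol = 1e-12,
                   events = list(root = TRUE, terminalroot = 1),
                   rootfunc = rootfun)
  } else {
    deSolve::rk4(c(z = z0), t_solve, rhs, parms = NULL)
  }
  z <- rep(NA_real_, length(t_solve))
  z[seq_len(nrow(sol))] <- sol[, "z"]
  landed <- is.na(z) | z <= drag$z_min * (1 + 1e-9)
  z[is.na(z)] <- drag$z_min
  z <- pmax(z, drag$z_min)
  keep <- match(t, t_solve)
  tibble::tibble(t_s = t, z_um = z[keep] * 1e6, landed = landed[keep])
}

#' Simulate a gravity-only fall
#'
#' \code{\link{integrate_motion}} with zero acoustic force: after the drive
#' is switched off only the buoyant weight acts and the bead settles back to
#' the surface. Used to validate calibrations.
#'
#' @inheritParams integrate_motion
#' @return A tibble as in \code{\link{integrate_motion}}.
#' @export
simulate_fall <- function(z0, bead, fluid, drag, t, method = c("lsoda", "rk4")) {
  integrate_motion(NULL, bead, fluid, drag, z0, t, method = match.arg(method))
}
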