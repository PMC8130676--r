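# Near-wall corrections to Stokes drag for a sphere: Brenner's exact series
# for motion perpendicular to a plane wall, and Faxen's polynomial for motion
# parallel to it. Both return the factor lambda multiplying the fluid
# viscosity, eta_eff = lambda * eta_fluid.

#' Brenner wall-drag correction (perpendicular motion)
#'
#' Exact bipolar-coordinate series solution for the drag on a sphere of
#' radius \code{R} translating perpendicular to a plane wall, with the sphere
#' centre at distance \code{L} from the wall (cosh a = L/R). The series is
#' truncated at \code{n_terms} terms (default 100). lambda >= 1 always, with
#' lambda -> 1 far from the wall and lambda ~ R/(L - R) in the lubrication
#' limit.
#'
#' @param L Centre-to-wall distance in m (or any unit shared with \code{R});
#'   must exceed \code{R}.
#' @param R Sphere radius, same unit as \code{L}.
#' @param n_terms Number of series terms (>= 1).
#' @return Dimensionless drag correction factor lambda.
#' @examples
#' brenner_lambda(2, 1)   # one radius above the surface
#' @export
brenner_lambda <- function(L, R, n_terms = 100) {
  if (any(!is.finite(L)) || any(!is.finite(R))) {
    stop("non-finite L or R", call. = FALSE)
  }
  if (any(R <= 0)) stop("bead radius must be positive", call. = FALSE)
  if (any(L <= R)) stop("bead intersects surface: L must exceed R", call. = FALSE)
  if (n_terms < 1) stop("n_terms must be >= 1", call. = FALSE)
  n <- seq_len(n_terms)
  cn <- n * (n + 1) / ((2 * n - 1) * (2 * n + 3))
  vapply(L / R, function(ratio) {
    a <- acosh(ratio)
    # All exponentials are scaled by exp(-(2n+1)a) so large a cannot overflow.
    e_m <- exp(-(2 * n - 1) * a)
    e_0 <- exp(-(2 * n + 1) * a)
    e_p <- exp(-(2 * n + 3) * a)
    num <- 1 - e_0^2 + (2 * n + 1) * (e_m - e_p) / 2
    den <- 1 - 2 * e_0 + e_0^2 - (2 * n + 1)^2 * (e_m - 2 * e_0 + e_p) / 4
    (4 / 3) * sinh(a) * sum(cn * (num / den - 1))
  }, numeric(1))
}

#' Faxen wall-drag correction (parallel motion)
#'
#' Fifth-order reciprocal polynomial in s = R/L for a sphere translating
#' parallel to a plane wall; the canonical optical-tweezers wall correction.
#'
#' @inheritParams brenner_lambda
#' @return Dimensionless drag correction factor lambda (>= 1).
#' @export
faxen_lambda <- function(L, R) {
  if (any(!is.finite(L)) || any(!is.finite(R))) {
    stop("non-finite L or R", call. = FALSE)
  }
  if (any(R <= 0)) stop("bead radius must be positive", call. = FALSE)
  if (any(L <= R)) stop("bead intersects surface: L must exceed R", call. = FALSE)
  s <- R / L
  1 / (1 - (9 / 16) * s + (1 / 8) * s^3 - (45 / 256) * s^4 - (1 / 16) * s^5)
}

#' Wall-drag specification
#'
#' Selects which viscosity correction is applied when a bead moves near the
#' chamber bottom, and the minimum height below which the bead is treated as
#' landed.
#'
#' @param method One of \code{"brenner"} (perpendicular, the calibration
#'   default), \code{"faxen"} (parallel) or \code{"none"}.
#' @param n_terms Series truncation for the Brenner sum.
#' @param z_min Minimum surface-to-bead-bottom distance in m (default 10 nm);
#'   guards the lubrication divergence of the Brenner factor.
#' @return An object of class \code{wall_drag_spec}.
#' @export
wall_drag_spec <- function(method = c("brenner", "faxen", "none"),
                           n_terms = 100, z_min = 1e-8) {
  method <- match.arg(method)
  stopifnot(n_terms >= 1, z_min > 0)
  structure(list(method = method, n_terms = n_terms, z_min = z_min),
            class = "wall_drag_spec")
}

#' Drag correction factor at height z
#'
#' @param spec A \code{\link{wall_drag_spec}}.
#' @param z Surface-to-bead-bottom distance in m (so L = z + R).
#' @param R Bead radius in m.
#' @return lambda, dimensionless.
#' @export
drag_lambda <- function(spec, z, R) {
  stopifnot(inherits(spec, "wall_drag_spec"))
  z <- pmax(z, spec$z_min)
  switch(spec$method,
    brenner = brenner_lambda(z + R, R, spec$n_terms),
    faxen = faxen_lambda(z + R, R),
    none = rep(1, length(z))
  )
}

#' Effective viscosity near the wall
#'
#' eta_eff = lambda(method, z + R, R) * eta_fluid.
#'
#' @param eta_fluid Fluid viscosity in Pa s.
#' @param spec A \code{\link{wall_drag_spec}}.
#' @param z Surface-to-bead-bottom distance in m.
#' @param R Bead radius in m.
#' @return Effective viscosity in Pa s.
#' @export
effective_viscosity <- function(eta_fluid, spec, z, R) {
  stopifnot(eta_fluid > 0)
  drag_lambda(spec, z, R) * eta_fluid
}
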