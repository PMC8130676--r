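# Stokes force calibration (SFC): fit the acoustic force-profile triple
# (f0, k_p, phi_p) to pull traces, validate against gravity-fall traces,
# convert drive amplitude to force, and build/query the spatial calibration
# map across the field of view.

.r_squared <- function(observed, predicted) {
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(ifelse(ss_res == 0, 1, -Inf))
  1 - ss_res / ss_tot
}

.predict_pull_z <- function(f0_pNum, kp_um, phi, bead, fluid, drag, z0, t) {
  p <- acoustic_force_params(f0_pNum, kp_um, phi)
  integrate_motion(p, bead, fluid, drag, z0, t)$z_um
}

#' Quality-control thresholds for calibration traces
#'
#' The instrument intent is to drop beads stuck to the glass, clustered
#' beads, and beads that detached before the pull. Thresholds are
#' configurable; defaults: minimum total displacement 0.5 um, minimum pull
#' fit R^2 0.95, maximum start height 1 um.
#'
#' @param min_displacement_um Minimum pull displacement in um.
#' @param min_r2_on Minimum coefficient of determination of the pull fit.
#' @param max_start_um Maximum allowed start height in um.
#' @return A list of thresholds.
#' @export
calibration_qc <- function(min_displacement_um = 0.5, min_r2_on = 0.95,
                           max_start_um = 1) {
  list(min_displacement_um = min_displacement_um, min_r2_on = min_r2_on,
       max_start_um = max_start_um)
}

#' Fit the acoustic force profile to a pull trace
#'
#' Least-squares estimation of (f0, k_p, phi_p): the overdamped equation of
#' motion is integrated for trial parameters and the predicted z(t) is
#' matched to the measured trace. The optimizer is Levenberg--Marquardt with
#' multiple starts over phi_p to escape the periodic local minima of the
#' sine profile.
#'
#' @param traj_on Tibble with columns \code{t_s} and \code{z_um} covering the
#'   force-on (pull) phase; uniform sampling.
#' @param bead A \code{\link{bead_spec}}.
#' @param fluid A \code{\link{fluid_state}}.
#' @param drag A \code{\link{wall_drag_spec}}.
#' @param amplitude_pct Drive amplitude (%) of this pull, stored with the
#'   result.
#' @param qc \code{\link{calibration_qc}} thresholds.
#' @param phi_starts Multi-start values for phi_p in rad.
#' @return An object of class \code{stokes_calibration}: fitted
#'   \code{params}, \code{r2_on}, \code{qc_code} ("pass", "stuck_bead",
#'   "start_too_high", "low_r2" or "no_convergence"), start/end heights and
#'   bead position if present in \code{traj_on}.
#' @export
fit_force_model <- function(traj_on, bead, fluid, drag,
                            amplitude_pct = NA_real_,
                            qc = calibration_qc(),
                            phi_starts = c(0.2, 0.8, 1.4)) {
  stopifnot(is.data.frame(traj_on), all(c("t_s", "z_um") %in% names(traj_on)))
  t <- traj_on$t_s - traj_on$t_s[1]
  z_meas <- traj_on$z_um
  z0_um <- z_meas[1]
  out <- list(params = NULL, r2_on = NA_real_, r2_off = NA_real_,
              fitted_density = NA_real_, amplitude_pct = amplitude_pct,
              x_um = if ("x_um" %in% names(traj_on)) mean(traj_on$x_um) else NA_real_,
              y_um = if ("y_um" %in% names(traj_on)) mean(traj_on$y_um) else NA_real_,
              z_start_um = z0_um, z_end_um = z_meas[length(z_meas)],
              qc_code = "pass", converged = FALSE)
  class(out) <- "stokes_calibration"
  displacement <- max(z_meas) - min(z_meas)
  if (displacement < qc$min_displacement_um) {
    out$qc_code <- "stuck_bead"
    return(out)
  }
  if (z0_um > qc$max_start_um) {
    out$qc_code <- "start_too_high"
    return(out)
  }
  z0 <- max(z0_um * 1e-6, drag$z_min)
  # crude f0 seed from the initial climb velocity (force ~ f0 k_p at small z)
  v0 <- (z_meas[min(6, length(z_meas))] - z_meas[1]) * 1e-6 /
    (t[min(6, length(t))] - t[1])
  lam0 <- drag_lambda(drag, z0, bead$radius)
  f_grav <- effective_gravity(bead, fluid)
  kp_seed <- 0.05
  f0_seed <- (6 * pi * bead$radius * fluid$viscosity * lam0 * v0 + f_grav) /
    (kp_seed * 1e6) * 1e18  # pN um
  f0_seed <- min(max(f0_seed, 1e-2), 1e5)
  # The start height is a nuisance parameter: the wall drag diverges at the
  # surface, so the early trajectory is far more sensitive to z0 than the
  # tracking noise on the first sample would suggest.
  resid_fn <- function(par) {
    zp <- tryCatch(
      .predict_pull_z(exp(par[1]), par[2], par[3], bead, fluid, drag,
                      max(par[4] * 1e-6, drag$z_min), t),
      error = function(e) rep(1e6, length(t)))
    zp - z_meas
  }
  best <- NULL
  for (phi0 in phi_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(log(f0_seed), kp_seed, phi0, max(z0_um, 0.02)),
        fn = resid_fn,
        lower = c(log(1e-3), 1e-3, 0, drag$z_min * 1e6),
        upper = c(log(1e6), 1, pi / 2 - 1e-6, qc$max_start_um),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    out$qc_code <- "no_convergence"
    return(out)
  }
  par <- best$par
  out$params <- acoustic_force_params(exp(par[1]), par[2], par[3],
                                      amplitude_pct = amplitude_pct,
                                      correction_method = drag$method)
  out$r2_on <- .r_squared(z_meas, z_meas + best$fvec)
  out$converged <- best$info %in% 1:4
  if (!out$converged) out$qc_code <- "no_convergence"
  else if (out$r2_on < qc$min_r2_on) out$qc_code <- "low_r2"
  out
}

#' @export
print.stokes_calibration <- function(x, ...) {
  cat("<stokes_calibration> qc:", x$qc_code, "\n")
  if (!is.null(x$params)) {
    print(x$params)
    cat(sprintf("  r2_on = %.4f, r2_off = %.4f\n", x$r2_on, x$r2_off))
  }
  invisible(x)
}

#' Tidy a Stokes calibration
#'
#' @param x A \code{stokes_calibration}.
#' @param ... Unused.
#' @return One-row tibble with the fitted parameters and diagnostics.
#' @export
tidy.stokes_calibration <- function(x, ...) {
  tibble::tibble(
    f0_pN_um = if (is.null(x$params)) NA_real_ else x$params$f0 * 1e18,
    k_p_per_um = if (is.null(x$params)) NA_real_ else x$params$k_p * 1e-6,
    phi_p_rad = if (is.null(x$params)) NA_real_ else x$params$phi_p,
    r2_on = x$r2_on, r2_off = x$r2_off,
    fitted_density = x$fitted_density,
    amplitude_pct = x$amplitude_pct,
    x_um = x$x_um, y_um = x$y_um, qc_code = x$qc_code
  )
}

#' Validate a calibration against a gravity fall
#'
#' After the drive is switched off only the buoyant weight acts; nothing is
#' fitted. The fall predicted with the calibrated drag model is compared to
#' the measured fall and summarized as R^2 = 1 - SS_res/SS_tot (may be
#' negative when the drag model is wrong).
#'
#' @param calib A \code{stokes_calibration} (updated in the return value).
#' @param traj_off Tibble with \code{t_s}, \code{z_um} for the fall phase,
#'   starting at the last force-on position.
#' @inheritParams fit_force_model
#' @param start_tol_um Warn if the fall start deviates from the calibrated
#'   pull end by more than this (um).
#' @return The calibration with \code{r2_off} filled in.
#' @export
validate_fall <- function(calib, traj_off, bead, fluid, drag,
                          start_tol_um = 0.5) {
  stopifnot(inherits(calib, "stokes_calibration"),
            all(c("t_s", "z_um") %in% names(traj_off)))
  if (!is.na(calib$z_end_um) &&
      abs(traj_off$z_um[1] - calib$z_end_um) > start_tol_um) {
    warning("fall trace does not start at the calibrated pull end position",
            call. = FALSE)
  }
  t <- traj_off$t_s - traj_off$t_s[1]
  z0 <- max(traj_off$z_um[1] * 1e-6, drag$z_min)
  pred <- simulate_fall(z0, bead, fluid, drag, t)$z_um
  calib$r2_off <- .r_squared(traj_off$z_um, pred)
  calib
}

#' Fit the bead density to a gravity fall
#'
#' Control analysis: the bead density is the single free parameter of the
#' gravity-only fall. With the correct wall-drag model the recovered density
#' should match the bead material (1050 kg m^-3 for polystyrene).
#'
#' @inheritParams validate_fall
#' @param traj_off Fall-phase tibble (\code{t_s}, \code{z_um}).
#' @return Fitted density in kg m^-3.
#' @export
fit_bead_density <- function(traj_off, bead, fluid, drag) {
  stopifnot(all(c("t_s", "z_um") %in% names(traj_off)))
  t <- traj_off$t_s - traj_off$t_s[1]
  z0 <- max(traj_off$z_um[1] * 1e-6, drag$z_min)
  resid_fn <- function(par) {
    b2 <- bead_spec(bead$radius * 1e6, par[1])
    simulate_fall(z0, b2, fluid, drag, t)$z_um - traj_off$z_um
  }
  fit <- minpack.lm::nls.lm(par = c(rho = bead$density), fn = resid_fn,
                            lower = fluid$density + 0.1, upper = 2000,
                            control = minpack.lm::nls.lm.control(maxiter = 100))
  unname(fit$par[1])
}

#' Amplitude-to-force conversion factor
#'
#' Single-parameter least squares of the quadratic force law F = c V^2
#' through the origin, fitted to forces measured at different non-zero drive
#' amplitudes (the forces are taken from each amplitude's fitted profile at
#' a fixed reference height, 1 um by convention).
#'
#' @param forces Data frame with columns \code{amplitude_pct} and
#'   \code{force_pN}.
#' @param min_points Minimum number of valid (non-zero amplitude) points
#'   (default 2; set to 1 to force a single-point conversion).
#' @return Conversion factor c in pN per percent squared.
#' @examples
#' conversion_factor(data.frame(amplitude_pct = c(2, 4),
#'                              force_pN = c(5.575, 22.30)))
#' @export
conversion_factor <- function(forces, min_points = 2) {
  stopifnot(is.data.frame(forces),
            all(c("amplitude_pct", "force_pN") %in% names(forces)))
  ok <- is.finite(forces$amplitude_pct) & is.finite(forces$force_pN) &
    forces$amplitude_pct != 0
  v <- forces$amplitude_pct[ok]
  f <- forces$force_pN[ok]
  if (length(v) < min_points) {
    stop("need at least ", min_points,
         " force values at non-zero amplitude", call. = FALSE)
  }
  cc <- sum(f * v^2) / sum(v^4)
  if (cc <= 0) stop("fitted conversion factor is not positive (QC rejection)",
                    call. = FALSE)
  cc
}

#' Force profile evaluated at the conversion reference height
#'
#' Helper combining per-amplitude calibrations into one conversion factor:
#' evaluates each amplitude's fitted profile at \code{z_ref_um} and fits the
#' quadratic amplitude law.
#'
#' @param calibs List of \code{stokes_calibration} objects, one per
#'   amplitude.
#' @param z_ref_um Reference height in um (default 1).
#' @return Conversion factor c in pN per percent squared.
#' @export
conversion_from_calibrations <- function(calibs, z_ref_um = 1) {
  pts <- purrr::map_dfr(calibs, function(cb) {
    tibble::tibble(
      amplitude_pct = cb$amplitude_pct,
      force_pN = if (is.null(cb$params)) NA_real_ else
        acoustic_force(z_ref_um * 1e-6, cb$params) * 1e12
    )
  })
  conversion_factor(pts)
}

#' Build the spatial calibration map
#'
#' QC-filters per-bead conversion factors and merges beads closer than
#' \code{merge_radius} (greedy nearest-cluster assignment, averaging
#' position and c). Records raw and merged bead counts.
#'
#' @param points Data frame with columns \code{x_um}, \code{y_um},
#'   \code{c_pN_per_pct2}, and optionally \code{r2_on} and \code{qc_code}
#'   used for filtering.
#' @param merge_radius Merge radius in um (default 5, one bead radius).
#' @param interpolation Query mode: \code{"linear"} (local plane fit,
#'   default) or \code{"nearest"}.
#' @param qc \code{\link{calibration_qc}} thresholds (applied where the
#'   corresponding columns are present).
#' @return An object of class \code{conversion_map}.
#' @export
build_spatial_map <- function(points, merge_radius = 5,
                              interpolation = c("linear", "nearest"),
                              qc = calibration_qc()) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.data.frame(points),
            all(c("x_um", "y_um", "c_pN_per_pct2") %in% names(points)))
  keep <- is.finite(points$c_pN_per_pct2) & points$c_pN_per_pct2 > 0
  if ("r2_on" %in% names(points)) {
    keep <- keep & !is.na(points$r2_on) & points$r2_on >= qc$min_r2_on
  }
  if ("qc_code" %in% names(points)) keep <- keep & points$qc_code == "pass"
  pts <- points[keep, , drop = FALSE]
  n_raw <- nrow(pts)
  if (n_raw == 0) stop("no calibration points pass QC", call. = FALSE)
  # greedy merge: assign each bead to the nearest existing cluster centre
  cx <- numeric(0); cy <- numeric(0); cs <- numeric(0); cn <- integer(0)
  for (i in seq_len(n_raw)) {
    if (length(cx) > 0) {
      d2 <- (cx - pts$x_um[i])^2 + (cy - pts$y_um[i])^2
      j <- which.min(d2)
    }
    if (length(cx) > 0 && d2[j] <= merge_radius^2) {
      w <- cn[j]
      cx[j] <- (cx[j] * w + pts$x_um[i]) / (w + 1)
      cy[j] <- (cy[j] * w + pts$y_um[i]) / (w + 1)
      cs[j] <- (cs[j] * w + pts$c_pN_per_pct2[i]) / (w + 1)
      cn[j] <- w + 1L
    } else {
      cx <- c(cx, pts$x_um[i]); cy <- c(cy, pts$y_um[i])
      cs <- c(cs, pts$c_pN_per_pct2[i]); cn <- c(cn, 1L)
    }
  }
  structure(list(
    points = tibble::tibble(x_um = cx, y_um = cy, c_pN_per_pct2 = cs,
                            n_merged = cn),
    merge_radius = merge_radius, interpolation = interpolation,
    n_raw = n_raw, n_merged = length(cx)
  ), class = "conversion_map")
}

#' @export
print.conversion_map <- function(x, ...) {
  cat(sprintf("<conversion_map> %d beads merged to %d points (radius %.1f um, %s lookup)\n",
              x$n_raw, x$n_merged, x$merge_radius, x$interpolation))
  invisible(x)
}

.in_convex_hull <- function(px, py, x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  n <- length(hx)
  # degenerate (collinear) maps have no interior; let the local fit decide
  if (n < 3) return(TRUE)
  # consistent orientation sign test against every hull edge
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    if (abs(cr) < 1e-12) next
    if (sgn == 0) sgn <- sign(cr)
    else if (sign(cr) != sgn) return(FALSE)
  }
  TRUE
}

#' Query the spatial calibration map
#'
#' Interpolates the conversion factor at a query position. In
#' \code{"linear"} mode a plane is fitted to the nearest map points (exact
#' for affine fields and at map points); queries outside the convex hull
#' fall back to the nearest neighbour with a warning. \code{"nearest"} mode
#' returns the closest point's c anywhere.
#'
#' @param map A \code{\link{conversion_map}}.
#' @param x,y Query coordinates in um (vectorized, equal length).
#' @param k Number of neighbours used for the local plane fit.
#' @return Conversion factor(s) in pN per percent squared.
#' @export
lookup_conversion <- function(map, x, y, k = 12) {
  stopifnot(inherits(map, "conversion_map"), length(x) == length(y))
  p <- map$points
  vapply(seq_along(x), function(i) {
    d2 <- (p$x_um - x[i])^2 + (p$y_um - y[i])^2
    j_near <- which.min(d2)
    if (d2[j_near] < 1e-12) return(p$c_pN_per_pct2[j_near])
    if (map$interpolation == "nearest" || nrow(p) == 1) {
      return(p$c_pN_per_pct2[j_near])
    }
    if (nrow(p) == 2) {
      w <- 1 / d2
      return(sum(w * p$c_pN_per_pct2) / sum(w))
    }
    if (!.in_convex_hull(x[i], y[i], p$x_um, p$y_um)) {
      warning("query outside the calibrated region; using nearest neighbour",
              call. = FALSE)
      return(p$c_pN_per_pct2[j_near])
    }
    idx <- order(d2)[seq_len(min(k, nrow(p)))]
    X <- cbind(1, p$x_um[idx] - x[i], p$y_um[idx] - y[i])
    fit <- stats::lm.fit(X, p$c_pN_per_pct2[idx])
    # design is centred at the query: the intercept is the prediction, and
    # rank-deficient (collinear) neighbourhoods reduce to a 1-D line fit
    unname(fit$coefficients[1])
  }, numeric(1))
}
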