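# Multi-frequency oscillatory (mOsc) microrheology: force waveform design,
# force reconstruction from drive amplitude and the spatial map, immersion
# geometry, and sliding-window Fourier estimation of the complex shear
# modulus G*(omega).

#' mOsc protocol
#'
#' The drive superimposes several sinusoidal force components; the defaults
#' follow the monolayer experiments: 0.1, 0.5 and 1.5 Hz applied
#' simultaneously, sampled at 59 Hz, analysed in 500 s windows shifted by
#' 100 s. Every component frequency times the window length must be an
#' integer so windows are leakage-free (50/250/750 cycles).
#'
#' @param frequencies_hz Component frequencies in Hz.
#' @param amplitudes_pN Per-component force amplitudes in pN (recycled).
#' @param offset_pN Constant force offset in pN; must keep min F(t) >= 0.
#' @param duration_s Total drive duration in s.
#' @param sampling_hz Camera sampling rate in Hz (default 59).
#' @param window_s Analysis window length in s (default 500).
#' @param shift_s Window shift in s (default 100).
#' @return An object of class \code{osc_protocol}.
#' @export
osc_protocol <- function(frequencies_hz = c(0.1, 0.5, 1.5),
                         amplitudes_pN = 200, offset_pN = 700,
                         duration_s = 3700, sampling_hz = 59,
                         window_s = 500, shift_s = 100) {
  amplitudes_pN <- rep_len(amplitudes_pN, length(frequencies_hz))
  cyc <- frequencies_hz * window_s
  if (any(abs(cyc - round(cyc)) > 1e-9)) {
    stop("every component frequency times the window length must be an ",
         "integer number of cycles", call. = FALSE)
  }
  if (sampling_hz <= 2 * max(frequencies_hz)) {
    stop("sampling rate must exceed twice the largest component frequency",
         call. = FALSE)
  }
  min_f <- offset_pN - sum(abs(amplitudes_pN))
  if (min_f < 0) {
    stop(sprintf(
      "force waveform can go negative; increase the offset to at least %.3g pN",
      sum(abs(amplitudes_pN))), call. = FALSE)
  }
  structure(list(frequencies_hz = frequencies_hz,
                 amplitudes_pN = amplitudes_pN, offset_pN = offset_pN,
                 duration_s = duration_s, sampling_hz = sampling_hz,
                 window_s = window_s, shift_s = shift_s),
            class = "osc_protocol")
}

#' mOsc force waveform
#'
#' F(t) = offset + sum_i A_i sin(2 pi f_i t).
#'
#' @param protocol An \code{\link{osc_protocol}}.
#' @param t Optional time grid in s; defaults to the protocol's full
#'   duration at its sampling rate.
#' @return Tibble with \code{t_s} and \code{force_pN}.
#' @export
design_mosc_force <- function(protocol, t = NULL) {
  stopifnot(inherits(protocol, "osc_protocol"))
  if (is.null(t)) {
    t <- seq(0, protocol$duration_s - 1 / protocol$sampling_hz,
             by = 1 / protocol$sampling_hz)
  }
  f <- protocol$offset_pN
  for (i in seq_along(protocol$frequencies_hz)) {
    f <- f + protocol$amplitudes_pN[i] *
      sin(2 * pi * protocol$frequencies_hz[i] * t)
  }
  tibble::tibble(t_s = t, force_pN = f)
}

#' Drive amplitude realizing a force waveform
#'
#' Inverts the quadratic conversion law: V(t) = sqrt(F(t)/c).
#'
#' @param force_pN Non-negative force values in pN.
#' @param c_pN_per_pct2 Conversion factor in pN per percent squared (> 0).
#' @return Amplitude in percent.
#' @export
amplitude_from_force <- function(force_pN, c_pN_per_pct2) {
  if (any(force_pN < 0)) stop("force must be non-negative", call. = FALSE)
  stopifnot(c_pN_per_pct2 > 0)
  sqrt(force_pN / c_pN_per_pct2)
}

#' Reconstruct the applied force from a trajectory and the spatial map
#'
#' F(t) = c(x(t), y(t)) * V(t)^2, with the conversion factor re-looked-up as
#' the bead drifts laterally across the field of view.
#'
#' @param traj Tibble with columns \code{x_um}, \code{y_um},
#'   \code{amplitude_pct} (one row per sample).
#' @param map A \code{\link{conversion_map}}, or a single numeric constant c.
#' @return Force in pN, one value per row of \code{traj}.
#' @export
reconstruct_force <- function(traj, map) {
  stopifnot(all(c("amplitude_pct") %in% names(traj)))
  if (is.numeric(map) && length(map) == 1) {
    return(map * traj$amplitude_pct^2)
  }
  stopifnot(inherits(map, "conversion_map"),
            all(c("x_um", "y_um") %in% names(traj)))
  # look up only at distinct positions (beads move slowly relative to frames)
  key <- paste(round(traj$x_um, 3), round(traj$y_um, 3))
  uk <- !duplicated(key)
  cvals <- lookup_conversion(map, traj$x_um[uk], traj$y_um[uk])
  cvals[match(key, key[uk])] * traj$amplitude_pct^2
}

#' Immersion half-angle from the contact-circle diameter
#'
#' theta = arcsin(d / (2R)): the contact circle of diameter d is a chord of
#' the sphere of radius R.
#'
#' @param d Contact-circle diameter (same unit as \code{R}); 0 < d <= 2R.
#' @param R Bead radius.
#' @return Half-angle in rad.
#' @export
immersion_half_angle <- function(d, R) {
  if (any(d <= 0) || any(d > 2 * R)) {
    stop("contact diameter must satisfy 0 < d <= 2R", call. = FALSE)
  }
  asin(d / (2 * R))
}

#' Immersion correction f(theta)
#'
#' Scales the generalized Stokes--Einstein geometry for a bead only
#' partially immersed in the material: f(theta) = 1 - cos(theta), the
#' immersed spherical-cap area relative to a hemisphere. f < 1 on
#' (10 deg, 90 deg), monotone increasing, and f(90 deg) = 1 so that full
#' immersion recovers the generalized Stokes--Einstein relation.
#'
#' @param theta_rad Half-angle in rad, in (0, pi/2].
#' @return Dimensionless correction in (0, 1].
#' @export
immersion_correction <- function(theta_rad) {
  if (any(theta_rad <= 0) || any(theta_rad > pi / 2 + 1e-12)) {
    stop("theta must lie in (0, 90] degrees", call. = FALSE)
  }
  1 - cos(theta_rad)
}

#' Immersion geometry
#'
#' @param R_um Bead radius in um.
#' @param theta_deg Immersion half-angle in degrees (default 28.73, the
#'   measured monolayer mean). Ignored if \code{d_um} is given.
#' @param d_um Optional contact-circle diameter in um, from which theta is
#'   computed.
#' @return An object of class \code{immersion_geometry} with \code{R} (m),
#'   \code{theta} (rad) and \code{f_theta}.
#' @export
immersion_geometry <- function(R_um = 5, theta_deg = 28.73, d_um = NULL) {
  R <- R_um * 1e-6
  theta <- if (!is.null(d_um)) immersion_half_angle(d_um * 1e-6, R)
           else theta_deg * pi / 180
  structure(list(R = R, theta = theta,
                 f_theta = immersion_correction(theta)),
            class = "immersion_geometry")
}

#' Geometry factor of the modulus relation
#'
#' g(R, theta) = 6 pi R f(theta), so that G*(omega) =
#' F~(omega) / (g(R, theta) z~(omega)). At theta = 90 deg this reduces to
#' the generalized Stokes--Einstein factor 6 pi R.
#'
#' @param geom An \code{\link{immersion_geometry}}.
#' @return Geometry factor in m.
#' @export
geometry_factor <- function(geom) {
  stopifnot(inherits(geom, "immersion_geometry"))
  6 * pi * geom$R * geom$f_theta
}

# Harmonic regression at the exact drive frequencies: least squares on the
# basis {1, t, cos(w_i t), sin(w_i t)}. The explicit trend columns remove
# offset and linear drift without biasing the sinusoid coefficients, and the
# estimate is exact (to rounding) for noiseless signals on integer-cycle
# windows. Returns the complex amplitude C_i with x(t) ~ Re(C_i e^{i w t}).
.harmonic_amplitudes <- function(x, basis) {
  cf <- stats::.lm.fit(basis, x)$coefficients
  m <- (length(cf) - 2) / 2
  cf[2 + seq_len(m)] - 1i * cf[2 + m + seq_len(m)]
}

.harmonic_basis <- function(t, freqs_hz) {
  w <- outer(t, 2 * pi * freqs_hz)
  cbind(1, t - mean(t), cos(w), sin(w))
}

#' Complex shear modulus from one analysis window
#'
#' Demodulates force and position at the drive frequencies by harmonic
#' regression (sinusoids plus an explicit offset-and-linear-drift trend) and
#' forms G*(omega) = F~(omega) / (6 pi R f(theta) z~(omega)). Windows
#' holding an integer number of cycles of every target frequency make the
#' estimate leakage-free.
#'
#' @param force_pN Force samples in pN.
#' @param z_um Position samples in um (same grid).
#' @param t_s Time grid in s.
#' @param freqs_hz Target frequencies in Hz.
#' @param geom An \code{\link{immersion_geometry}}.
#' @param z_floor_um Amplitude floor in um below which a point is flagged
#'   invalid (default 1e-6 um).
#' @return Tibble with columns \code{freq_hz}, \code{G1_Pa}, \code{G2_Pa},
#'   \code{absG_Pa}, \code{delta_rad}, \code{valid}.
#' @export
estimate_modulus_window <- function(force_pN, z_um, t_s, freqs_hz, geom,
                                    z_floor_um = 1e-6) {
  stopifnot(length(force_pN) == length(z_um), length(z_um) == length(t_s))
  basis <- .harmonic_basis(t_s, freqs_hz)
  Ft <- .harmonic_amplitudes(force_pN, basis) * 1e-12   # pN -> N
  Zt <- .harmonic_amplitudes(z_um, basis) * 1e-6        # um -> m
  valid <- Mod(Zt) > z_floor_um * 1e-6
  G <- Ft / (geometry_factor(geom) * Zt)
  delta <- Arg(Ft) - Arg(Zt)
  delta <- atan2(sin(delta), cos(delta))  # wrap to (-pi, pi]
  tibble::tibble(
    freq_hz = freqs_hz,
    G1_Pa = Re(G), G2_Pa = Im(G),
    absG_Pa = Mod(G), delta_rad = delta,
    valid = valid
  )
}

#' Sliding-window modulus series for one bead
#'
#' Applies \code{\link{estimate_modulus_window}} in moving windows of length
#' \code{window_s} shifted by \code{shift_s}. Windows whose shift is smaller
#' than the window length overlap; every \code{window_s/shift_s}-th window
#' is marked independent.
#'
#' @param traj Tibble with \code{t_s}, \code{z_um} and either
#'   \code{force_pN} or (\code{amplitude_pct} + positions for \code{map}).
#' @param map A \code{\link{conversion_map}} or constant c; only needed when
#'   \code{traj} lacks a \code{force_pN} column.
#' @param protocol An \code{\link{osc_protocol}}.
#' @param geom An \code{\link{immersion_geometry}}.
#' @return Tibble with \code{t_center_s}, the modulus columns of
#'   \code{\link{estimate_modulus_window}} and \code{independent} flags.
#' @export
sliding_window_series <- function(traj, map = NULL, protocol, geom) {
  stopifnot(inherits(protocol, "osc_protocol"),
            all(c("t_s", "z_um") %in% names(traj)))
  force <- if ("force_pN" %in% names(traj)) traj$force_pN
           else reconstruct_force(traj, map)
  t <- traj$t_s
  dur <- t[length(t)] - t[1] + stats::median(diff(t))
  if (dur < protocol$window_s) {
    stop("trajectory shorter than one analysis window", call. = FALSE)
  }
  n_win <- floor((dur - protocol$window_s) / protocol$shift_s) + 1
  per_indep <- max(1L, as.integer(round(protocol$window_s / protocol$shift_s)))
  purrr::map_dfr(seq_len(n_win), function(w) {
    t0 <- t[1] + (w - 1) * protocol$shift_s
    idx <- which(t >= t0 - 1e-9 & t < t0 + protocol$window_s - 1e-9)
    est <- estimate_modulus_window(force[idx], traj$z_um[idx], t[idx],
                                   protocol$frequencies_hz, geom)
    est$t_center_s <- t0 + protocol$window_s / 2
    est$independent <- ((w - 1L) %% per_indep) == 0L
    est
  })
}

#' Aggregate per-bead modulus series across a population
#'
#' Mean and standard error of the mean of G' and G'' across beads per
#' (window, frequency); |G| and the phase delta are derived from the
#' aggregated components with first-order error propagation. Invalid points
#' are skipped, not deleted.
#'
#' @param series Tibble from \code{\link{sliding_window_series}} for several
#'   beads, with an added \code{bead_id} column.
#' @return Tibble with columns \code{t_center_s}, \code{freq_hz},
#'   \code{G1_Pa}, \code{G2_Pa}, \code{G1_sem_Pa}, \code{G2_sem_Pa},
#'   \code{absG_Pa}, \code{absG_err_Pa}, \code{delta_rad},
#'   \code{delta_err_rad}, \code{n_beads}, \code{independent}.
#' @export
aggregate_beads <- function(series) {
  stopifnot("bead_id" %in% names(series))
  series |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$t_center_s, .data$freq_hz) |>
    dplyr::summarise(
      G1 = mean(.data$G1_Pa), G2 = mean(.data$G2_Pa),
      G1_sem_Pa = stats::sd(.data$G1_Pa) / sqrt(dplyr::n()),
      G2_sem_Pa = stats::sd(.data$G2_Pa) / sqrt(dplyr::n()),
      n_beads = dplyr::n(),
      independent = all(.data$independent),
      .groups = "drop") |>
    dplyr::mutate(
      G1_sem_Pa = ifelse(.data$n_beads > 1, .data$G1_sem_Pa, 0),
      G2_sem_Pa = ifelse(.data$n_beads > 1, .data$G2_sem_Pa, 0),
      absG_Pa = sqrt(.data$G1^2 + .data$G2^2),
      absG_err_Pa = sqrt((.data$G1 * .data$G1_sem_Pa)^2 +
                           (.data$G2 * .data$G2_sem_Pa)^2) / .data$absG_Pa,
      delta_rad = atan2(.data$G2, .data$G1),
      delta_err_rad = sqrt((.data$G2 * .data$G1_sem_Pa)^2 +
                             (.data$G1 * .data$G2_sem_Pa)^2) / .data$absG_Pa^2
    ) |>
    dplyr::rename(G1_Pa = "G1", G2_Pa = "G2") |>
    dplyr::select("t_center_s", "freq_hz", "G1_Pa", "G2_Pa", "G1_sem_Pa",
                  "G2_sem_Pa", "absG_Pa", "absG_err_Pa", "delta_rad",
                  "delta_err_rad", "n_beads", "independent")
}
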