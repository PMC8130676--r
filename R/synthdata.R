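# Seeded generators for every input the pipeline consumes: calibration
# pull/fall traces, spatial conversion-factor fields, and bead-on-cell mOsc
# experiments with configurable ground-truth viscoelasticity and drug time
# courses. All generators are pure functions of (arguments, seed).

.FOV_UM <- c(678.40, 542.72)  # camera field of view (1280 x 1024 px at 0.53 um/px)

#' Synthetic calibration pull/fall trace
#'
#' Simulates the Stokes force calibration protocol: for each drive amplitude
#' a 1 s pull (force on) is followed by a gravity fall (force off), sampled
#' at the camera rate, with additive Gaussian tracking noise. The force
#' profile prefactor scales quadratically with amplitude relative to the
#' reference amplitude the supplied profile was calibrated at.
#'
#' @param params Ground-truth \code{\link{acoustic_force_params}} at
#'   \code{ref_amplitude_pct}.
#' @param bead,fluid,drag Bead, medium and wall-drag specifications.
#' @param amplitudes_pct Drive amplitudes to cycle through (default 2, 3, 4).
#' @param ref_amplitude_pct Amplitude the profile refers to (default 4).
#' @param pull_s Pull duration in s (default 1).
#' @param fall_s Fall duration in s (default 12).
#' @param sampling_hz Camera rate in Hz (default 59).
#' @param noise_um Tracking noise RMS in um (default 0.02, i.e. 20 nm).
#' @param z0_um Start height in um (default 0.1).
#' @param bead_id Identifier stored in the output.
#' @param x_um,y_um Lateral bead position (field-of-view um).
#' @param seed RNG seed.
#' @return Trajectory tibble with columns \code{bead_id}, \code{t_s},
#'   \code{x_um}, \code{y_um}, \code{z_um}, \code{amplitude_pct},
#'   \code{phase} ("on"/"off").
#' @export
gen_calibration_trace <- function(params, bead, fluid, drag,
                                  amplitudes_pct = c(2, 3, 4),
                                  ref_amplitude_pct = 4,
                                  pull_s = 1, fall_s = 12, sampling_hz = 59,
                                  noise_um = 0.02, z0_um = 0.1,
                                  bead_id = "bead1", x_um = .FOV_UM[1] / 2,
                                  y_um = .FOV_UM[2] / 2, seed = 1) {
  stopifnot(inherits(params, "acoustic_force_params"), noise_um >= 0)
  set.seed(seed)
  dt <- 1 / sampling_hz
  t_off <- 0
  segs <- purrr::map(amplitudes_pct, function(V) {
    pV <- acoustic_force_params(
      params$f0 * 1e18 * (V / ref_amplitude_pct)^2,
      params$k_p * 1e-6, params$phi_p, amplitude_pct = V,
      correction_method = params$correction_method)
    t_pull <- seq(0, pull_s, by = dt)
    pull <- integrate_motion(pV, bead, fluid, drag, z0_um * 1e-6, t_pull)
    t_fall <- seq(dt, fall_s, by = dt)
    fall <- simulate_fall(max(pull$z_um[nrow(pull)] * 1e-6, drag$z_min),
                          bead, fluid, drag, c(0, t_fall))[-1, ]
    seg <- dplyr::bind_rows(
      tibble::tibble(t_s = pull$t_s, z_um = pull$z_um, amplitude_pct = V,
                     phase = "on"),
      tibble::tibble(t_s = pull_s + t_fall, z_um = fall$z_um,
                     amplitude_pct = 0, phase = "off"))
    seg$t_s <- seg$t_s + t_off
    t_off <<- t_off + pull_s + fall_s + dt
    seg
  })
  out <- dplyr::bind_rows(segs)
  out$z_um <- pmax(out$z_um + stats::rnorm(nrow(out), 0, noise_um), 0)
  tibble::tibble(bead_id = bead_id, t_s = out$t_s, x_um = x_um, y_um = y_um,
                 z_um = out$z_um, amplitude_pct = out$amplitude_pct,
                 phase = out$phase)
}

#' Synthetic spatial conversion-factor field
#'
#' A smooth band-limited random field over the field of view, affinely
#' rescaled so its max/min ratio over a reference grid equals
#' \code{dynamic_range} (instrument maps vary by up to a factor of six) and
#' its maximum equals \code{c_max}. Virtual beads sample the field at random
#' positions.
#'
#' @param extent_um Field-of-view extent c(x, y) in um.
#' @param n_modes Number of random cosine modes (roughness; default 6).
#' @param dynamic_range Max/min ratio of the rescaled field (>= 1).
#' @param c_max Maximum conversion factor in pN per percent squared.
#' @param n_beads Number of sampled virtual bead positions.
#' @param seed RNG seed.
#' @return A list with \code{field} (vectorized function of x, y in um),
#'   \code{points} (tibble \code{x_um}, \code{y_um}, \code{c_pN_per_pct2}),
#'   and \code{extent_um}.
#' @export
gen_spatial_field <- function(extent_um = .FOV_UM, n_modes = 6,
                              dynamic_range = 6, c_max = 2, n_beads = 1000,
                              seed = 1) {
  stopifnot(dynamic_range >= 1, c_max > 0, n_beads >= 1)
  set.seed(seed)
  kx <- stats::runif(n_modes, 0.5, 2.5) * pi / extent_um[1]
  ky <- stats::runif(n_modes, 0.5, 2.5) * pi / extent_um[2]
  ph <- stats::runif(n_modes, 0, 2 * pi)
  amp <- stats::runif(n_modes, 0.3, 1)
  raw <- function(x, y) {
    g <- 0
    for (m in seq_len(n_modes)) {
      g <- g + amp[m] * cos(kx[m] * x + ky[m] * y + ph[m])
    }
    g
  }
  grd <- expand.grid(x = seq(0, extent_um[1], length.out = 80),
                     y = seq(0, extent_um[2], length.out = 80))
  gv <- raw(grd$x, grd$y)
  gmin <- min(gv); gmax <- max(gv)
  if (dynamic_range == 1 || gmax == gmin) {
    a <- 0; b <- c_max
  } else {
    a <- c_max * (1 - 1 / dynamic_range) / (gmax - gmin)
    b <- c_max - a * gmax
  }
  field <- function(x, y) a * raw(x, y) + b
  xs <- stats::runif(n_beads, 0, extent_um[1])
  ys <- stats::runif(n_beads, 0, extent_um[2])
  list(field = field,
       points = tibble::tibble(x_um = xs, y_um = ys,
                               c_pN_per_pct2 = field(xs, ys)),
       extent_um = extent_um)
}

#' Step stiffness schedule (drug time course)
#'
#' Multiplicative factor on the ground-truth G0 over time: 1 at baseline,
#' \code{factor} between \code{t_on} and \code{t_off} (drug acting), back to
#' 1 after wash-out.
#'
#' @param t_on,t_off Start and end of the perturbed phase in s.
#' @param factor Stiffness factor during the perturbation (default 0.5).
#' @return A vectorized function of time returning the factor.
#' @export
stiffness_step <- function(t_on, t_off, factor = 0.5) {
  stopifnot(t_off > t_on, factor > 0)
  function(t) ifelse(t >= t_on & t < t_off, factor, 1)
}

#' Synthetic multi-oscillation experiment
#'
#' Generates bead-on-cell responses by linear-response superposition: per
#' drive frequency, the displacement amplitude and phase follow from the
#' ground-truth viscoelastic modulus through the same geometry factor the
#' estimator uses, z_i(t) = A_i / (6 pi R f(theta) |G*(f_i)|) *
#' sin(2 pi f_i t - delta_i). Adds linear drift and Gaussian tracking noise,
#' optional per-bead modulus dispersion and an optional stiffness time
#' course (quasi-static scaling of G0).
#'
#' @param truth Named list with ground-truth GKV parameters \code{G0} (Pa),
#'   \code{alpha}, \code{beta}.
#' @param protocol An \code{\link{osc_protocol}}.
#' @param geom An \code{\link{immersion_geometry}}.
#' @param n_beads Number of beads (default 15, a typical experiment).
#' @param noise_um Tracking noise RMS in um (default 0.02).
#' @param drift_um_per_s Linear drift rate in um/s (default 0.001).
#' @param bead_dispersion Lognormal sigma of per-bead G0 factors
#'   (median-unbiased; default 0.1).
#' @param schedule Optional stiffness schedule function of time (see
#'   \code{\link{stiffness_step}}); \code{NULL} for a stationary material.
#' @param map Optional \code{\link{conversion_map}} used to also record the
#'   drive-amplitude channel; \code{NULL} records force only.
#' @param seed RNG seed.
#' @return Trajectory tibble with columns \code{bead_id}, \code{t_s},
#'   \code{x_um}, \code{y_um}, \code{z_um}, \code{force_pN} and, when a map
#'   is supplied, \code{amplitude_pct}.
#' @export
gen_mosc_experiment <- function(truth, protocol, geom, n_beads = 15,
                                noise_um = 0.02, drift_um_per_s = 0.001,
                                bead_dispersion = 0.1, schedule = NULL,
                                map = NULL, seed = 1) {
  stopifnot(inherits(protocol, "osc_protocol"),
            inherits(geom, "immersion_geometry"),
            all(c("G0", "alpha", "beta") %in% names(truth)))
  set.seed(seed)
  t <- seq(0, protocol$duration_s - 1 / protocol$sampling_hz,
           by = 1 / protocol$sampling_hz)
  s_t <- if (is.null(schedule)) rep(1, length(t)) else schedule(t)
  gfac <- geometry_factor(geom)
  omega <- 2 * pi * protocol$frequencies_hz
  Gstar <- gkv_modulus(omega, truth$G0, truth$alpha, truth$beta)
  delta <- Arg(Gstar)
  if (any(delta < 0 | delta > pi / 2 + 1e-12)) {
    stop("ground-truth phase outside [0, pi/2]: not a passive material",
         call. = FALSE)
  }
  force <- design_mosc_force(protocol, t)$force_pN
  xs <- stats::runif(n_beads, 0, .FOV_UM[1])
  ys <- stats::runif(n_beads, 0, .FOV_UM[2])
  g0_fac <- exp(stats::rnorm(n_beads, 0, bead_dispersion))
  purrr::map_dfr(seq_len(n_beads), function(b) {
    z <- drift_um_per_s * t
    for (i in seq_along(omega)) {
      # |G*| scales linearly with the G0 factor; the phase is unchanged
      amp_m <- protocol$amplitudes_pN[i] * 1e-12 /
        (gfac * Mod(Gstar[i]) * g0_fac[b] * s_t)
      z <- z + amp_m * 1e6 * sin(omega[i] * t - delta[i])
    }
    z <- z + stats::rnorm(length(t), 0, noise_um)
    out <- tibble::tibble(bead_id = sprintf("bead%02d", b), t_s = t,
                          x_um = xs[b], y_um = ys[b], z_um = z,
                          force_pN = force)
    if (!is.null(map)) {
      cb <- lookup_conversion(map, xs[b], ys[b])
      out$amplitude_pct <- amplitude_from_force(force, cb)
    }
    out
  })
}
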