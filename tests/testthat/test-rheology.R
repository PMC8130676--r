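# mOsc force design, force reconstruction, immersion geometry, and the
# sliding-window modulus estimator.

geom_def <- immersion_geometry()

test_that("mOsc waveform respects offsets, bounds and orthogonality", {
  p1 <- osc_protocol(frequencies_hz = 0.1, amplitudes_pN = 50,
                     offset_pN = 50, duration_s = 600)
  w <- design_mosc_force(p1)
  # extrema to within the discrete sampling of the grid
  expect_gte(min(w$force_pN), 0)
  expect_lt(min(w$force_pN), 0.01)
  expect_lte(max(w$force_pN), 100)
  expect_gt(max(w$force_pN), 99.99)
  # default three components: demodulation returns each amplitude at its bin
  p3 <- osc_protocol(duration_s = 600)
  w3 <- design_mosc_force(p3)
  idx <- w3$t_s < 500
  basis <- afsrheo:::.harmonic_basis(w3$t_s[idx], c(0.1, 0.5, 1.5, 0.3, 0.7))
  amps <- afsrheo:::.harmonic_amplitudes(w3$force_pN[idx], basis)
  expect_equal(Mod(amps)[1:3], p3$amplitudes_pN, tolerance = 1e-9)
  expect_equal(Mod(amps)[4:5], c(0, 0), tolerance = 1e-9)
  # 500 s windows hold exactly 50/250/750 cycles
  expect_equal(p3$frequencies_hz * p3$window_s, c(50, 250, 750))
})

test_that("protocol invariants are enforced", {
  expect_error(osc_protocol(frequencies_hz = 0.123), "integer")
  expect_error(osc_protocol(offset_pN = 0), "offset")
  expect_error(osc_protocol(frequencies_hz = 40, window_s = 1,
                            sampling_hz = 59), "sampling rate")
})

test_that("amplitude inversion round-trips the quadratic law", {
  expect_equal(amplitude_from_force(1.4, 1.4), 1)
  expect_equal(amplitude_from_force(4 * 1.4, 1.4), 2)
  f <- seq(0, 100, by = 0.5)
  expect_equal(1.7 * amplitude_from_force(f, 1.7)^2, f)
  expect_error(amplitude_from_force(-1, 1.4), "non-negative")
})

test_that("force reconstruction follows the bead across the map", {
  traj <- tibble::tibble(x_um = c(10, 10, 90, 90), y_um = 0,
                         amplitude_pct = 2)
  expect_equal(reconstruct_force(traj, 1.5), rep(6, 4))
  # step in c at the crossing
  map <- build_spatial_map(
    tibble::tibble(x_um = c(0, 20, 80, 100), y_um = 0,
                   c_pN_per_pct2 = c(1, 1, 3, 3)), merge_radius = 1,
    interpolation = "nearest")
  f <- reconstruct_force(traj, map)
  expect_equal(f[1] / f[3], 1 / 3)
  # drifting bead on a linear ramp: analytic composition
  fld_pts <- tibble::tibble(x_um = seq(0, 200, by = 10), y_um = 0,
                            c_pN_per_pct2 = 1 + 0.01 * seq(0, 200, by = 10))
  rmap <- build_spatial_map(fld_pts, merge_radius = 1)
  drift <- tibble::tibble(x_um = seq(5, 195, by = 5), y_um = 0,
                          amplitude_pct = 3)
  expect_equal(reconstruct_force(drift, rmap),
               (1 + 0.01 * drift$x_um) * 9, tolerance = 1e-6)
})

test_that("immersion half-angle is the arcsine of the chord ratio", {
  expect_equal(immersion_half_angle(10e-6, 5e-6), pi / 2)
  expect_equal(immersion_half_angle(5e-6, 5e-6), pi / 6)
  expect_equal(immersion_half_angle(4.807e-6, 5e-6) * 180 / pi, 28.73,
               tolerance = 1e-3)
  expect_error(immersion_half_angle(11e-6, 5e-6), "2R")
})

test_that("immersion correction is below one and monotone, with GSER limit", {
  th <- seq(10, 90, by = 1) * pi / 180
  f <- immersion_correction(th)
  expect_true(all(f[th < pi / 2 - 1e-9] < 1))
  expect_true(all(diff(f) > 0))
  expect_lt(immersion_correction(28.73 * pi / 180), 1)
  # full immersion: geometry factor reduces to 6 pi R
  full <- immersion_geometry(R_um = 5, theta_deg = 90)
  expect_equal(geometry_factor(full), 6 * pi * 5e-6)
  expect_error(immersion_correction(0), "theta")
  expect_error(immersion_correction(pi), "theta")
})

test_that("Newtonian and elastic limits give the expected phase", {
  proto <- proto_short()
  t <- seq(0, 500 - 1 / 59, by = 1 / 59)
  w <- design_mosc_force(proto, t)
  gfac <- geometry_factor(geom_def)
  eta <- 10  # Pa s
  omega <- 2 * pi * proto$frequencies_hz
  # viscous response: z lags force by 90 deg, G'' = omega eta
  z <- rep(0, length(t))
  for (i in seq_along(omega)) {
    z <- z + proto$amplitudes_pN[i] * 1e-12 / (gfac * eta * omega[i]) *
      sin(omega[i] * t - pi / 2) * 1e6
  }
  est <- estimate_modulus_window(w$force_pN, z, t, proto$frequencies_hz,
                                 geom_def)
  expect_equal(est$delta_rad, rep(pi / 2, 3), tolerance = 1e-9)
  expect_equal(est$G2_Pa, omega * eta, tolerance = 1e-9)
  expect_equal(est$G1_Pa, rep(0, 3), tolerance = 1e-6)
  # elastic response: in phase, |G| frequency-independent
  k <- 500  # Pa
  z_el <- rep(0, length(t))
  for (i in seq_along(omega)) {
    z_el <- z_el + proto$amplitudes_pN[i] * 1e-12 / (gfac * k) *
      sin(omega[i] * t) * 1e6
  }
  est_el <- estimate_modulus_window(w$force_pN, z_el, t,
                                    proto$frequencies_hz, geom_def)
  expect_equal(est_el$delta_rad, rep(0, 3), tolerance = 1e-9)
  expect_equal(est_el$absG_Pa, rep(k, 3), tolerance = 1e-9)
})

test_that("a known viscoelastic material is recovered exactly when noiseless", {
  proto <- proto_short()
  tr <- gen_mosc_experiment(gkv_truth, proto, geom_def, n_beads = 1,
                            noise_um = 0, drift_um_per_s = 0.01,
                            bead_dispersion = 0, seed = 4)
  sw <- sliding_window_series(tr, protocol = proto, geom = geom_def)
  truthG <- gkv_modulus(2 * pi * proto$frequencies_hz, gkv_truth$G0,
                        gkv_truth$alpha, gkv_truth$beta)
  for (w in unique(sw$t_center_s)) {
    est <- sw[sw$t_center_s == w, ]
    expect_equal(est$G1_Pa, Re(truthG), tolerance = 1e-9)
    expect_equal(est$G2_Pa, Im(truthG), tolerance = 1e-9)
  }
})

test_that("pipeline is invariant under joint scaling of force and position", {
  proto <- proto_short()
  tr <- gen_mosc_experiment(gkv_truth, proto, geom_def, n_beads = 1,
                            noise_um = 0.01, bead_dispersion = 0, seed = 9)
  s1 <- sliding_window_series(tr, protocol = proto, geom = geom_def)
  tr2 <- tr
  tr2$force_pN <- tr$force_pN * 3.7
  tr2$z_um <- tr$z_um * 3.7
  s2 <- sliding_window_series(tr2, protocol = proto, geom = geom_def)
  expect_equal(s2$G1_Pa, s1$G1_Pa, tolerance = 1e-9)
  expect_equal(s2$G2_Pa, s1$G2_Pa, tolerance = 1e-9)
})

test_that("window layout follows the duration, length and shift", {
  proto <- osc_protocol(duration_s = 3700)
  tr <- gen_mosc_experiment(gkv_truth, proto, geom_def, n_beads = 1,
                            noise_um = 0, bead_dispersion = 0, seed = 2)
  sw <- sliding_window_series(tr, protocol = proto, geom = geom_def)
  centers <- unique(sw$t_center_s)
  expect_equal(length(centers), floor((3700 - 500) / 100) + 1)
  expect_equal(centers[1:3], c(250, 350, 450))
  # every 5th window (500/100) is independent
  expect_equal(unique(sw$independent[sw$t_center_s %in% centers[c(1, 6, 11)]]),
               TRUE)
  expect_equal(unique(sw$independent[sw$t_center_s %in% centers[c(2, 3)]]),
               FALSE)
  expect_error(sliding_window_series(tr[tr$t_s < 400, ], protocol = proto,
                                     geom = geom_def), "shorter")
})

test_that("retained phases satisfy passivity (delta within the quadrant)", {
  proto <- proto_short()
  tr <- gen_mosc_experiment(gkv_truth, proto, geom_def, n_beads = 3,
                            noise_um = 0.02, seed = 12)
  sw <- series_by_bead(tr, proto, geom_def)
  ok <- sw$valid
  expect_true(all(sw$delta_rad[ok] >= 0 & sw$delta_rad[ok] <= pi / 2))
})

test_that("bead aggregation computes mean, SEM and propagated errors", {
  base <- tibble::tibble(t_center_s = 250, freq_hz = 0.5, valid = TRUE,
                         independent = TRUE)
  two <- dplyr::bind_rows(
    dplyr::mutate(base, bead_id = "a", G1_Pa = 1000, G2_Pa = 500,
                  absG_Pa = NA, delta_rad = NA),
    dplyr::mutate(base, bead_id = "b", G1_Pa = 3000, G2_Pa = 500,
                  absG_Pa = NA, delta_rad = NA))
  agg <- aggregate_beads(two)
  expect_equal(agg$G1_Pa, 2000)
  expect_equal(agg$G1_sem_Pa, 1000)  # sd/sqrt(2) of {1,3} kPa
  expect_equal(agg$n_beads, 2L)
  # identical beads: SEM zero
  same <- dplyr::bind_rows(
    dplyr::mutate(base, bead_id = "a", G1_Pa = 1000, G2_Pa = 500,
                  absG_Pa = NA, delta_rad = NA),
    dplyr::mutate(base, bead_id = "b", G1_Pa = 1000, G2_Pa = 500,
                  absG_Pa = NA, delta_rad = NA))
  expect_equal(aggregate_beads(same)$G1_sem_Pa, 0)
  # single bead: values pass through with zero SEM
  one <- dplyr::mutate(base, bead_id = "a", G1_Pa = 1200, G2_Pa = 600,
                       absG_Pa = NA, delta_rad = NA)
  agg1 <- aggregate_beads(one)
  expect_equal(agg1$G1_Pa, 1200)
  expect_equal(agg1$G1_sem_Pa, 0)
  expect_equal(agg1$delta_rad, atan2(600, 1200))
})
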