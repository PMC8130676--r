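# Stokes force calibration: pull-trace fitting, fall validation, density
# control analysis, amplitude conversion, and the spatial map.

make_pull <- function(noise_um = 0, seed = 1, drag = drag_brenner) {
  t <- t59(1)
  z <- integrate_motion(params_ref, bead10, fl36, drag, 0.1e-6, t)$z_um
  if (noise_um > 0) {
    set.seed(seed)
    z <- pmax(z + rnorm(length(z), 0, noise_um), 0)
  }
  tibble::tibble(t_s = t, z_um = z)
}

make_fall <- function(z0_um, noise_um = 0, seed = 1, dur = 12) {
  t <- t59(dur)
  z <- simulate_fall(z0_um * 1e-6, bead10, fl36, drag_brenner, t)$z_um
  if (noise_um > 0) {
    set.seed(seed)
    z <- pmax(z + rnorm(length(z), 0, noise_um), 0)
  }
  tibble::tibble(t_s = t, z_um = z)
}

test_that("noiseless pull trace returns the generating parameters", {
  cal <- fit_force_model(make_pull(), bead10, fl36, drag_brenner,
                         amplitude_pct = 4)
  expect_equal(cal$qc_code, "pass")
  td <- tidy(cal)
  expect_equal(td$f0_pN_um, 488.189, tolerance = 0.01)
  expect_equal(td$k_p_per_um, 0.046, tolerance = 0.01)
  expect_equal(td$phi_p_rad, 0.799, tolerance = 0.01)
  expect_gt(td$r2_on, 0.9999)
})

test_that("tracking noise leaves the recovered profile within a few percent", {
  # median over seeded repetitions; the conversion-relevant quantity is the
  # force at the 1 um reference height
  reps <- lapply(1:10, function(s) {
    cal <- fit_force_model(make_pull(noise_um = 0.02, seed = s),
                           bead10, fl36, drag_brenner)
    c(f0 = tidy(cal)$f0_pN_um,
      F1 = acoustic_force(1e-6, cal$params) * 1e12)
  })
  reps <- do.call(rbind, reps)
  f_true <- acoustic_force(1e-6, params_ref) * 1e12
  expect_lt(abs(median(reps[, "f0"]) / 488.189 - 1), 0.05)
  expect_lt(abs(median(reps[, "F1"]) / f_true - 1), 0.05)
})

test_that("degenerate traces are rejected by QC, not fitted", {
  flat <- tibble::tibble(t_s = t59(1), z_um = rep(0.1, 60))
  expect_equal(fit_force_model(flat, bead10, fl36, drag_brenner)$qc_code,
               "stuck_bead")
  high <- tibble::tibble(t_s = t59(1), z_um = seq(5, 16, length.out = 60))
  expect_equal(fit_force_model(high, bead10, fl36, drag_brenner)$qc_code,
               "start_too_high")
})

test_that("fall validation ranks the drag models as the physics demands", {
  cal <- fit_force_model(make_pull(), bead10, fl36, drag_brenner)
  traj_off <- make_fall(z0_um = 16.6, noise_um = 0.02)
  r2 <- vapply(list(drag_brenner, drag_faxen, drag_none), function(d) {
    validate_fall(cal, traj_off, bead10, fl36, d)$r2_off
  }, numeric(1))
  expect_gt(r2[1], 0.99)              # matched model predicts the fall
  expect_gt(r2[1], r2[2])             # Brenner > Faxen
  expect_gt(r2[2], r2[3])             # Faxen > no correction
})

test_that("perfect prediction gives r2_off of one", {
  cal <- fit_force_model(make_pull(), bead10, fl36, drag_brenner)
  traj_off <- make_fall(z0_um = cal$z_end_um)
  expect_equal(validate_fall(cal, traj_off, bead10, fl36,
                             drag_brenner)$r2_off, 1, tolerance = 1e-6)
})

test_that("a mismatched fall start position triggers a warning", {
  cal <- fit_force_model(make_pull(), bead10, fl36, drag_brenner)
  traj_off <- make_fall(z0_um = cal$z_end_um - 3)
  expect_warning(validate_fall(cal, traj_off, bead10, fl36, drag_brenner),
                 "start")
})

test_that("bead density is recovered from the fall under the matched model", {
  traj_off <- make_fall(z0_um = 16)
  rho <- fit_bead_density(traj_off, bead10, fl36, drag_brenner)
  expect_equal(rho, 1050, tolerance = 5e-3)
  set.seed(11)
  noisy <- traj_off
  noisy$z_um <- pmax(noisy$z_um + rnorm(nrow(noisy), 0, 0.02), 0)
  expect_equal(fit_bead_density(noisy, bead10, fl36, drag_brenner), 1050,
               tolerance = 5e-3)
  # the wrong drag model biases the density well beyond that tolerance
  rho_none <- fit_bead_density(traj_off, bead10, fl36, drag_none)
  expect_gt(abs(rho_none - 1050) / 1050, 5e-3)
})

test_that("refitting under the wrong correction spreads the prefactor", {
  pull <- make_pull()
  f0_b <- tidy(fit_force_model(pull, bead10, fl36, drag_brenner))$f0_pN_um
  f0_n <- tidy(fit_force_model(pull, bead10, fl36, drag_none))$f0_pN_um
  expect_gt(f0_b / f0_n, 2)
})

test_that("conversion factor solves the quadratic amplitude law", {
  expect_equal(conversion_factor(data.frame(amplitude_pct = c(2, 4),
                                            force_pN = c(5.575, 22.30))),
               1.394, tolerance = 1e-3)
  # exact quadratic data: zero residual
  cc <- 1.7
  pts <- data.frame(amplitude_pct = c(1, 3, 5),
                    force_pN = cc * c(1, 3, 5)^2)
  expect_equal(conversion_factor(pts), cc)
  # forced single-point conversion
  expect_equal(conversion_factor(data.frame(amplitude_pct = 3, force_pN = 18),
                                 min_points = 1), 2)
  expect_error(conversion_factor(data.frame(amplitude_pct = 3, force_pN = 18)),
               "at least 2")
  expect_error(conversion_factor(data.frame(amplitude_pct = c(1, 2),
                                            force_pN = c(-1, -4))),
               "not positive")
})

test_that("per-amplitude calibrations combine into one conversion factor", {
  tr <- gen_calibration_trace(params_ref, bead10, fl36, drag_brenner,
                              noise_um = 0, seed = 3)
  calibs <- lapply(c(2, 3, 4), function(V) {
    seg <- tr[tr$amplitude_pct == V & tr$phase == "on", ]
    fit_force_model(seg, bead10, fl36, drag_brenner, amplitude_pct = V)
  })
  c_fit <- conversion_from_calibrations(calibs)
  c_true <- acoustic_force(1e-6, params_ref) * 1e12 / 16
  expect_equal(c_fit, c_true, tolerance = 0.01)
})

test_that("spatial map merges nearby beads and filters QC failures", {
  pts <- tibble::tibble(x_um = c(100, 100.8, 300), y_um = c(50, 50.6, 200),
                        c_pN_per_pct2 = c(1, 3, 5))
  map <- build_spatial_map(pts, merge_radius = 5)
  expect_equal(map$n_raw, 3)
  expect_equal(map$n_merged, 2)
  expect_equal(sort(map$points$c_pN_per_pct2), c(2, 5))
  bad <- tibble::tibble(x_um = 1, y_um = 1, c_pN_per_pct2 = 2, r2_on = 0.5)
  expect_error(build_spatial_map(bad), "QC")
})

test_that("map lookup is exact at points and averages a two-point ramp", {
  pts <- tibble::tibble(x_um = c(0, 100), y_um = c(0, 0),
                        c_pN_per_pct2 = c(1, 3))
  map <- build_spatial_map(pts, merge_radius = 1)
  expect_equal(lookup_conversion(map, 0, 0), 1)
  expect_equal(lookup_conversion(map, 100, 0), 3)
  expect_equal(lookup_conversion(map, 50, 0), 2)
  # constant map: constant everywhere
  cmap <- build_spatial_map(tibble::tibble(x_um = c(0, 50, 100, 50),
                                           y_um = c(0, 80, 0, 30),
                                           c_pN_per_pct2 = 1.4),
                            merge_radius = 1)
  expect_equal(lookup_conversion(cmap, c(25, 60), c(20, 40)), c(1.4, 1.4))
})

test_that("a smooth synthetic field is reconstructed within 10 percent", {
  fld <- gen_spatial_field(n_beads = 1000, seed = 5)
  map <- build_spatial_map(fld$points, merge_radius = 1)
  qx <- seq(80, 600, length.out = 12)
  qy <- seq(60, 480, length.out = 12)
  grid <- expand.grid(x = qx, y = qy)
  est <- lookup_conversion(map, grid$x, grid$y)
  truth <- fld$field(grid$x, grid$y)
  expect_lt(max(abs(est - truth) / truth), 0.10)
})

test_that("queries outside the calibrated region fall back with a warning", {
  pts <- tibble::tibble(x_um = c(0, 100, 50), y_um = c(0, 0, 80),
                        c_pN_per_pct2 = c(1, 2, 3))
  map <- build_spatial_map(pts, merge_radius = 1)
  expect_warning(v <- lookup_conversion(map, 500, 500), "nearest")
  expect_true(v %in% pts$c_pN_per_pct2)
})
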