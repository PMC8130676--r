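# File formats, configuration and the end-to-end workflow. All artifacts are
# delimited text with explicit unit suffixes in column names; every output is
# regenerable from (config, inputs, seed).

.TRAJ_COLS <- c("bead_id", "t_s", "x_um", "y_um", "z_um", "amplitude_pct")

#' Read bead trajectories
#'
#' Reads the delimited trajectory format (header mandatory; columns
#' \code{bead_id}, \code{t_s}, \code{x_um}, \code{y_um}, \code{z_um},
#' \code{amplitude_pct}, optionally \code{phase} and \code{force_pN}; one
#' file may hold many beads). Validates monotone time per bead, reports rows
#' with non-finite positions, and infers the sampling rate from the
#' timestamps.
#'
#' @param path File path.
#' @return Tibble of trajectories with attributes \code{sampling_hz}
#'   (inferred) and \code{n_flagged} (rows with non-finite z).
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path,
                               call. = FALSE)
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(.TRAJ_COLS, names(tr))
  if (length(missing_cols) > 0) {
    stop("trajectory file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(tr$z_um)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite z flagged (lines ",
            paste(utils::head(which(bad) + 1, 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", ")", call. = FALSE)
  }
  tr$z_flagged <- bad
  rates <- tr |>
    dplyr::group_by(.data$bead_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$t_s, strictly = TRUE),
                     rate = 1 / stats::median(diff(.data$t_s)),
                     .groups = "drop")
  if (any(!rates$ok)) {
    stop("non-monotone time for bead(s): ",
         paste(rates$bead_id[!rates$ok], collapse = ", "), call. = FALSE)
  }
  if (diff(range(rates$rate)) > 0.5) {
    stop("mixed sampling rates across beads", call. = FALSE)
  }
  attr(tr, "sampling_hz") <- stats::median(rates$rate)
  attr(tr, "n_flagged") <- sum(bad)
  tr
}

#' Write bead trajectories
#'
#' @param traj Trajectory tibble.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  readr::write_csv(traj, path, progress = FALSE)
  invisible(path)
}

#' Write a spatial calibration map
#'
#' @param map A \code{\link{conversion_map}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "conversion_map"))
  readr::write_csv(map$points, path, progress = FALSE)
  invisible(path)
}

#' Read a spatial calibration map
#'
#' @param path File with columns \code{x_um}, \code{y_um},
#'   \code{c_pN_per_pct2} and optionally \code{n_merged}.
#' @param interpolation Query mode for the returned map.
#' @return A \code{\link{conversion_map}}.
#' @export
read_map <- function(path, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  pts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("x_um", "y_um", "c_pN_per_pct2")
  if (!all(need %in% names(pts))) {
    stop("map file lacks required columns: ",
         paste(setdiff(need, names(pts)), collapse = ", "), call. = FALSE)
  }
  if (!"n_merged" %in% names(pts)) pts$n_merged <- 1L
  structure(list(points = tibble::as_tibble(pts), merge_radius = NA_real_,
                 interpolation = interpolation, n_raw = nrow(pts),
                 n_merged = nrow(pts)),
            class = "conversion_map")
}

.CONFIG_SCHEMA <- list(
  fluid = c("temperature_C", "pressure_kPa", "viscosity_factor", "medium"),
  bead = c("radius_um", "density", "coating"),
  channel = c("height_um", "width_mm", "flow_ul_per_min"),
  calibration = c("correction", "n_terms", "z_min_nm", "merge_radius_um",
                  "z_ref_um", "min_displacement_um", "min_r2_on",
                  "max_start_um", "amplitudes_pct"),
  protocol = c("frequencies_hz", "amplitudes_pN", "offset_pN", "duration_s",
               "sampling_hz", "window_s", "shift_s"),
  geometry = c("theta_deg", "contact_diameter_um"),
  fitting = c("model", "r2_min_sfe", "r2_flag_gkv", "n_boot",
              "log_residuals"),
  synthetic = c("enabled", "truth_G0_Pa", "truth_alpha", "truth_beta",
                "n_beads", "noise_nm", "drift_nm_per_s", "bead_dispersion",
                "dynamic_range", "n_field_beads", "schedule_t_on_s",
                "schedule_t_off_s", "schedule_factor"),
  run = c("seed", "output_dir", "log_level")
)

#' Read and validate a run configuration
#'
#' YAML configuration with sections \code{fluid}, \code{bead},
#' \code{channel}, \code{calibration}, \code{protocol}, \code{geometry},
#' \code{fitting}, \code{synthetic}, \code{run}. Unknown sections or keys
#' are rejected before any computation.
#'
#' @param path YAML file path.
#' @return Named list of configuration sections (validated).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown_sec <- setdiff(names(cfg), names(.CONFIG_SCHEMA))
  if (length(unknown_sec) > 0) {
    stop("unknown config section(s): ", paste(unknown_sec, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(cfg)) {
    unknown <- setdiff(names(cfg[[sec]]), .CONFIG_SCHEMA[[sec]])
    if (length(unknown) > 0) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  cfg
}

.cfg_get <- function(cfg, sec, key, default) {
  v <- cfg[[sec]][[key]]
  if (is.null(v)) default else v
}

#' Run the synthetic end-to-end workflow
#'
#' Generates a spatial calibration field, builds the conversion map,
#' synthesizes a multi-oscillation experiment on it, estimates the
#' sliding-window modulus series, fits the viscoelastic models per window,
#' and writes all artifacts (map, spectra, fits) as delimited text to the
#' configured output directory. Deterministic given (config, seed).
#'
#' @param config Configuration list from \code{\link{read_config}} (or an
#'   equivalent nested list).
#' @return Invisibly, a list with \code{map}, \code{spectra} (aggregated
#'   series), \code{fits} (per-window GKV results) and the written file
#'   paths.
#' @export
run_pipeline <- function(config) {
  seed <- .cfg_get(config, "run", "seed", 1)
  out_dir <- .cfg_get(config, "run", "output_dir", tempdir())
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!isTRUE(.cfg_get(config, "synthetic", "enabled", TRUE))) {
    stop("run_pipeline drives the synthetic workflow; set synthetic.enabled",
         call. = FALSE)
  }
  protocol <- osc_protocol(
    frequencies_hz = .cfg_get(config, "protocol", "frequencies_hz",
                              c(0.1, 0.5, 1.5)),
    amplitudes_pN = .cfg_get(config, "protocol", "amplitudes_pN", 50),
    offset_pN = .cfg_get(config, "protocol", "offset_pN", 200),
    duration_s = .cfg_get(config, "protocol", "duration_s", 3700),
    sampling_hz = .cfg_get(config, "protocol", "sampling_hz", 59),
    window_s = .cfg_get(config, "protocol", "window_s", 500),
    shift_s = .cfg_get(config, "protocol", "shift_s", 100))
  geom <- immersion_geometry(
    R_um = .cfg_get(config, "bead", "radius_um", 5),
    theta_deg = .cfg_get(config, "geometry", "theta_deg", 28.73))
  truth <- list(G0 = .cfg_get(config, "synthetic", "truth_G0_Pa", 1033),
                alpha = .cfg_get(config, "synthetic", "truth_alpha", 0.850),
                beta = .cfg_get(config, "synthetic", "truth_beta", 0.058))
  t_on <- .cfg_get(config, "synthetic", "schedule_t_on_s", NULL)
  schedule <- if (is.null(t_on)) NULL else {
    stiffness_step(t_on,
                   .cfg_get(config, "synthetic", "schedule_t_off_s", Inf),
                   .cfg_get(config, "synthetic", "schedule_factor", 0.5))
  }
  field <- gen_spatial_field(
    dynamic_range = .cfg_get(config, "synthetic", "dynamic_range", 6),
    n_beads = .cfg_get(config, "synthetic", "n_field_beads", 200),
    seed = seed)
  map <- build_spatial_map(
    field$points,
    merge_radius = .cfg_get(config, "calibration", "merge_radius_um", 5))
  traj <- gen_mosc_experiment(
    truth, protocol, geom,
    n_beads = .cfg_get(config, "synthetic", "n_beads", 15),
    noise_um = .cfg_get(config, "synthetic", "noise_nm", 20) * 1e-3,
    drift_um_per_s = .cfg_get(config, "synthetic", "drift_nm_per_s", 1) * 1e-3,
    bead_dispersion = .cfg_get(config, "synthetic", "bead_dispersion", 0.1),
    schedule = schedule, map = map, seed = seed + 1)
  series <- traj |>
    dplyr::group_by(.data$bead_id) |>
    dplyr::group_modify(~ sliding_window_series(.x, map = map,
                                                protocol = protocol,
                                                geom = geom)) |>
    dplyr::ungroup()
  spectra <- aggregate_beads(series)
  fits <- spectra |>
    dplyr::group_by(.data$t_center_s) |>
    dplyr::group_modify(function(sp, key) {
      ft <- fit_gkv(sp)
      tibble::tibble(G0_Pa = ft$G0, alpha = ft$alpha, beta = ft$beta,
                     fx_Hz = ft$f_x, E_Pa = ft$E, r2 = ft$r2,
                     n_beads = max(sp$n_beads),
                     flag = ifelse(ft$flagged, "flagged", "ok"))
    }) |>
    dplyr::ungroup()
  paths <- list(map = file.path(out_dir, "calibration_map.csv"),
                spectra = file.path(out_dir, "modulus_spectra.csv"),
                fits = file.path(out_dir, "gkv_fits.csv"))
  write_map(map, paths$map)
  readr::write_csv(spectra, paths$spectra, progress = FALSE)
  readr::write_csv(fits, paths$fits, progress = FALSE)
  invisible(list(map = map, spectra = spectra, fits = fits, paths = paths))
}
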