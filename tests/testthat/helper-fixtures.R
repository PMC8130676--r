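# Shared fixtures: the experimental operating point (36 degC water, 10 um
# polystyrene beads) and the published Brenner-corrected force profile used
# as ground truth for synthetic traces.

fl36 <- fluid_state(36)
bead10 <- bead_spec(radius_um = 5, density = 1050)
drag_brenner <- wall_drag_spec("brenner")
drag_faxen <- wall_drag_spec("faxen")
drag_none <- wall_drag_spec("none")

# published Brenner-row calibration triple
params_ref <- acoustic_force_params(488.189, 0.046, 0.799, amplitude_pct = 4)

t59 <- function(dur, from = 0) seq(from, dur, by = 1 / 59)

# short mOsc protocol for fast tests: one 500 s window
proto_short <- function(duration_s = 600, ...) {
  osc_protocol(duration_s = duration_s, ...)
}

gkv_truth <- list(G0 = 1033, alpha = 0.850, beta = 0.058)

# per-bead sliding-window series for a multi-bead trajectory set
series_by_bead <- function(traj, protocol, geom, map = NULL) {
  traj |>
    dplyr::group_by(bead_id) |>
    dplyr::group_modify(~ sliding_window_series(.x, map = map,
                                                protocol = protocol,
                                                geom = geom)) |>
    dplyr::ungroup()
}
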