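# Example run configuration for the synthetic end-to-end workflow.
fluid:
  temperature_C: 36
  pressure_kPa: 101.325
  viscosity_factor: 1.0
bead:
  radius_um: 5
  density: 1050
channel:
  height_um: 100
  width_mm: 2
  flow_ul_per_min: 1.66
calibration:
  correction: brenner
  n_terms: 100
  merge_radius_um: 5
  z_ref_um: 1
protocol:
  frequencies_hz: [0.1, 0.5, 1.5]
  amplitudes_pN: [200, 200, 200]
  offset_pN: 700
  duration_s: 3700
  sampling_hz: 59
  window_s: 500
  shift_s: 100
geometry:
  theta_deg: 28.73
synthetic:
  enabled: true
  truth_G0_Pa: 1033
  truth_alpha: 0.850
  truth_beta: 0.058
  n_beads: 15
  noise_nm: 20
  drift_nm_per_s: 1
  bead_dispersion: 0.1
  dynamic_range: 6
  n_field_beads: 200
run:
  seed: 1
  output_dir: afsrheo-output
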