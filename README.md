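# afsrheo

Calibration and analysis for **acoustic force spectroscopy (AFS)
microrheology**: from raw bead trajectories to the frequency-dependent
complex shear modulus of cells, with honest uncertainties.

AFS chips drive a standing acoustic pressure wave across a microfluidic
chamber, pushing microspheres along *z* toward a pressure node. With beads
bound to a cell monolayer, modulating the drive oscillates dozens of beads
at once against the cells — a high-throughput active microrheology
measurement that works under continuous medium flow. The catch is that the
instrument only exposes a drive amplitude in percent; the force behind it
depends on the height, the lateral position in the field of view, the
temperature, the medium, and the individual chip. This package implements
the full quantitative chain:

* **Stokes force calibration (SFC).** The acoustic force profile
  F_ac(z) = f₀ k_p sin(2(k_p z + φ_p)) is fitted to the overdamped rise of
  a bead during a force pulse, dz/dt = (F_ac − F_grav)/(6πR λ(z) η), using
  **Brenner's exact series** for the wall-drag factor λ of a sphere moving
  perpendicular to a plane (the parallel-wall Faxén factor and an
  uncorrected option are included for comparison). The parameter-free
  gravity fall after switch-off validates the drag model: only the
  perpendicular correction predicts it.
* **Spatial conversion maps.** Force and amplitude obey F = c·V², with c
  (pN/%²) varying several-fold across the field of view; per-bead
  calibrations are QC-filtered, merged, and interpolated as beads drift.
* **Multi-oscillation (mOsc) rheology.** Several force frequencies
  (0.1/0.5/1.5 Hz by default) are applied simultaneously; sliding 500 s
  windows (100 s shift) hold integer cycle counts of every component, and
  harmonic regression gives leakage-free force and position phasors. The
  modulus follows from G*(ω) = F̃/(6πR f(θ) z̃), with an immersion
  correction f(θ) for beads partially embedded in the cell surface
  (θ = arcsin(d/2R) from the contact-circle diameter).
* **Fractional viscoelastic models.** A single springpot
  (G* = G̃(iωt₀)^α) fitted separately to G′ and G″, and the generalized
  Kelvin–Voigt model G*(ω) = G₀[(iωt₀)^α + (iωt₀)^β] fitted jointly, with
  closed-form G′=G″ crossover frequency, Young's modulus E = 2G₀(1+ν), and
  seeded bead-bootstrap 2σ confidence intervals.
* **A seeded forward simulator** for every input: calibration pull/fall
  traces, spatial c-fields, and bead-on-cell mOsc experiments with known
  ground-truth viscoelasticity, drift, tracking noise, and optional drug
  time courses.

See the methods vignette (`vignettes/afs-microrheology.Rmd`) for the models,
assumptions, and numerical choices.

## Worked example

```r
library(afsrheo)

## medium at the 36 degC set point
fl <- fluid_state(36)
fl
#> <fluid_state> water at 36.00 degC, 101.325 kPa
#>   density 993.681 kg/m^3 | viscosity 0.0007073 Pa s | c 1505.7 m/s

## wall shear stress at the culture flow rate (1.66 ul/min, 100 um x 2 mm)
wall_shear_stress(fl, channel_geometry(100, 2, flow_ul_per_min = 1.66)) * 1e3
#> 5.9  (mPa) — gentle enough to grow a monolayer

## a calibrated force profile: force at the 1 um reference height and the
## first acoustic node
params <- acoustic_force_params(488.189, 0.046, 0.799)  # f0, k_p, phi_p
acoustic_force(1e-6, params) * 1e12   #> 22.3 pN
node_position(params) * 1e6           #> 16.8 um (inside the usable 10-20 um band)

## amplitude-to-force conversion from two calibrated amplitudes
conversion_factor(data.frame(amplitude_pct = c(2, 4),
                             force_pN     = c(5.575, 22.30)))
#> 1.394  (pN per percent squared)

## synthetic mOsc experiment on a known material, full analysis chain
proto <- osc_protocol(duration_s = 1100)
geom  <- immersion_geometry(theta_deg = 28.73)
traj  <- gen_mosc_experiment(list(G0 = 1033, alpha = 0.850, beta = 0.058),
                             proto, geom, n_beads = 5, seed = 42)
series <- traj |>
  dplyr::group_by(bead_id) |>
  dplyr::group_modify(~ sliding_window_series(.x, protocol = proto, geom = geom)) |>
  dplyr::ungroup()
spectra <- aggregate_beads(series)
spectra[spectra$t_center_s == 250, c("freq_hz", "G1_Pa", "G2_Pa", "n_beads")]
#>   freq_hz G1_Pa G2_Pa n_beads
#> 1     0.1 1242.  827.       5
#> 2     0.5 1836. 3042.       5
#> 3     1.5 2635. 7366.       5

fit_gkv(spectra[spectra$t_center_s == 250, ])
#> <gkv_fit> G0 = 1065 Pa, alpha = 0.868, beta = 0.058 (R2 = 0.9983)
#>   crossover f_x = 0.1936 Hz, E = 3195 Pa
```

The fitted G₀ ≈ 1.07 kPa, α ≈ 0.87 and β ≈ 0.06 recover the generating
material (G₀ = 1.033 kPa, α = 0.850, β = 0.058) from 5 noisy beads and one
500 s window; the storage/loss crossover near 0.2 Hz marks the transition
from solid-like to fluid-like response, and E ≈ 3.2 kPa is the equivalent
Young's modulus for an incompressible material.

`tidy()` and `glance()` methods give tibble views of fits,
`plot_modulus_series()`, `plot_modulus_spectrum()` and
`plot_conversion_map()` the standard figures, and `run_pipeline()` the
config-driven end-to-end workflow (see
`inst/extdata/example_config.yaml`). A thin command-line wrapper lives at
`inst/cli/afs-rheo.R` with subcommands `calibrate`, `map`, `rheology`,
`fit` and `run`.

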