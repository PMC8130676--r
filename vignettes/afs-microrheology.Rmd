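---
title: "Methods: acoustic force spectroscopy calibration and multi-oscillation microrheology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AFS calibration and multi-oscillation microrheology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afsrheo)
```

## The measurement

Acoustic force spectroscopy (AFS) drives a piezo element glued to a
microfluidic chip, creating a standing pressure wave across the ~100 µm fluid
layer. Microspheres in the chamber experience an acoustic radiation force
along *z* that pulls them toward the first pressure node, 10–20 µm above the
bottom glass. When beads are bound to a cell monolayer grown on that glass,
modulating the drive amplitude oscillates the beads against the cells, and
the ratio of applied force to measured displacement gives the complex shear
modulus of the cell surface — an active, highly parallel microrheology
measurement under physiological flow.

Two quantitative problems stand between the raw camera tracks and a modulus:

1. **Calibration** — the instrument exposes only a drive amplitude in
   percent; the force it corresponds to depends on the *z*-position, the
   lateral (*x*, *y*) position in the field of view, the temperature, the
   medium, and the individual chip.
2. **Rheology** — converting per-frequency force/displacement ratios into a
   material model with meaningful parameters and honest uncertainties.

This package implements both halves plus a seeded forward simulator that can
generate every input synthetically, so the full pipeline is testable without
instrument data.

## Stokes force calibration (SFC)

A free bead in the chamber obeys a force balance between the acoustic force,
the buoyancy-corrected weight, and Stokes drag. With no inertia (bead
Reynolds number ≪ 1) the equation of motion is first order:

$$\frac{dz}{dt} \;=\; \frac{F_\mathrm{ac}(z) - F_\mathrm{grav}}
{6\pi R\, \lambda(z)\, \eta},$$

where the acoustic force profile is parameterized as

$$F_\mathrm{ac}(z) = f_0\, k_p \sin\!\big(2 (k_p z + \phi_p)\big),$$

with prefactor $f_0$ (pN µm), wave number $k_p$ (µm⁻¹) and phase $\phi_p$
(rad). The prefactor absorbs the acoustic radiation prefactor, so no material
compressibilities are needed for calibration. Fitting $(f_0, k_p, \phi_p)$ to
the measured rise of a bead during a ~1 s force pulse calibrates the profile;
the subsequent gravity-only fall back to the surface involves **no free
parameters** and validates the drag model.

The wall-drag factor $\lambda(z)$ is the crux. A bead moving perpendicular to
a plane wall experiences drag described by Brenner's exact series solution
(in bipolar coordinates, with $\cosh\alpha = L/R$, $L = z + R$), which
diverges like $R/z$ at contact. The package evaluates the exact series,
truncated at 100 terms by default (relative truncation error below 10⁻⁶ for
$L/R \ge 1.1$; verified against a 10⁴-term evaluation in the tests). The
parallel-wall Faxén polynomial — the standard optical-tweezers correction —
and an uncorrected option are provided for comparison: fitted to the same
pull data all three produce high R², but only the perpendicular Brenner
correction predicts the parameter-free fall, which is why the fall-phase R²
is the package's model-selection diagnostic.

Amplitude and force are connected by the quadratic law $F = c\,V_\%^2$
(force ∝ pressure², pressure ∝ amplitude). The conversion factor *c* is
fitted through the origin to forces evaluated at a reference height of
$z = 1$ µm from at least two amplitudes. Because *c* varies several-fold
across the field of view, per-bead calibrations are merged into a spatial
map (beads closer than one bead radius, 5 µm, are averaged — the merge rule
is a package choice) that is re-queried as beads drift laterally.

### Numerical choices

* **Integrator.** `deSolve::lsoda` (adaptive; `rtol = 1e-9`,
  `atol = 1e-12`) with dense output on the camera grid (59 Hz default) and a
  root-stop at the surface cutoff; a fixed-step RK4 fallback is available.
  Halving the step changes trajectories by well under 1 nm.
* **Surface cutoff.** $\lambda \to \infty$ at contact, so a configurable
  minimum height $z_\mathrm{min}$ = 10 nm defines "landed"; trajectories are
  clamped and flagged rather than integrated through contact.
* **Optimizer.** Levenberg–Marquardt (`minpack.lm`) on
  $(\log f_0, k_p, \phi_p, z_0)$ with box bounds and multi-start over
  $\phi_p \in \{0.2, 0.8, 1.4\}$ rad, because the sine profile creates
  periodic local minima. The start height $z_0$ is a nuisance parameter: the
  near-wall drag divergence makes the early trajectory far more sensitive to
  $z_0$ than the tracking noise on the first sample suggests, so fixing
  $z_0$ to that sample visibly biases the fit.
* **QC.** Traces with < 0.5 µm total displacement ("stuck bead"), start
  heights above 1 µm (pre-detached), pull-fit R² < 0.95, or non-convergent
  optimizations are rejected with a coded reason, not fitted. Thresholds are
  configurable.
* **Identifiability.** With pull data only, distinct
  $(f_0, k_p, \phi_p)$ triples sharing the same node height can compete when
  noise is present; occasional fits select the wrong branch even though the
  force at the 1 µm reference height (the quantity entering *c*) is much
  more stable. Recovery assertions therefore use medians over seeded
  repetitions.
* **Map lookup.** No triangulation library is assumed: "linear" mode fits a
  plane to the *k* = 12 nearest map points with the design centred at the
  query (exact for affine fields, exact at map points, and degrading
  gracefully to a line fit for collinear neighbourhoods); queries outside
  the convex hull fall back to the nearest neighbour with a warning.
  "nearest" mode is appropriate for discontinuous fields.

## From trajectories to G*(ω)

The multi-oscillation (mOsc) drive superimposes sinusoidal force components
at 0.1, 0.5 and 1.5 Hz on a constant offset. The offset keeps the force
non-negative and the beads seated; the three frequencies span more than a
decade in a single recording. Windows of Δt = 500 s shifted by
Δt_sh = 100 s each contain an integer number of cycles of every component
(50/250/750), which makes single-bin spectral estimation leakage-free.

Per window, force and position are demodulated by **harmonic regression**:
least squares on the basis $\{1, t, \cos\omega_i t, \sin\omega_i t\}$. The
explicit offset-and-drift columns remove slow drift without biasing the
sinusoid coefficients (a plain detrend-then-project estimator is biased at
the 10⁻⁴ level because a linear ramp is not orthogonal to the sinusoids on a
finite grid; the regression form is exact to rounding for noiseless signals,
which the tests assert). The modulus follows as

$$G^*(\omega) = \frac{\tilde F(\omega)}{6\pi R\, f(\theta)\, \tilde z(\omega)},$$

the generalized Stokes–Einstein relation scaled by an immersion correction
$f(\theta)$ for a bead only partially embedded in the cell surface, with
$\theta$ the immersion half-angle obtained from the bead–cell contact-circle
diameter via $\theta = \arcsin(d/2R)$.

**Choice of $f(\theta)$.** The package uses the immersed spherical-cap area
relative to a hemisphere, $f(\theta) = 1 - \cos\theta$: it is monotone,
strictly below 1 for partial immersion, and equals 1 at $\theta = 90°$,
where the half-space problem maps onto the full-space one by symmetry and
the relation must reduce to the bare generalized Stokes–Einstein form (a
unit test pins this limit). This is a geometric interface scaling, not an
exact hydrodynamic solution; any other monotone correction with the same
limits can be substituted through `immersion_correction()`, and — because
the forward simulator and the estimator share the same geometry factor —
parameter-recovery results are independent of the specific form. The
default half-angle is 28.73°, a typical measured mean for beads on an
endothelial monolayer.

Per-bead window estimates are aggregated across beads as mean ± SEM of
G′ and G″; |G| and the loss angle δ are derived from the aggregated
components with first-order error propagation. Retained points must satisfy
passivity (δ ∈ [0, π/2]); violations are flagged invalid and skipped, never
silently deleted. Windows are additionally marked independent
(non-overlapping) or overlapping.

## Fractional viscoelastic models

Two models are fitted to each window's spectrum (t₀ = 1 s throughout):

* **SFE (springpot)** — $G^*(\omega) = \tilde G\,(i\omega t_0)^{\alpha}$,
  fitted *separately* to G′ and G″. Two different apparent exponents signal
  that a single springpot cannot describe the material.
* **GKV (generalized Kelvin–Voigt)** — two springpots in parallel,
  $G^*(\omega) = G_0\big[(i\omega t_0)^{\alpha} + (i\omega t_0)^{\beta}\big]$,
  fitted *jointly* to (G′, G″) by least squares over the concatenated
  vector. With $\beta \approx 0$ the low-frequency branch is a steady-state
  elasticity, giving a Young's modulus $E = 2G_0(1+\nu)$ (ν = 0.5 by
  default). The exponent pair defines a crossover frequency where
  G′ = G″:
  $$\omega_x = \left[\frac{\cos(\pi\beta/2) - \sin(\pi\beta/2)}
  {\sin(\pi\alpha/2) - \cos(\pi\alpha/2)}\right]^{1/(\alpha-\beta)},$$
  defined only when the bracket is positive (fluid-like fast branch,
  solid-like slow branch); the closed form is verified against a bisection
  root-finder to 10⁻⁹ relative in the tests.

Fitting details: residuals are on the linear modulus scale by default
(log-scale residuals are available by option); exponents are box-bounded to
[0, 1] and the springpot symmetry (swapping α and β leaves the model
unchanged) orders α ≥ β after the fit, which enforces the constraint
without a joint bound. SFE fits below R² = 0.9 and GKV fits below R² = 0.7
are flagged (thresholds configurable). Bootstrap uncertainties resample
**beads** with replacement (n_boot = 100, seeded), refit the aggregated
spectrum per resample, and report 2σ of the bootstrap distribution; the
unit is the bead because bead-to-bead variation dominates window-to-window
noise.

## The forward simulator

`gen_calibration_trace()` produces pull/fall cycles by integrating the same
equation of motion the fitter uses, at several amplitudes (the profile
prefactor scales as amplitude squared), plus Gaussian tracking noise.
`gen_spatial_field()` draws a smooth band-limited random conversion-factor
field rescaled to a requested max/min ratio (default 6, typical of real
maps). `gen_mosc_experiment()` synthesizes bead-on-cell responses by linear
response: per drive frequency, displacement amplitude and phase follow from
the ground-truth GKV modulus through the same geometry factor the estimator
uses. All generators are pure functions of (arguments, seed).

Default study conditions mirror a typical monolayer experiment: 15 beads,
3700 s duration, 59 Hz sampling, 20 nm RMS tracking noise, 1 nm/s linear
drift, and 10% lognormal bead-to-bead dispersion of $G_0$
(median-unbiased). The per-component force amplitude (200 pN on a 700 pN
offset) is a package choice — the drive must produce oscillation amplitudes
(~2–9 nm here at kPa moduli) that survive the tracking noise after coherent
averaging, as any workable real experiment does. An optional stiffness
schedule scales $G_0$ over time to emulate a drug treatment and wash-out
(e.g. halving during exposure), which the sliding-window fits resolve with
the expected ≤ (Δt/Δt_sh + 1)-window transition.

What the simulator deliberately omits: Brownian motion during calibration
pulls (noise is purely additive tracking error), lateral acoustic forces,
bead-size/compressibility dispersion, nonlinear or history-dependent cell
mechanics, and any image-formation effects. Passing recovery tests
therefore demonstrates that the estimator inverts the stated forward model
under realistic noise — not that real cells obey that model.

## Problem sizes and determinism

The test-suite study sizes are chosen for completeness per unit time:
noisy calibration recovery uses 10 seeded repetitions (asserted on
medians); the Monte-Carlo GKV recovery uses 100 spectra; the full-pipeline
recovery study uses 20 replicates of 15 beads × 3700 s, the same
configuration `scripts/acceptance.R` reruns from scratch. Every stochastic
path takes an explicit seed, and rerunning the pipeline with the same seed
reproduces artifacts byte for byte.

## Known limitations

* Single-wall drag only: the top cover (~100 µm away) is ignored, which is
  adequate while calibration beads stay within ~20 µm of the bottom.
* The immersion correction is a geometric scaling (see above), and a single
  mean half-angle is used unless per-bead geometry is supplied.
* Frequencies are limited by the camera Nyquist rate; the defaults assume
  59 Hz tracking.
* The generalized Maxwell model is registered but intentionally not
  implemented.
* Crossover frequencies are evaluated per window from that window's
  (α, β); averaging crossover values over windows and evaluating the
  crossover at averaged exponents differ at the ~1% level (Jensen gap).
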