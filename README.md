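# rotorpose

Single-camera 3D pose reconstruction and flow diagnostics for
magnetically levitated blood-pump impellers.

## The problem

A MagLev centrifugal blood pump (CentriMag-class) levitates its
impeller electromagnetically: no shaft, no bearings, and therefore a
rotor that can translate and tilt slightly while it spins. Knowing
that residual motion matters both for validating CFD against particle
image velocimetry (PIV) -- a wobbling rotor perturbs the phase-averaged
flow field -- and as a diagnostic of the levitation itself.

The optical trick this package implements recovers the full 3D pose
from a *single* camera view. Each of the four main blades carries two
counter-angled fluorescent marker channels; where the PIV laser sheet
cuts a channel the camera sees a dot, and the planar distance `d_n`
between a blade's two dots encodes the local height `z_n` at which the
sheet cut that blade. From at least three blades the rotor plane, axis
direction, center and blade angle follow.

The package is aimed at experimentalists and CFD engineers working on
rotary blood pumps (or any small levitated rotor observed through one
window): it provides the forward model, the inverse pipeline, the
motion-mode decomposition, and the phase-averaged field statistics
used to compare PIV with CFD.

## The model in brief

Local (rotor) coordinates map to global ones through

    (X, Y, Z) = OR + R_z(alpha) . R_psi(theta) . (x, y, z)

with `OR` the rotor center, `theta`/`phi` the axis polar angle and
azimuth (`psi = R_Z(phi) Y-hat` the tilt axis), and `alpha` the blade
angle. A channel centerline is `x(z) = x0 + a z`, `y(z) = y0 + b z`;
neglecting the height difference between the two cuts of a blade, the
dot distance obeys

    d_n^2 = (da_n z_n + dx0_n)^2 + (db_n z_n + dy0_n)^2,

solved in closed form for `z_n`. Inner markers are projected down
their channels to blade reference points `P_n` on the rotor plane; the
plane through the `P_n` gives the axis, opposing-pair midpoints give
the center. The default solver refines this closed-form seed by
nonlinear least squares against the exact channel/laser-plane
intersection model (all eight markers, six pose parameters), which on
noiseless data recovers the pose to numerical precision.

A pose time series is then decomposed into three motion modes --
center shift, mean-axis tilt `(theta_mean, phi_mean)`, and synchronous
precession `(theta_prec, phi_prec)` -- by `rotor_motion()`, a fitting
function returning an object with the usual `coef`, `predict`, `plot`,
`simulate` and `residuals` methods.

Alongside: 1-degree phase binning modulo 90 (fourfold blade symmetry),
phase-averaged velocity magnitude `U-bar = |mean(u)|`, normalized
error `E_rel = (U - U_ref) / max(U_ref)` and its RMS in percent,
velocity-magnitude variability `sigma_U`, inlet-referenced pressure
errors in mmHg, an out-of-plane displacement check, Welch spectra
normalized by the rotation frequency with blade-passage /
rotational-harmonic classification, and the scalar flow-regime
formulas (viscosity-temperature model, inlet and pump Reynolds
numbers, turbulence boundary-condition estimates).

## Worked example

Simulate one revolution of the reference study conditions (2350 rpm
imaged at 10 kHz, shift/tilt/precession defaults of
`fixture_centrimag_motion()`), reconstruct every frame from unlabeled
marker coordinates, and decompose the motion:

```r
library(rotorpose)

fx <- fixture_centrimag_motion()
bundle <- synth_marker_tracks(fx$model, fx$geom, fx$plane,
                              n_frames = 255, fps = fx$fps)
rec <- reconstruct_track(bundle$tracks[, c("frame", "X_mm", "Y_mm")],
                         fx$geom, fx$plane,
                         dalpha_hint_deg = 360 * fx$model$rpm / (60 * fx$fps))
fit <- rotor_motion(rec$table, geom = fx$geom, rpm = fx$model$rpm)
fit
#> Three-mode impeller motion fit
#>   1) center shift : (-0.130, +0.040) mm  [sd 0.000 / 0.000 mm, s* = -0.00 mm]
#>   2) mean tilt    : theta = 0.649 deg at azimuth 273.0 deg
#>   3) precession   : theta = 0.450 deg at offset 275.0 deg from blade 1 (sync slope 1.000)
```

The fit reads: the motion center sits 0.13 mm off the housing origin
in `-X`; the mean rotation axis leans 0.65 degrees toward azimuth 273;
on top of that the instantaneous axis precesses 0.45 degrees around
the mean, locked to the rotation (slope 1.000) with the tilt leading
blade 1 by 275 degrees -- the same side of the impeller stays high.
On this noiseless synthetic track the recovered coefficients match the
generating model to numerical precision:

```r
round(coef(fit), 4)
#>    center_X_mm    center_Y_mm theta_mean_deg   phi_mean_deg theta_prec_deg   phi_prec_deg
#>        -0.1300         0.0400         0.6494       272.9991         0.4500       275.0000
```

Scalar diagnostics of the test condition:

```r
mu <- viscosity(24.3)          # blood analog at 24.3 degC
signif(mu, 2)
#> [1] 0.0039                   # Pa.s
round(reynolds_inlet(1164, mu, 4.4, 9.2))    # 4.4 L/min, 9.2 mm inlet
#> [1] 3031
round(reynolds_pump(1164, mu, 2350, 44.9))   # 2350 rpm, 44.9 mm rotor
#> [1] 148174
```

## Layout

- `R/` — geometry and pose transforms, channel geometry, synthetic rig
  (trajectories, projections, frames, fields, signals), marker
  pipeline, pose reconstruction, motion decomposition
  (`rotor_motion`), field statistics, spectral/flow metrics, pipeline
  wrappers (`rig_simulate`, `rig_reconstruct`, `rig_compare`).
- `vignettes/rotor-pose-methods.Rmd` — the models, assumptions,
  numerical choices and limitations, in detail.
- `tests/testthat/` — oracle-based unit and property tests per module
  plus the end-to-end acceptance suite.
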