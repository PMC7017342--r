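---
title: "Steering by beat-symmetry breaking: models, numerics and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steering by beat-symmetry breaking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagsteer)
```

## The model

A uniflagellated sperm cell is morphologically symmetric about its long
axis, so a beat whose curvature satisfies the half-period mirror
condition `C(s, t) = −C(s, t + T/2)` produces no net rotation per beat
cycle: whatever heading change accumulates in the first half-period is
undone in the second. Expanding `C(s, t)` in temporal Fourier modes shows
that the condition kills exactly the even modes — so the only planar
routes to steering are a non-zero time-average curvature `C0` (mode 0, an
arc superimposed on the wave) and even harmonics, of which the second
(`C2`, with phase `φ` relative to the fundamental) is the leading one.
`flagsteer` works with the three prototypical waves built from these
ingredients,

$$C(s,t) = C_0 + C_1\sin(ks-\omega_0 t) + C_2\sin(ks-2\omega_0 t+\varphi),$$

with constant amplitudes along arc length and wavelength equal to the
flagellar length (`k = 2π/L`). Arc-length-dependent amplitude envelopes,
non-planar beats and elastic waveform compliance are out of scope.

Hydrodynamics is resistive-force theory: a local drag density
`f(s) = −[ξ∥ t̂t̂ + ξ⊥(I − t̂t̂)]·u(s)` with a single physical parameter,
the anisotropy ratio `ξ_R = ξ⊥/ξ∥` (the absolute scale cancels from all
kinematics, which the tests assert). The default `ξ_R = 1.81` is the
classic bull-sperm fit; a thin rod in Stokes flow has `ξ_R ≈ 2`. The
model sperm is headless: head drag, wall effects and cell–cell
hydrodynamic interactions are not modelled. At negligible Reynolds number
the cell is force- and torque-free at every instant, so the instantaneous
rigid motion `(U, Ω)` solves a symmetric 3×3 linear system assembled from
the force balance and one torque balance; for a cell tethered at its base
(the pivot stands in for the tethered head, which the headless model
lacks) only the scalar torque balance about the pivot remains.

## Parameters that matter

| parameter | units | default | meaning |
|---|---|---|---|
| `L` | µm | 40 | flagellar length; also the wavelength |
| `C1` | 1/µm | — | fundamental curvature amplitude; rotation scales as `C1²` |
| `C0` | 1/µm | 0 | mean curvature, the rudder |
| `C2`, `φ` | 1/µm, rad | 0, 0 | second harmonic and its phase; steers as `C2 sin φ` (free) |
| `ω0` | rad/s | — | beat frequency; kinematics scale linearly with it |
| `ξ_R` | — | 1.81 | drag anisotropy, the only hydrodynamic parameter |
| `l` | s | 0.25 / 0.5 | spectral window (sea-urchin / human presets) |
| smoothing | s | 0.25 / 0.3 | Gaussian filter size for all parameter series |
| PCA threshold | — | 0.05 | variance fraction below which shape modes are noise |

The steering coefficients recovered at `ξ_R = 1.81` are
`A0 ≈ −0.362`, `A2 ≈ −0.0431` (free) and `B0 ≈ −0.102`, `B2 ≈ 0.081`,
`δ ≈ 0.556π` (tethered). Their signs encode the conventions: angles and
`Ω` are counterclockwise-positive in a y-up lab frame, curvature is the
arc-length derivative of the tangent angle, and with `A0 < 0` a beat with
`C0 > 0` rotates the period-averaged swimming velocity clockwise. Free
swimmers respond roughly ten-fold more strongly to a mean curvature than
to a second harmonic of equal magnitude (`A0/A2 ≈ 8.4`), whereas
tethering makes the two channels comparable (`|B0|/B2 ≈ 1.26`) — one
reason tethered assays overstate the second harmonic's role in free
swimming.

## Numerical choices

**Gauge.** The body frame clamps the base material point (`r(0) = 0`)
and the base tangent (`ψ(0) = 0`). Shapes are realized by cumulative
trapezoidal integration of the tangent angle (`ψ = ∫C ds`,
`r = ∫(cos ψ, sin ψ) ds`) on 101 uniform arc-length nodes by default;
deformation velocities propagate the analytic `∂C/∂t` through the same
construction, so base velocity is zero by the gauge. The free-swimmer
result is gauge-independent after the rigid-motion solve; the tests
assert reference-point invariance of `(U, Ω)`.

**Solver quadrature.** Segment sums with midpoint values (tangents from
chords, positions and velocities averaged to midpoints) assemble the 3×3
system in O(N); balance residuals come out at machine precision and are
checked against 1e−9 at every step. Degenerate shapes (coincident
points, zero rotational drag about the pivot) raise errors.

**Path integration.** The pose ODE is integrated with a midpoint (RK2)
scheme at `dt = T/500` by default (dt coarser than `T/20` warns); an
exact SE(2) exponential-map step (circular-arc update) is available.
Halving `dt` reduces the end-pose error about four-fold, as the tests
check. Period-averaged observables (net rotation rate, path curvature)
insist on integer-period coverage, and path curvature is evaluated on
period-averaged pose samples so the within-beat wobble cancels.

**Coefficient recovery.** For each `ε` of a descending ladder
(0.05, 0.025, 0.0125 in units of `k`) the relevant amplitudes are set to
`εk`, the mean rotation rate over one period (500 uniform time samples —
spectrally accurate for a periodic integrand) is normalized by
`k⁻³C1²C_j`, and the ladder is extrapolated to `ε → 0` by least squares
in `ε²` (the leading corrections are even in the amplitude). A relative
extrapolation residual above 5% is an error, with an absolute floor so a
genuinely vanishing coefficient converges cleanly. The `φ`-dependence of
the tethered rotation rate is fitted with `p sin φ + q cos φ` on a
32-point grid; the amplitude gives `B2`, and `δ = atan2(q, p)` is the
zero crossing with positive slope, which decouples `B2` from `δ`. The
free-mode second harmonic is estimated at `φ = π/2`, where the signal is
maximal. Estimates default to 201 arc-length samples: 100 segments leave
a ≈0.1% spatial bias, visible in the third significant figure of the
`B` factors.

**Schedules.** Time-varying `C0(t)`, `C2(t)`, `φ(t)` (the parameter-sweep
protocols) are applied quasi-statically: the deformation velocity uses
the frozen-parameter time derivative. This is accurate when parameters
change slowly compared with the beat, which is the regime the sweeps and
the synthetic schedules emulate.

## The analysis pipeline

From tracked coordinates to curvature: tracked skeleton points are
approximately equidistant along the flagellum, so each frame is
parameterized by point index, `x(i)` and `y(i)` are smoothed with a cubic
Savitzky–Golay filter (window ≈ one fifth of the point count), arc length
is measured on the smoothed curve, and the curve is resampled to uniform
arc length. Two designs here deserve comment. First, the chord-length
parameter of *noisy* points is useless — at pixel-scale point spacing the
noise inflates chord lengths severalfold — which is why the index
parameterization comes first and arc length is measured only after
smoothing. Second, Savitzky–Golay rather than a cross-validated
smoothing spline: the beat harmonics must pass with unit gain, because
any amplitude attenuation biases `C1`, `C2`, `C0` directly; the SG filter
has a flat passband where a GCV spline attenuated amplitudes by 7–10% in
our validation runs. Curvature then comes from chord angles (exact
`O(h²)` tangent samples at segment midpoints) differenced once; the two
end nodes are filled by quadratic extrapolation, since tracked flagellar
ends are the least reliable part of any skeleton.

The curvature field is denoised by principal components, discarding
eigenmodes below 5% of the total variance — a planar beat needs only a
few shape modes (a travelling wave is two standing modes). Time-resolved
spectral quantities come from a sliding minimum-4-term Blackman–Harris
window (250 ms or 500 ms presets): the largest peak of the
arc-length-averaged power spectrum above `5/l` Hz gives `ω0(t)` (refined
by parabolic interpolation on log power), complex projections at `ω0`
and `2ω0` give amplitudes and phases, and `C2(t)` is the amplitude-
spectrum integral over `2ω0 ± Δω` with `Δω = 1/l`, calibrated against the
window's own response so a pure sinusoid of amplitude `a` reports `a`.
The relative phase `φ(t)` is referenced to the travelling-wave convention
(`sin(ks − nω0t + …)` with `k = 2π/L` from the tracked length) and
averaged over arc length with a circular mean; without this referencing
`φ` would be position-dependent and the scanned `φ_eff` unidentifiable.

Three points the underlying methods leave open were decided as follows,
as explicit stand-ins rather than claims about anyone's intent: the
correlation maximized for `φ_eff` is the Pearson correlation; the
"size" of the Gaussian filter is its full width at half maximum (the
filter truncates at ±4σ and renormalizes at the record edges rather than
padding, so strongly oscillating series are not biased); and the power
spectrum of the curvature is computed per arc-length station and
averaged over stations, chosen for noise robustness. Similarly, the
second-harmonic superposition is implemented in its plain two-wave form;
the equivalent single-wave form with time-dependent amplitude and phase
is not.

## The synthetic generator

`generate_tracked_cell()` emulates a 500-fps dark-field recording: the
rigid motion integrated from the solver (internally substepped so the
step never exceeds `T/200`), lab-frame flagellar points with i.i.d.
isotropic Gaussian positional noise, head position at the flagellar base
and head angle along the base tangent. The default 100 points per frame
matches the roughly pixel-spaced skeletons real trackers emit for a
40 µm flagellum. The ground truth stored alongside is exactly what the
solver produced — the same dynamics, a single source of truth that the
tests exploit.

What the generator does *not* emulate: correlated tracking noise (real
skeleton errors are correlated along the flagellum and in time), frame
drops, length fluctuations from segmentation, head-shape effects on the
orientation estimate, out-of-plane beat components, and beat-frequency
jitter. Passing the recovery tests therefore shows the pipeline is
unbiased and noise-robust under idealized jitter, not that it is immune
to systematic tracking artefacts. The figure-parameter fixtures
(`make_figure_fixtures()`) use a 30 Hz beat and modest schedule ramps;
these two choices are package choices (the dimensionless results do not
depend on them).

## A note on isotropic drag

Drag anisotropy is what couples undulation to *propulsion*: at
`ξ_R = 1` the force balance reduces to `d/dt` of the lab-frame centroid,
which is therefore exactly stationary, and the cell goes nowhere. Net
*rotation*, however, does not vanish at `ξ_R = 1`: reorientation under
isotropic drag is a geometric phase of the shape cycle (the same
mathematics as a falling cat reorienting at zero angular momentum), and
the solver gives a mean-curvature rotation coefficient of about −0.119
there, confirmed by an independent centroid-referenced oracle. The tests
assert this pair of facts — stationary centroid, persistent rotation —
rather than the tempting but wrong "no anisotropy, no turning".

## Problem sizes and limitations

The suite and the acceptance script run at the sizes quoted above: 101
(solver) or 201 (coefficient recovery) arc-length samples, 500 time
steps per period, 2 s synthetic recordings at 500 fps with 100 points
per frame, amplitude ladders down to `C1 k⁻¹ = 0.0125`. The
small-curvature laws are leading-order: at the realistic sweep amplitude
`C1 = 0.05 µm⁻¹` the tethered slopes carry ≈10–15% finite-amplitude
corrections, and by `C1 k⁻¹ ≈ 0.6` the corrections approach a factor of
two — the analytic laws are a guide there, not a fit. The recovered
`B` factors assume the pivot sits exactly at the base of the headless
flagellum; with that assumption the continuum-extrapolated
`B0 = −0.1016` agrees with the published −0.102 at its printed
precision, so no systematic pivot offset is detectable at that
precision. Known limitations beyond scope: no hydrodynamic interactions
or boundaries, no 3D or rolling motion, no elasticity (the beat is
prescribed, not emergent), and raw-image tracking is upstream of this
package — the pipeline starts from coordinates.
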