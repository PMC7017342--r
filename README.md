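# flagsteer

Sperm cells swim at low Reynolds number by propagating a planar bending
wave along the flagellum. A perfectly symmetric wave drives the cell
straight; to *steer*, the cell must break the space–time symmetry of its
beat. `flagsteer` implements the computational machinery for studying the
two symmetry-breaking channels a planar beat offers — a non-zero mean
flagellar curvature (an arc superimposed on the wave, acting as a rudder)
and a second harmonic of the beat — together with the waveform-analysis
pipeline that extracts both steering signals from tracked flagella. It is
aimed at biophysicists modelling flagellar propulsion and at
microscopists analysing high-speed recordings of beating sperm.

## The model

The beat is prescribed as a curvature wave along the arc length
`s ∈ [0, L]`:

    C(s,t) = C0 + C1 sin(ks − ω0 t) + C2 sin(ks − 2 ω0 t + φ),

with wavelength equal to the flagellar length (`k = 2π/L`). Swimming
follows from resistive-force theory: each filament element feels a drag
force `f = −[ξ∥ t̂t̂ + ξ⊥(I − t̂t̂)]·u` with anisotropy ratio
`ξ_R = ξ⊥/ξ∥ ≈ 1.81` (bull-sperm fit), and the instantaneous rigid-body
velocities `(U, Ω)` solve the force- and torque-balance of a force-free
swimmer (or the torque balance about the pivot for a cell tethered at its
base). In the small-curvature limit the beat-averaged rotation rate obeys

    Ω/ω0 = A0 k⁻³ C1² C0 + A2 k⁻³ C1² C2 sin φ        (free swimmer)
    Ω/ω0 = B0 k⁻³ C1² C0 + B2 k⁻³ C1² C2 sin(φ + δ)   (tethered)

and the package recovers the proportionality factors numerically by
small-amplitude extrapolation of the solver (`A0 ≈ −0.36`, `A2 ≈ −0.04`,
`B0 ≈ −0.102`, `B2 ≈ 0.081`, `δ ≈ 0.56π` at `ξ_R = 1.81`). The analysis
half of the package runs the reverse direction: from tracked flagellar
coordinates it computes the curvature field, denoises it by principal
components, extracts time-resolved `ω0(t)`, `C1(t)`, `C2(t)`, `φ(t)` by
short-time Fourier analysis with a Blackman–Harris window, the mean
curvature `C0(t)`, and the rotation velocity `Ω(t)` from the head
orientation, and fits the steering laws.

## Worked example

```r
library(flagsteer)

## the arched beat with a second harmonic (simulation-figure parameters)
k <- 2 * pi / 40
pat <- beat_pattern(C1 = 0.75 * k, omega0 = 2 * pi * 30, L = 40,
                    C0 = -1.5 / 40, C2 = 0.75 * k / 2, phi = pi / 2)
pat
#> Planar flagellar beat pattern
#>   L      = 40 um   (lambda = 40 um, k = 0.15708 1/um)
#>   omega0 = 188.5 rad/s (period 0.033333 s)
#>   C0 = -0.0375, C1 = 0.11781, C2 = 0.058905 1/um;  phi = 1.5708 rad

## steering coefficients recovered from the solver (~3 s)
coeffs <- estimate_coefficients(drag_model(xi_ratio = 1.81), "free")
coeffs
#> Small-curvature steering coefficients
#>   free:     A0 = -0.3623, A2 = -0.04307

## analytic law vs direct numerics for a mildly curved beat
p <- beat_pattern(C1 = 0.05, omega0 = 2 * pi * 30, L = 40, C0 = -0.01)
predict_rotation_free(p, coeffs)   # 0.0023367
mean_rotation_rate(p, "mean")      # 0.0023159

## synthetic 500-fps recording (tethered, 1% positional noise) analysed
## back through the pipeline
g <- generate_tracked_cell(synth_config(pat, mode = "tethered",
                                        duration = 2, noise_sd = 0.4,
                                        seed = 1))
analyze_beat(g$cell, preset = "sea_urchin")
#> Beat spectrum 'synthetic': 55 windows of 0.25 s
#>   median omega0 = 188.6 rad/s (30 Hz), C1 = 0.1191, C2 = 0.06063 1/um
```

The recovered `C1`, `C2` and beat frequency match the generating pattern
to a few percent despite 0.4 µm tracking noise on every point. A negative
`A0` with the counterclockwise-positive angle convention means a beat
with `C0 > 0` turns the swimming velocity clockwise.

A command-line front end over the same functions ships in
`inst/cli/flagsteer.R` with subcommands `simulate`, `coeffs`, `synth` and
`analyze`.

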