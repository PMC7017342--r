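Package: flagsteer
Title: Flagellar Beat Patterns, Resistive-Force-Theory Swimming and
    Steering Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how sperm cells steer by breaking the
    symmetry of their flagellar beat. Provides prototypical planar
    curvature waves (travelling wave, mean-curvature arc, second
    harmonic), a resistive-force-theory solver for force-free and
    head-tethered swimming of a slender flagellum, rigid-body path
    integration, numerical recovery of the small-curvature steering
    coefficients, a waveform-analysis pipeline that extracts mean
    curvature and second-harmonic steering signals from tracked
    flagella via short-time Fourier analysis, and a synthetic
    tracked-cell generator for validating the pipeline by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
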