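# Shared fixtures, built lazily and cached for the whole run.

.fx <- new.env(parent = emptyenv())

# the arched-plus-second-harmonic beat of the simulation figures
fig2_pattern <- function(omega0 = 2 * pi * 30) {
  k <- 2 * pi / 40
  beat_pattern(C1 = 0.75 * k, omega0 = omega0, L = 40, C0 = -1.5 / 40,
               C2 = 0.75 * k / 2, phi = pi / 2)
}

# small-amplitude pattern for solver asymptotics
small_pattern <- function(eps = 0.0125, C0 = 0, C2 = 0, phi = 0, L = 40) {
  k <- 2 * pi / L
  beat_pattern(C1 = eps * k, omega0 = 2 * pi, L = L, C0 = C0, C2 = C2,
               phi = phi)
}

cached <- function(key, fn) {
  if (is.null(.fx[[key]])) .fx[[key]] <- fn()
  .fx[[key]]
}

free_coeffs <- function() {
  cached("free_coeffs", function()
    estimate_coefficients(drag_model(), "free"))
}

tethered_coeffs <- function() {
  cached("tethered_coeffs", function()
    estimate_coefficients(drag_model(), "tethered"))
}

# noise-free tethered recording of the figure beat, short
tethered_cell_clean <- function() {
  cached("tethered_cell_clean", function()
    generate_tracked_cell(synth_config(fig2_pattern(), mode = "tethered",
                                       duration = 0.6, noise_sd = 0,
                                       seed = 101, cell_id = "clean")))
}
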