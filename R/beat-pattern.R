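#' Prototypical planar flagellar beat pattern
#'
#' A `beat_pattern` collects the parameters of the prototypical planar
#' curvature waves used throughout the package,
#' \deqn{C(s,t) = C_0 + C_1 \sin(ks - \omega_0 t) + C_2 \sin(ks - 2\omega_0 t + \phi),}
#' where `s` is the arc-length coordinate along the flagellum and `t` is
#' time. The fundamental travelling wave (amplitude `C1`) propels the cell;
#' a non-zero mean curvature `C0` or a second harmonic (`C2`, phase `phi`)
#' breaks the beat symmetry and steers it. By default the wavelength equals
#' the flagellar length, i.e. `k = 2*pi/L`.
#'
#' @param C1 fundamental curvature amplitude (1/micron).
#' @param omega0 angular beat frequency (rad/s).
#' @param L flagellar length (micron).
#' @param C0 mean (intrinsic) curvature (1/micron). Default 0.
#' @param C2 second-harmonic curvature amplitude (1/micron). Default 0.
#' @param phi phase of the second harmonic relative to the fundamental (rad).
#' @param k wavenumber (1/micron); defaults to `2*pi/L` (wavelength = length).
#'
#' @return An object of class `beat_pattern`: a list with elements
#'   `C0, C1, C2, phi, k, omega0, L` and derived `lambda = 2*pi/k`,
#'   `period = 2*pi/omega0`.
#' @examples
#' p <- beat_pattern(C1 = 0.75 * 2 * pi / 40, omega0 = 2 * pi * 30, L = 40,
#'                   C0 = -1.5 / 40)
#' eval_curvature(p, "mean", s = 10, t = 0)
#' @export
beat_pattern <- function(C1, omega0, L, C0 = 0, C2 = 0, phi = 0, k = NULL) {
  if (!is.numeric(L) || length(L) != 1 || !is.finite(L) || L <= 0)
    stop_domain("`L` must be a positive finite scalar")
  if (!is.numeric(omega0) || length(omega0) != 1 || !is.finite(omega0) ||
      omega0 <= 0)
    stop_domain("`omega0` must be a positive finite scalar")
  k <- k %||% (2 * pi / L)
  if (!is.finite(k) || k <= 0) stop_domain("`k` must be positive and finite")
  amps <- c(C0 = C0, C1 = C1, C2 = C2, phi = phi)
  if (!all(is.finite(amps))) stop_domain("amplitudes and phase must be finite")
  structure(
    list(C0 = C0, C1 = C1, C2 = C2, phi = phi, k = k, omega0 = omega0,
         L = L, lambda = 2 * pi / k, period = 2 * pi / omega0),
    class = "beat_pattern"
  )
}

#' @export
print.beat_pattern <- function(x, ...) {
  cat("Planar flagellar beat pattern\n")
  cat(sprintf("  L      = %g um   (lambda = %g um, k = %.5g 1/um)\n",
              x$L, x$lambda, x$k))
  cat(sprintf("  omega0 = %.5g rad/s (period %.5g s)\n", x$omega0, x$period))
  cat(sprintf("  C0 = %.5g, C1 = %.5g, C2 = %.5g 1/um;  phi = %.5g rad\n",
              x$C0, x$C1, x$C2, x$phi))
  invisible(x)
}

.variants <- c("sine", "mean", "second_harmonic", "full")

.check_variant <- function(variant) {
  match.arg(variant, .variants)
}

#' Evaluate a prototypical curvature wave
#'
#' Evaluates the flagellar curvature `C(s, t)` of a [beat_pattern()] at
#' arc-length position(s) `s` and time(s) `t`. The `variant` selects which
#' terms enter: `"sine"` is the pure travelling wave
#' `C1*sin(k*s - omega0*t)`; `"mean"` adds the mean curvature `C0`;
#' `"second_harmonic"` adds instead the second harmonic
#' `C2*sin(k*s - 2*omega0*t + phi)`; `"full"` includes all three terms.
#'
#' @param pattern a [beat_pattern()].
#' @param variant one of `"sine"`, `"mean"`, `"second_harmonic"`, `"full"`.
#' @param s arc length (micron), must lie in `[0, L]`.
#' @param t time (s). `s` and `t` are recycled against each other.
#' @return curvature values (1/micron).
#' @export
eval_curvature <- function(pattern, variant, s, t) {
  variant <- .check_variant(variant)
  if (any(s < 0 | s > pattern$L))
    stop_domain("arc length `s` outside [0, L]")
  out <- pattern$C1 * sin(pattern$k * s - pattern$omega0 * t)
  if (variant %in% c("mean", "full")) out <- out + pattern$C0
  if (variant %in% c("second_harmonic", "full"))
    out <- out + pattern$C2 * sin(pattern$k * s - 2 * pattern$omega0 * t +
                                    pattern$phi)
  out
}

#' Time derivative of a prototypical curvature wave
#'
#' Analytic partial derivative of [eval_curvature()] with respect to time,
#' used to build the deformation velocity of material points.
#'
#' @inheritParams eval_curvature
#' @return `dC/dt` values (1/(micron s)).
#' @export
curvature_rate <- function(pattern, variant, s, t) {
  variant <- .check_variant(variant)
  if (any(s < 0 | s > pattern$L))
    stop_domain("arc length `s` outside [0, L]")
  out <- -pattern$omega0 * pattern$C1 *
    cos(pattern$k * s - pattern$omega0 * t)
  if (variant %in% c("second_harmonic", "full"))
    out <- out - 2 * pattern$omega0 * pattern$C2 *
      cos(pattern$k * s - 2 * pattern$omega0 * t + pattern$phi)
  out
}

#' Read a beat-pattern configuration file
#'
#' Reads a YAML configuration declaring a beat pattern. Recognized keys:
#' `C0`, `C1`, `C2`, `phi`, `k` (optional, defaults to `2*pi/L`), `omega0`,
#' `L`, `variant`.
#'
#' @param path path to a YAML file.
#' @return list with elements `pattern` (a [beat_pattern()]) and `variant`.
#' @export
read_beat_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("C1", "omega0", "L")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop_domain("config missing required keys: ", paste(miss, collapse = ", "))
  pat <- beat_pattern(C1 = cfg$C1, omega0 = cfg$omega0, L = cfg$L,
                      C0 = cfg$C0 %||% 0, C2 = cfg$C2 %||% 0,
                      phi = cfg$phi %||% 0, k = cfg$k)
  list(pattern = pat, variant = .check_variant(cfg$variant %||% "full"))
}
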