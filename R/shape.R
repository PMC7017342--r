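#' Geometric realization of a curvature profile
#'
#' Builds the planar flagellar shape from a curvature profile by the
#' tangent-angle construction: `psi(s) = integral of C ds'` and
#' `r(s) = integral of (cos psi, sin psi) ds'` (cumulative trapezoids), in
#' the body-frame gauge `r(0) = (0,0)`, `psi(0) = 0` that clamps the base
#' material point and base tangent. The arc-length parameterization makes
#' the curve inextensible by construction.
#'
#' @param s_grid arc-length samples (micron).
#' @param curvature curvature values at `s_grid` (1/micron).
#' @return An object of class `flagellar_shape`: list with `s_grid`, the
#'   tangent angle `psi` (rad), and `points`, an `n x 2` matrix of body-frame
#'   coordinates (micron).
#' @export
flagellar_shape <- function(s_grid, curvature) {
  if (length(s_grid) != length(curvature))
    stop_domain("`s_grid` and `curvature` lengths differ")
  psi <- cumtrapz1(s_grid, curvature)
  x <- cumtrapz1(s_grid, cos(psi))
  y <- cumtrapz1(s_grid, sin(psi))
  structure(list(s_grid = as.numeric(s_grid), psi = psi,
                 points = cbind(x = x, y = y)),
            class = "flagellar_shape")
}

#' @export
print.flagellar_shape <- function(x, ...) {
  cat(sprintf("Flagellar shape: %d points, arc length %.4g um\n",
              length(x$s_grid), max(x$s_grid) - min(x$s_grid)))
  invisible(x)
}

#' Shape at one time slice of a curvature field
#'
#' Realizes the flagellar shape for a single frame of a discretized
#' curvature field via [flagellar_shape()].
#'
#' @param field a [curvature_field()].
#' @param t_index frame index into `field$t_grid`.
#' @return a [flagellar_shape()].
#' @export
shape_from_curvature <- function(field, t_index) {
  if (t_index < 1 || t_index > nrow(field$values))
    stop_domain("`t_index` out of range")
  flagellar_shape(field$s_grid, field$values[t_index, ])
}

#' Deformation velocity of the beating flagellum
#'
#' Velocity of each material point in the body-frame gauge, obtained by
#' propagating the analytic curvature rate `dC/dt` through the tangent-angle
#' construction: `dpsi/dt = integral of dC/dt ds'`,
#' `dr/dt = integral of dpsi/dt * (-sin psi, cos psi) ds'`. The base point
#' has zero velocity by the gauge choice. This is the actuation velocity
#' that enters the resistive-force-theory drag density.
#'
#' @inheritParams eval_curvature
#' @param s_grid arc-length samples (micron).
#' @return `n x 2` matrix of body-frame velocities (micron/s).
#' @export
deformation_velocity <- function(pattern, variant, t, s_grid) {
  C <- eval_curvature(pattern, variant, s_grid, t)
  psi <- cumtrapz1(s_grid, C)
  dpsi <- cumtrapz1(s_grid, curvature_rate(pattern, variant, s_grid, t))
  vx <- cumtrapz1(s_grid, -dpsi * sin(psi))
  vy <- cumtrapz1(s_grid, dpsi * cos(psi))
  cbind(x = vx, y = vy)
}

# shape + deformation velocity for a pattern at time t (single construction
# shared by the solvers; psi computed once)
.shape_and_velocity <- function(pattern, variant, t, s_grid) {
  C <- eval_curvature(pattern, variant, s_grid, t)
  psi <- cumtrapz1(s_grid, C)
  x <- cumtrapz1(s_grid, cos(psi))
  y <- cumtrapz1(s_grid, sin(psi))
  dpsi <- cumtrapz1(s_grid, curvature_rate(pattern, variant, s_grid, t))
  vx <- cumtrapz1(s_grid, -dpsi * sin(psi))
  vy <- cumtrapz1(s_grid, dpsi * cos(psi))
  shape <- structure(list(s_grid = s_grid, psi = psi,
                          points = cbind(x = x, y = y)),
                     class = "flagellar_shape")
  list(shape = shape, defvel = cbind(x = vx, y = vy))
}
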