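#' Anisotropic drag model of a slender flagellum
#'
#' Resistive-force theory assigns each filament element a drag force linear
#' in its velocity, with distinct coefficients for tangential and normal
#' motion. Only the anisotropy ratio `xi_ratio = xi_perp / xi_par` affects
#' force-free kinematics; the absolute scale `xi_par` cancels. The default
#' ratio 1.81 is the value fitted for bull sperm and used for all
#' quantitative estimates here; an isotropic fluid (`xi_ratio = 1`) produces
#' neither propulsion nor net rotation.
#'
#' @param xi_par tangential drag coefficient per unit length (arbitrary
#'   units, default 1).
#' @param xi_ratio drag anisotropy ratio `xi_perp / xi_par` (default 1.81).
#' @return An object of class `drag_model`.
#' @export
drag_model <- function(xi_par = 1, xi_ratio = 1.81) {
  if (!is.finite(xi_par) || xi_par <= 0)
    stop_domain("`xi_par` must be positive")
  if (!is.finite(xi_ratio) || xi_ratio <= 0)
    stop_domain("`xi_ratio` must be positive")
  structure(list(xi_par = xi_par, xi_perp = xi_par * xi_ratio,
                 xi_ratio = xi_ratio),
            class = "drag_model")
}

#' @export
print.drag_model <- function(x, ...) {
  cat(sprintf("RFT drag model: xi_par = %g, xi_perp = %g (ratio %.4g)\n",
              x$xi_par, x$xi_perp, x$xi_ratio))
  invisible(x)
}

#' Resistive-force drag density along the flagellum
#'
#' Local drag force per unit length at each point of the shape,
#' `f(s) = -[xi_par t t' + xi_perp (I - t t')] u(s)`, where `t` is the unit
#' tangent and `u` the local velocity. Tangential motion is resisted by
#' `xi_par`, normal motion by `xi_perp`; the anisotropy is what couples
#' undulation to propulsion.
#'
#' @param shape a [flagellar_shape()].
#' @param velocities `n x 2` matrix of point velocities on the shape's grid
#'   (micron/s).
#' @param drag a [drag_model()].
#' @return `n x 2` matrix of force per unit length.
#' @export
force_density <- function(shape, velocities, drag = drag_model()) {
  velocities <- as.matrix(velocities)
  if (nrow(velocities) != length(shape$s_grid) || ncol(velocities) != 2)
    stop_domain("`velocities` must be n x 2 on the shape's grid")
  tx <- cos(shape$psi)
  ty <- sin(shape$psi)
  ut <- velocities[, 1] * tx + velocities[, 2] * ty
  fx <- -(drag$xi_perp * velocities[, 1] +
            (drag$xi_par - drag$xi_perp) * ut * tx)
  fy <- -(drag$xi_perp * velocities[, 2] +
            (drag$xi_par - drag$xi_perp) * ut * ty)
  cbind(x = fx, y = fy)
}

#' Instantaneous rigid motion of the body frame
#'
#' Holds the translational velocity of the body-frame origin and the angular
#' velocity about the out-of-plane axis (counterclockwise positive). For a
#' tethered solve `U` is identically zero.
#'
#' @param U length-2 translational velocity (micron/s).
#' @param Omega scalar angular velocity (rad/s).
#' @return An object of class `rigid_motion`.
#' @export
rigid_motion <- function(U, Omega) {
  if (length(U) != 2 || !all(is.finite(U)) || !is.finite(Omega))
    stop_domain("rigid motion must be finite, U of length 2")
  structure(list(U = as.numeric(U), Omega = as.numeric(Omega)),
            class = "rigid_motion")
}

#' @export
print.rigid_motion <- function(x, ...) {
  cat(sprintf("Rigid motion: U = (%.5g, %.5g) um/s, Omega = %.5g rad/s\n",
              x$U[1], x$U[2], x$Omega))
  invisible(x)
}

# Midpoint-rule assembly shared by both solvers. Returns segment midpoint
# positions, drag tensor components, midpoint velocities and lengths.
.segment_data <- function(shape, defvel, drag) {
  pts <- shape$points
  n <- nrow(pts)
  if (n < 3) stop_domain("shape needs at least 3 points")
  dx <- diff(pts[, 1]); dy <- diff(pts[, 2])
  len <- sqrt(dx^2 + dy^2)
  if (any(len == 0)) stop_domain("degenerate shape: coincident points")
  tx <- dx / len; ty <- dy / len
  ds <- diff(shape$s_grid)
  mid <- function(z) (z[-1] + z[-n]) / 2
  dxi <- drag$xi_par - drag$xi_perp
  list(
    mx = mid(pts[, 1]), my = mid(pts[, 2]),
    vx = mid(defvel[, 1]), vy = mid(defvel[, 2]),
    ds = ds,
    # drag tensor Xi = xi_par t t' + xi_perp (I - t t') per segment
    Xxx = drag$xi_perp + dxi * tx * tx,
    Xxy = dxi * tx * ty,
    Xyy = drag$xi_perp + dxi * ty * ty
  )
}

#' Force- and torque-free swimming solve
#'
#' Finds the instantaneous rigid-body motion `(U, Omega)` of a free swimmer
#' with prescribed deformation: at low Reynolds number inertia is
#' negligible, so the total resistive-force-theory drag force and torque
#' must vanish at every instant. With the point velocity
#' `u(s) = U + Omega z x (r - r0) + defvel(s)`, the two force-balance
#' components and the torque balance about `r0` form a symmetric 3x3 linear
#' system in `(Ux, Uy, Omega)`. The solution is independent of the reference
#' point `r0`: `Omega` is identical, and `U` (the velocity of the frame
#' origin) is unchanged because the balance conditions themselves do not
#' depend on `r0`.
#'
#' @param shape a [flagellar_shape()].
#' @param defvel `n x 2` deformation velocities on the shape's grid
#'   (micron/s), e.g. from [deformation_velocity()].
#' @param drag a [drag_model()].
#' @param ref_point reference point for the torque balance (body frame,
#'   default the origin).
#' @return a [rigid_motion()], with attributes `residual_force` and
#'   `residual_torque` (the achieved balance residuals).
#' @export
solve_free <- function(shape, defvel, drag = drag_model(),
                       ref_point = c(0, 0)) {
  defvel <- as.matrix(defvel)
  if (nrow(defvel) != length(shape$s_grid))
    stop_domain("`defvel` grid does not match the shape")
  sd_ <- .segment_data(shape, defvel, drag)
  px <- -(sd_$my - ref_point[2])
  py <- sd_$mx - ref_point[1]
  ds <- sd_$ds
  Xp_x <- sd_$Xxx * px + sd_$Xxy * py
  Xp_y <- sd_$Xxy * px + sd_$Xyy * py
  Xv_x <- sd_$Xxx * sd_$vx + sd_$Xxy * sd_$vy
  Xv_y <- sd_$Xxy * sd_$vx + sd_$Xyy * sd_$vy
  A <- matrix(0, 3, 3)
  A[1, 1] <- sum(ds * sd_$Xxx)
  A[1, 2] <- A[2, 1] <- sum(ds * sd_$Xxy)
  A[2, 2] <- sum(ds * sd_$Xyy)
  A[1, 3] <- A[3, 1] <- sum(ds * Xp_x)
  A[2, 3] <- A[3, 2] <- sum(ds * Xp_y)
  A[3, 3] <- sum(ds * (px * Xp_x + py * Xp_y))
  b <- -c(sum(ds * Xv_x), sum(ds * Xv_y),
          sum(ds * (px * Xv_x + py * Xv_y)))
  sol <- tryCatch(solve(A, b),
                  error = function(e) stop_domain(
                    "singular force/torque system (degenerate shape)"))
  # the solved translational unknown is the velocity of the reference
  # point; convert to the velocity of the body-frame origin
  U0 <- sol[1:2] + sol[3] * c(ref_point[2], -ref_point[1])
  mot <- rigid_motion(U0, sol[3])
  res <- A %*% sol - b
  attr(mot, "residual_force") <- max(abs(res[1:2]))
  attr(mot, "residual_torque") <- abs(res[3])
  mot
}

#' Tethered (pivoting) solve
#'
#' Rigid rotation rate of a cell tethered at a pivot point and free only to
#' rotate about it: the translational velocity is zero and the single
#' unknown `Omega` solves the torque balance about the pivot, with
#' `u(s) = Omega z x (r - pivot) + defvel(s)`. This mimics the tethered
#' assay in which the head is fixed to the chamber wall; in the headless
#' model the pivot defaults to the flagellar base point.
#'
#' @inheritParams solve_free
#' @param pivot body-frame pivot point (default the base, `c(0, 0)`).
#' @return a [rigid_motion()] with `U = c(0, 0)` and attribute
#'   `residual_torque`.
#' @export
solve_tethered <- function(shape, defvel, drag = drag_model(),
                           pivot = c(0, 0)) {
  defvel <- as.matrix(defvel)
  if (nrow(defvel) != length(shape$s_grid))
    stop_domain("`defvel` grid does not match the shape")
  sd_ <- .segment_data(shape, defvel, drag)
  px <- -(sd_$my - pivot[2])
  py <- sd_$mx - pivot[1]
  ds <- sd_$ds
  den <- sum(ds * (px * (sd_$Xxx * px + sd_$Xxy * py) +
                     py * (sd_$Xxy * px + sd_$Xyy * py)))
  if (den <= 0 || !is.finite(den))
    stop_domain("zero rotational drag about the pivot (degenerate shape)")
  num <- -sum(ds * (px * (sd_$Xxx * sd_$vx + sd_$Xxy * sd_$vy) +
                      py * (sd_$Xxy * sd_$vx + sd_$Xyy * sd_$vy)))
  mot <- rigid_motion(c(0, 0), num / den)
  attr(mot, "residual_torque") <- abs(den * mot$Omega - num)
  mot
}

# instantaneous rigid motion for a pattern at time t (solver front-end used
# by kinematics and asymptotics)
.instantaneous_motion <- function(pattern, variant, t, s_grid, drag,
                                  mode = c("free", "tethered"),
                                  pivot = c(0, 0)) {
  mode <- match.arg(mode)
  sv <- .shape_and_velocity(pattern, variant, t, s_grid)
  if (mode == "free") solve_free(sv$shape, sv$defvel, drag)
  else solve_tethered(sv$shape, sv$defvel, drag, pivot)
}

#' Beat-cycle-averaged rotation rate
#'
#' Mean instantaneous rotation rate over one beat period, normalized by the
#' beat frequency: the dimensionless steering observable `Omega/omega0`.
#' Because the instantaneous solve depends only on the body-frame shape and
#' deformation (not on the pose), the average is taken directly over a
#' uniform time grid spanning one period.
#'
#' @inheritParams eval_curvature
#' @param drag a [drag_model()].
#' @param mode `"free"` (force- and torque-free) or `"tethered"` (pivot at
#'   the base).
#' @param n_s arc-length samples (default 101).
#' @param n_t time samples per period (default 500).
#' @return scalar `Omega / omega0` (dimensionless).
#' @export
mean_rotation_rate <- function(pattern, variant = "full",
                               drag = drag_model(),
                               mode = c("free", "tethered"),
                               n_s = 101, n_t = 500) {
  mode <- match.arg(mode)
  s <- seq(0, pattern$L, length.out = n_s)
  ts <- (seq_len(n_t) - 1) * pattern$period / n_t
  om <- vapply(ts, function(t)
    .instantaneous_motion(pattern, variant, t, s, drag, mode)$Omega, 0)
  mean(om) / pattern$omega0
}
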