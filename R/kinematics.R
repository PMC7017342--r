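#' Swimming-path integration of the body frame
#'
#' Advances the lab-frame pose (position of the body-frame origin and its
#' orientation angle, counterclockwise positive) by integrating the
#' instantaneous rigid motions returned by the resistive-force-theory
#' solver. Because at low Reynolds number the velocities follow the beat
#' instantaneously, the body-frame velocities depend only on time (through
#' the beat phase and any parameter schedule), never on the pose; the pose
#' ODE is integrated with a midpoint (RK2) scheme, or with the exact SE(2)
#' exponential-map step (circular-arc update) if requested.
#'
#' Parameter schedules emulate slow modulation of the steering parameters
#' (as in chemotactic steering): entries of `schedule` named `C0`, `C2` or
#' `phi` override the corresponding pattern parameter as a function of time.
#' Each entry is either a function of time or a two-column object
#' (time, value) that is linearly interpolated. Schedules are treated
#' quasi-statically: the deformation velocity uses the frozen-parameter
#' analytic time derivative.
#'
#' @inheritParams mean_rotation_rate
#' @param duration total integration time (s); for period-averaged
#'   observables use an integer number of beat periods.
#' @param dt time step (s), default `pattern$period / 500`. Steps coarser
#'   than `period/20` trigger a warning; `dt > period/100` is inaccurate.
#' @param schedule optional named list of time-varying overrides for
#'   `C0`, `C2`, `phi` (see Details).
#' @param pivot pivot point for `mode = "tethered"` (body frame).
#' @param method `"rk2"` (midpoint, default) or `"exact"` (exponential map).
#' @param theta0,origin0 initial orientation (rad) and position (micron).
#' @return An object of class `swim_path`: a data frame with columns
#'   `t, x, y, theta, omega` (pose and instantaneous rotation rate at the
#'   sample times), with the beat period and `omega0` stored as attributes.
#' @examples
#' p <- beat_pattern(C1 = 0.05, omega0 = 2 * pi, L = 40, C0 = -0.0375)
#' path <- integrate_path(p, "mean", duration = 2 * p$period,
#'                        dt = p$period / 200)
#' net_rotation_rate(path, 2)
#' @export
integrate_path <- function(pattern, variant = "full", drag = drag_model(),
                           mode = c("free", "tethered"), duration,
                           dt = pattern$period / 500, schedule = NULL,
                           pivot = c(0, 0), method = c("rk2", "exact"),
                           theta0 = 0, origin0 = c(0, 0), n_s = 101) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  variant <- .check_variant(variant)
  if (dt > pattern$period / 20)
    warning("time step coarser than period/20; results will be inaccurate")
  sched <- .compile_schedule(schedule)
  s_grid <- seq(0, pattern$L, length.out = n_s)
  n_steps <- max(1L, round(duration / dt))
  tgrid <- (0:n_steps) * dt

  pat_at <- function(t) {
    if (is.null(sched)) return(pattern)
    p <- pattern
    for (key in names(sched)) p[[key]] <- sched[[key]](t)
    p
  }
  motion_at <- function(t)
    .instantaneous_motion(pat_at(t), variant, t, s_grid, drag, mode, pivot)

  x <- y <- theta <- omega <- numeric(n_steps + 1)
  x[1] <- origin0[1]; y[1] <- origin0[2]; theta[1] <- theta0
  m0 <- motion_at(0)
  omega[1] <- m0$Omega
  for (i in seq_len(n_steps)) {
    tm <- tgrid[i] + dt / 2
    mm <- motion_at(tm)
    th <- theta[i]
    if (method == "rk2") {
      th_mid <- th + mm$Omega * dt / 2
      dx <- cos(th_mid) * mm$U[1] - sin(th_mid) * mm$U[2]
      dy <- sin(th_mid) * mm$U[1] + cos(th_mid) * mm$U[2]
      x[i + 1] <- x[i] + dx * dt
      y[i + 1] <- y[i] + dy * dt
    } else {
      a <- mm$Omega * dt
      if (abs(a) < 1e-12) { s1 <- dt; s2 <- 0 } else {
        s1 <- sin(a) / mm$Omega
        s2 <- (1 - cos(a)) / mm$Omega
      }
      bx <- s1 * mm$U[1] - s2 * mm$U[2]
      by <- s2 * mm$U[1] + s1 * mm$U[2]
      x[i + 1] <- x[i] + cos(th) * bx - sin(th) * by
      y[i + 1] <- y[i] + sin(th) * bx + cos(th) * by
    }
    theta[i + 1] <- th + mm$Omega * dt
    omega[i + 1] <- motion_at(tgrid[i + 1])$Omega
  }
  out <- data.frame(t = tgrid, x = x, y = y, theta = theta, omega = omega)
  class(out) <- c("swim_path", "data.frame")
  attr(out, "period") <- pattern$period
  attr(out, "omega0") <- pattern$omega0
  out
}

# normalize a schedule to named list of functions of t
.compile_schedule <- function(schedule) {
  if (is.null(schedule)) return(NULL)
  ok <- c("C0", "C2", "phi")
  bad <- setdiff(names(schedule), ok)
  if (length(bad) || is.null(names(schedule)))
    stop_domain("invalid schedule keys: ",
                paste(bad %||% "<unnamed>", collapse = ", "),
                " (allowed: C0, C2, phi)")
  lapply(schedule, function(el) {
    if (is.function(el)) return(el)
    el <- as.data.frame(el)
    if (ncol(el) < 2) stop_domain("schedule tables need (time, value)")
    stats::approxfun(el[[1]], el[[2]], rule = 2)
  })
}

#' Net rotation rate of a swimming path
#'
#' Beat-cycle-averaged heading change, normalized by the beat frequency:
#' `(theta(t0 + n*T) - theta(t0)) / (n * T * omega0)`. Symmetric beats give
#' zero; the small-curvature steering laws predict the value from the beat
#' parameters.
#'
#' @param path a [integrate_path()] result.
#' @param n_periods number of beat periods to average over (from the start
#'   of the path). The path must cover them with an integer number of steps.
#' @return dimensionless net rotation rate `Omega_bar / omega0`.
#' @export
net_rotation_rate <- function(path, n_periods) {
  if (n_periods <= 0 || abs(n_periods - round(n_periods)) > 1e-9)
    stop_domain("`n_periods` must be a positive integer number of periods")
  T0 <- attr(path, "period")
  w0 <- attr(path, "omega0")
  dt <- path$t[2] - path$t[1]
  span <- n_periods * T0
  m <- span / dt
  if (abs(m - round(m)) > 1e-6)
    stop_domain("path does not sample an integer number of periods")
  m <- round(m)
  if (m + 1 > nrow(path))
    stop_domain("path covers fewer than ", n_periods, " periods")
  (path$theta[m + 1] - path$theta[1]) / (span * w0)
}

#' Mean curvature of the swimming path
#'
#' Signed path curvature `kappa = Omega_bar / |mean speed|` evaluated on
#' period-averaged pose samples, so that the within-beat wobble of the
#' trajectory does not contaminate the estimate. Positive values curve the
#' path counterclockwise.
#'
#' @param path a [integrate_path()] result covering at least 2 full beat
#'   periods.
#' @return path curvature (1/micron).
#' @export
mean_path_curvature <- function(path) {
  T0 <- attr(path, "period")
  dt <- path$t[2] - path$t[1]
  m <- T0 / dt
  if (abs(m - round(m)) > 1e-6)
    stop_domain("path time step does not divide the beat period")
  m <- round(m)
  n_per <- (nrow(path) - 1) %/% m
  if (n_per < 2) stop_domain("need at least 2 full periods")
  idx <- seq_len(n_per * m)
  per <- rep(seq_len(n_per), each = m)
  cx <- tapply(path$x[idx], per, mean)
  cy <- tapply(path$y[idx], per, mean)
  speed <- mean(sqrt(diff(cx)^2 + diff(cy)^2)) / T0
  if (speed < .Machine$double.eps^0.5)
    stop_domain("mean speed is zero; path curvature undefined")
  omega_bar <- (path$theta[n_per * m + 1] - path$theta[1]) / (n_per * T0)
  omega_bar / speed
}

#' Summarize a swimming path
#'
#' Period-averaged speed, net rotation rate and path curvature.
#'
#' @param object a `swim_path`.
#' @param ... unused.
#' @return list with `mean_speed` (micron/s), `net_rotation_rate`
#'   (dimensionless) and `path_curvature` (1/micron, `NA` for a tethered or
#'   non-translating path).
#' @export
summary.swim_path <- function(object, ...) {
  T0 <- attr(object, "period")
  dt <- object$t[2] - object$t[1]
  n_per <- floor(((nrow(object) - 1) * dt) / T0 + 1e-9)
  nrr <- net_rotation_rate(object, n_per)
  kap <- tryCatch(mean_path_curvature(object), error = function(e) NA_real_)
  m <- round(n_per * T0 / dt)
  disp <- c(object$x[m + 1] - object$x[1], object$y[m + 1] - object$y[1])
  list(mean_speed = sqrt(sum(disp^2)) / (n_per * T0),
       net_rotation_rate = nrr, path_curvature = kap)
}
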