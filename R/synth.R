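#' Configuration for the synthetic tracked-cell generator
#'
#' Describes a synthetic video-tracking experiment: a prescribed beat
#' pattern drives the resistive-force-theory engine, the resulting shapes
#' are sampled at the camera frame rate as lab-frame point sets with
#' additive Gaussian positional noise, emulating dark-field recordings of
#' free-swimming or head-tethered sperm at 500 frames per second.
#'
#' @param pattern a [beat_pattern()].
#' @param mode `"free"` or `"tethered"`.
#' @param duration recording length (s).
#' @param schedule optional time-varying overrides of `C0`, `C2`, `phi`
#'   (see [integrate_path()]).
#' @param frame_rate frames per second (default 500); must exceed four
#'   times the beat frequency.
#' @param noise_sd isotropic Gaussian positional noise per point per frame
#'   (micron, default 0).
#' @param n_points flagellar points per frame (default 100, matching the
#'   roughly pixel-spaced skeletons that video tracking produces for a
#'   40 micron flagellum).
#' @param seed integer seed; the same seed gives bit-identical output.
#' @param cell_id identifier.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(pattern, mode = c("free", "tethered"), duration,
                         schedule = NULL, frame_rate = 500, noise_sd = 0,
                         n_points = 100, seed = 1L, cell_id = "synthetic") {
  mode <- match.arg(mode)
  if (frame_rate <= 4 * pattern$omega0 / (2 * pi))
    stop_domain("`frame_rate` must exceed 4x the beat frequency")
  if (noise_sd < 0) stop_domain("`noise_sd` must be >= 0")
  if (n_points < 10) stop_domain("`n_points` must be >= 10")
  .compile_schedule(schedule)  # validate keys early
  structure(list(pattern = pattern, mode = mode, duration = duration,
                 schedule = schedule, frame_rate = frame_rate,
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 seed = as.integer(seed), cell_id = cell_id),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cell config '%s': %s, %g s at %g fps, %d pts, noise %g um, seed %d\n",
    x$cell_id, x$mode, x$duration, x$frame_rate, x$n_points, x$noise_sd,
    x$seed))
  invisible(x)
}

#' Generate a synthetic tracked cell
#'
#' Simulates the cell pose with the resistive-force-theory solver (rigid
#' motion integrated with the midpoint scheme, internally substepped so the
#' step never exceeds 1/200 of the beat period regardless of the frame
#' rate) and emits, at every frame time, the lab-frame flagellar points
#' with i.i.d. Gaussian positional noise. The head position is the
#' flagellar base point and the head angle the base tangent angle. The
#' ground truth stores exactly what the solver produced: per-frame `C0`,
#' `C2`, `phi` (after any schedule), the instantaneous rotation rate
#' `Omega`, the orientation `theta`, and the scalar `C1`, `omega0`, `k`,
#' `L`.
#'
#' @param cfg a [synth_config()].
#' @return list with `cell` (a [tracked_cell()]) and `truth` (list with
#'   per-frame data frame `series` and scalar parameters).
#' @export
generate_tracked_cell <- function(cfg) {
  p <- cfg$pattern
  sched <- .compile_schedule(cfg$schedule)
  dt_f <- 1 / cfg$frame_rate
  n_sub <- max(1L, ceiling(dt_f / (p$period / 200)))
  dt <- dt_f / n_sub
  n_frames <- max(2L, round(cfg$duration * cfg$frame_rate))
  s_body <- seq(0, p$L, length.out = cfg$n_points)
  s_solver <- seq(0, p$L, length.out = 101)
  drag <- drag_model()

  pat_at <- function(t) {
    if (is.null(sched)) return(p)
    q <- p
    for (key in names(sched)) q[[key]] <- sched[[key]](t)
    q
  }
  motion_at <- function(t)
    .instantaneous_motion(pat_at(t), "full", t, s_solver, drag, cfg$mode)

  set.seed(cfg$seed)
  pose <- c(0, 0, 0)  # x, y, theta
  flagella <- vector("list", n_frames)
  head <- matrix(0, n_frames, 3)
  truth <- data.frame(t = (seq_len(n_frames) - 1) * dt_f,
                      C0 = 0, C2 = 0, phi = 0, Omega = 0, theta = 0)
  for (fr in seq_len(n_frames)) {
    t_fr <- (fr - 1) * dt_f
    pf <- pat_at(t_fr)
    mot <- motion_at(t_fr)
    truth$C0[fr] <- pf$C0; truth$C2[fr] <- pf$C2; truth$phi[fr] <- pf$phi
    truth$Omega[fr] <- mot$Omega; truth$theta[fr] <- pose[3]
    # emit the frame
    Cb <- eval_curvature(pf, "full", s_body, t_fr)
    sh <- flagellar_shape(s_body, Cb)
    R <- matrix(c(cos(pose[3]), sin(pose[3]),
                  -sin(pose[3]), cos(pose[3])), 2, 2)
    lab <- sweep(sh$points %*% t(R), 2, pose[1:2], "+")
    if (cfg$noise_sd > 0)
      lab <- lab + matrix(stats::rnorm(length(lab), sd = cfg$noise_sd),
                          ncol = 2)
    flagella[[fr]] <- lab
    head[fr, ] <- c(pose[1:2], pose[3])
    # advance to the next frame with midpoint substeps
    if (fr < n_frames) {
      for (ss in seq_len(n_sub)) {
        t0 <- t_fr + (ss - 1) * dt
        mm <- motion_at(t0 + dt / 2)
        th_mid <- pose[3] + mm$Omega * dt / 2
        pose[1] <- pose[1] +
          (cos(th_mid) * mm$U[1] - sin(th_mid) * mm$U[2]) * dt
        pose[2] <- pose[2] +
          (sin(th_mid) * mm$U[1] + cos(th_mid) * mm$U[2]) * dt
        pose[3] <- pose[3] + mm$Omega * dt
      }
    }
  }
  cell <- tracked_cell(cfg$frame_rate, flagella, head, cfg$cell_id)
  list(cell = cell,
       truth = list(series = truth, C1 = p$C1, omega0 = p$omega0,
                    k = p$k, L = p$L, mode = cfg$mode, seed = cfg$seed))
}

#' Write a ground-truth table
#'
#' Sidecar tabular text next to a synthetic tracked-cell file: scalar
#' parameters as comment header, per-frame series as a TSV table.
#'
#' @param truth the `truth` element of [generate_tracked_cell()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%.10g", c("C1", "omega0", "k", "L"),
                     c(truth$C1, truth$omega0, truth$k, truth$L)), con)
  writeLines(sprintf("# mode=%s", truth$mode), con)
  utils::write.table(truth$series, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Named parameter sets of the published simulation figures
#'
#' Returns, as ready-to-run [synth_config()]s, the beat-pattern parameter
#' sets used in the simulation figures: `fig2` (L = 40 micron,
#' C0 = -1.5/L, C1 = 0.75 k, C2 = C1/2, phi = pi/2, wavelength = length)
#' and the parameter-sweep sets `fig3a` (C1 = 0.05 1/micron, time-ramped
#' C0), `fig3b` (C1 = 0.1 1/micron, phi = pi/2, time-ramped C2), `fig3c`
#' (C1 = 0.1 1/micron, constant C2, time-ramped phi) and `fig3ef`
#' (C1 = 0.05 1/micron, phi = pi/2, static). The beat frequency (30 Hz) and
#' the ramp amplitudes are package choices documented in the methods
#' vignette; the camera model is 500 fps throughout.
#'
#' @param duration recording length (s), default 2.
#' @param noise_sd positional noise (micron), default 0.
#' @param seed integer seed.
#' @return named list of [synth_config()] objects.
#' @export
make_figure_fixtures <- function(duration = 2, noise_sd = 0, seed = 1L) {
  w0 <- 2 * pi * 30
  L <- 40
  k <- 2 * pi / L
  ramp <- function(from, to)
    function(t) from + (to - from) * pmin(1, pmax(0, t / duration))
  list(
    fig2 = synth_config(
      beat_pattern(C1 = 0.75 * k, omega0 = w0, L = L, C0 = -1.5 / L,
                   C2 = 0.75 * k / 2, phi = pi / 2),
      mode = "free", duration = duration, noise_sd = noise_sd, seed = seed,
      cell_id = "fig2"),
    fig3a = synth_config(
      beat_pattern(C1 = 0.05, omega0 = w0, L = L),
      mode = "free", duration = duration,
      schedule = list(C0 = ramp(0, -0.05)),
      noise_sd = noise_sd, seed = seed, cell_id = "fig3a"),
    fig3b = synth_config(
      beat_pattern(C1 = 0.1, omega0 = w0, L = L, phi = pi / 2),
      mode = "free", duration = duration,
      schedule = list(C2 = ramp(0, 0.05)),
      noise_sd = noise_sd, seed = seed, cell_id = "fig3b"),
    fig3c = synth_config(
      beat_pattern(C1 = 0.1, omega0 = w0, L = L, C2 = 0.05),
      mode = "free", duration = duration,
      schedule = list(phi = ramp(0, 2 * pi)),
      noise_sd = noise_sd, seed = seed, cell_id = "fig3c"),
    fig3ef = synth_config(
      beat_pattern(C1 = 0.05, omega0 = w0, L = L, C2 = 0.025,
                   phi = pi / 2),
      mode = "free", duration = duration, noise_sd = noise_sd, seed = seed,
      cell_id = "fig3ef")
  )
}
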