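#' Curvature field from tracked coordinates
#'
#' Converts per-frame flagellar point sets into a discretized curvature
#' field. Tracked skeleton points are roughly equidistant along the
#' flagellum, so each frame is parameterized by point index, the x and y
#' coordinate sequences are smoothed with a cubic Savitzky-Golay filter
#' (flat passband, so beat harmonics pass unattenuated while tracking
#' jitter is suppressed; window about one fifth of the point count), the
#' arc length is measured on the smoothed curve, and the curve is resampled
#' to `n_s` uniform arc-length stations. Differentiation then uses chord
#' angles: the `atan2` of successive chord directions (unwrapped along the
#' flagellum) samples the tangent angle at segment midpoints, and its first
#' difference gives the curvature at the interior nodes; the two end nodes
#' are filled by quadratic extrapolation (tracked flagellar ends are the
#' least reliable part of the data). Frames with duplicate or reversed
#' (doubled-back) tracks are flagged, excluded, and filled by linear
#' interpolation from neighbouring frames so the time grid stays uniform
#' (indices in attribute `flagged_frames`).
#'
#' @param cell a [tracked_cell()].
#' @param n_s number of arc-length stations (default 50).
#' @param smooth logical: apply the Savitzky-Golay coordinate smoothing.
#'   Default `TRUE`; with `FALSE` the points are interpolated exactly
#'   (appropriate for noise-free synthetic input only).
#' @return a [curvature_field()] on the common grid `[0, L]` x frame times,
#'   where `L` is the median tracked arc length.
#' @export
curvature_from_coordinates <- function(cell, n_s = 50, smooth = TRUE) {
  n_f <- length(cell$flagella)
  dt <- 1 / cell$frame_rate
  lens <- numeric(n_f)
  curv <- matrix(NA_real_, n_f, n_s)
  flagged <- integer(0)
  for (i in seq_len(n_f)) {
    m <- cell$flagella[[i]]
    np <- nrow(m)
    seg <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
    if (any(seg == 0)) { flagged <- c(flagged, i); next }
    # reversed tracks double back: the end-to-end chord collapses
    if (sqrt((m[np, 1] - m[1, 1])^2 + (m[np, 2] - m[1, 2])^2) <
        0.25 * sum(seg)) { flagged <- c(flagged, i); next }
    idx <- seq_len(np)
    if (smooth) {
      w <- max(5L, 2L * floor(np / 10) + 1L)
      w <- min(w, np - 1L + np %% 2L)
      xs0 <- signal::sgolayfilt(m[, 1], p = 3, n = w)
      ys0 <- signal::sgolayfilt(m[, 2], p = 3, n = w)
    } else {
      xs0 <- m[, 1]
      ys0 <- m[, 2]
    }
    uf <- seq(1, np, length.out = 8L * n_s)
    xs <- stats::spline(idx, xs0, xout = uf)$y
    ys <- stats::spline(idx, ys0, xout = uf)$y
    a <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
    Lf <- a[length(a)]
    ag <- seq(0, Lf, length.out = n_s)
    x <- stats::approx(a, xs, xout = ag)$y
    y <- stats::approx(a, ys, xout = ag)$y
    h <- Lf / (n_s - 1)
    psi_mid <- signal::unwrap(atan2(diff(y), diff(x)))
    ci <- diff(psi_mid) / h
    cv <- c(3 * ci[1] - 3 * ci[2] + ci[3], ci,
            3 * ci[n_s - 2] - 3 * ci[n_s - 3] + ci[n_s - 4])
    lens[i] <- Lf
    curv[i, ] <- cv
  }
  if (length(flagged) == n_f) stop_domain("all frames flagged as invalid")
  ok <- setdiff(seq_len(n_f), flagged)
  if (length(flagged)) {
    for (j in seq_len(n_s))
      curv[flagged, j] <- stats::approx(ok, curv[ok, j], xout = flagged,
                                        rule = 2)$y
    lens[flagged] <- stats::approx(ok, lens[ok], xout = flagged, rule = 2)$y
  }
  L <- stats::median(lens)
  out <- curvature_field(seq(0, L, length.out = n_s),
                         (seq_len(n_f) - 1) * dt, curv)
  attr(out, "flagged_frames") <- flagged
  out
}

#' Principal-component denoising of a curvature field
#'
#' Decomposes the (time x arc-length) curvature matrix into principal
#' components and discards eigenmodes contributing less than a fraction
#' `threshold` of the total variance; the retained modes are recomposed
#' with the mean profile added back. A planar beating flagellum needs only
#' a few shape modes (a travelling wave is two standing modes), so a 5%
#' threshold removes most tracking noise while keeping the beat.
#'
#' @param field a [curvature_field()] with at least 2 frames.
#' @param threshold variance fraction below which a mode is discarded;
#'   `0 <= threshold < 1` (0 keeps everything). Default 0.05.
#' @return a denoised [curvature_field()]; the number of retained modes is
#'   in attribute `n_modes`.
#' @export
pca_denoise <- function(field, threshold = 0.05) {
  if (threshold < 0 || threshold >= 1)
    stop_domain("`threshold` must be in [0, 1)")
  V <- field$values
  if (nrow(V) < 2) stop_domain("need at least 2 frames")
  mu <- colMeans(V)
  Vc <- sweep(V, 2, mu)
  sv <- svd(Vc)
  frac <- sv$d^2 / sum(sv$d^2)
  keep <- which(frac >= threshold)
  if (!length(keep)) keep <- 1L
  rec <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
  out <- curvature_field(field$s_grid, field$t_grid,
                         sweep(rec, 2, mu, "+"), period = field$period)
  attr(out, "n_modes") <- length(keep)
  attr(out, "variance_fraction") <- frac
  out
}

# FWHM (s) -> Gaussian sd in sample units
.fwhm_sd <- function(fwhm_s, rate) fwhm_s * rate / (2 * sqrt(2 * log(2)))

#' Rotational velocity from the head orientation
#'
#' Time derivative (central differences) of the unwrapped head orientation
#' angle, Gaussian-smoothed to suppress the within-beat wobble. The
#' smoothing `smooth` is the filter size interpreted as full width at half
#' maximum, matching the temporal filtering applied to all other parameter
#' series.
#'
#' @param cell a [tracked_cell()].
#' @param smooth Gaussian filter size, FWHM in seconds (default 0.25; use
#'   0.3 for the human-sperm preset). 0 disables smoothing.
#' @return numeric vector `Omega(t)` (rad/s), one value per frame.
#' @export
rotation_velocity <- function(cell, smooth = 0.25) {
  th <- cell$head[, "angle"]
  om <- pracma::gradient(th, 1 / cell$frame_rate)
  gaussian_smooth(om, .fwhm_sd(smooth, cell$frame_rate))
}

#' Time course of the mean flagellar curvature
#'
#' The mean curvature `C0(t)` is the average of the flagellar curvature
#' over the full arc length, per frame, Gaussian-smoothed in time. A pure
#' travelling wave spanning a full wavelength averages to zero; a non-zero
#' value is the arc ("rudder") component of the beat.
#'
#' @param field a [curvature_field()].
#' @param smooth Gaussian filter FWHM in seconds (default 0.25; 0 disables).
#' @return numeric vector `C0(t)` (1/micron), one value per frame.
#' @export
mean_curvature_series <- function(field, smooth = 0.25) {
  c0 <- rowMeans(field$values)
  nt <- length(field$t_grid)
  rate <- if (nt > 1) 1 / (field$t_grid[2] - field$t_grid[1]) else 0
  gaussian_smooth(c0, .fwhm_sd(smooth, rate))
}

#' Short-time Fourier analysis of the beat
#'
#' Sliding-window spectral decomposition of the curvature field with a
#' minimum 4-term Blackman-Harris window of length `l`. In every window and
#' at every arc-length station the curvature is Fourier-transformed; the
#' largest peak of the arc-length-averaged power spectrum gives the
#' fundamental beat frequency `omega0(t)` (refined by parabolic
#' interpolation), and complex projections onto the refined fundamental and
#' its double give the amplitudes. The second-harmonic amplitude `C2(t)` is
#' the integral of the amplitude spectrum over `2*omega0 +/- delta` with
#' `delta = 1/l`, calibrated against the window's own response so that a
#' pure sinusoid of amplitude a reports a. The relative phase `phi(t)` is
#' the phase of the second-harmonic coefficient minus twice the
#' fundamental's, referenced to the travelling-wave convention
#' (`sin(k s - n omega0 t + ...)`, wavelength = tracked length) and
#' averaged over arc length with a circular mean.
#'
#' @param field a [curvature_field()].
#' @param l window length in seconds (default 0.25; use 0.5 for the
#'   human-sperm preset).
#' @param hop window hop in frames; default `round(l * rate / 8)`.
#' @param k wavenumber used to reference phases (1/micron); default
#'   `2*pi / max(s_grid)`.
#' @param f_min lowest admissible beat frequency (Hz); default `5/l`, below
#'   which the window cannot separate the fundamental from the mean-
#'   curvature (zero-frequency) peak.
#' @return list with `t_grid` (window centres, s), `omega0` (rad/s), `C1`,
#'   `C2` (1/micron), `phi` (rad), used by [analyze_beat()].
#' @export
windowed_spectrum <- function(field, l = 0.25, hop = NULL, k = NULL,
                              f_min = NULL) {
  nt <- length(field$t_grid)
  dt <- field$t_grid[2] - field$t_grid[1]
  rate <- 1 / dt
  w <- round(l * rate)
  if (w > nt) stop_domain("window (", w, " frames) longer than the record")
  if (w < 16) stop_domain("window too short for spectral analysis")
  k <- k %||% (2 * pi / max(field$s_grid))
  f_min <- f_min %||% (5 / l)
  hop <- hop %||% max(1L, round(w / 8))
  win <- blackman_harris(w)
  gain <- 2 / sum(win)
  trel <- (seq_len(w) - 1) * dt
  freqs <- (seq_len(w) - 1) / (w * dt)      # Hz, full FFT axis
  half <- seq_len(floor(w / 2))             # positive-frequency bins
  starts <- seq(1L, nt - w + 1L, by = hop)
  ns <- length(field$s_grid)
  res <- matrix(NA_real_, length(starts), 5)
  for (jj in seq_along(starts)) {
    idx <- starts[jj]:(starts[jj] + w - 1L)
    seg <- field$values[idx, , drop = FALSE] * win
    Z <- stats::mvfft(seg)
    amp <- Mod(Z[half, , drop = FALSE]) * gain
    pw <- rowMeans(amp^2)
    cand <- which(freqs[half] >= f_min)
    if (!length(cand)) stop_domain("`f_min` excludes the whole spectrum")
    pk <- cand[which.max(pw[cand])]
    # parabolic refinement on log power
    f0 <- freqs[pk]
    if (pk > 1 && pk < length(half)) {
      lp <- log(pw[(pk - 1):(pk + 1)])
      d <- (lp[1] - lp[3]) / (2 * (lp[1] - 2 * lp[2] + lp[3]))
      f0 <- freqs[pk] + d / (w * dt)
    }
    e1 <- exp(-2i * pi * f0 * trel)
    e2 <- exp(-4i * pi * f0 * trel)
    raw <- field$values[idx, , drop = FALSE]
    c1 <- as.vector(gain * (t(win * e1) %*% raw))
    c2 <- as.vector(gain * (t(win * e2) %*% raw))
    # band integral for C2, calibrated on the window's response to a unit
    # sinusoid at 2*f0
    band <- which(abs(freqs[half] - 2 * f0) <= 1 / l)
    ref <- Mod(stats::fft(win * cos(4 * pi * f0 * trel)))[half]
    cal <- sum(ref[band])
    C2s <- colSums(Mod(Z[band, , drop = FALSE])) / cal
    phi_s <- k * field$s_grid - (Arg(c2) - 2 * Arg(c1)) - pi / 2
    res[jj, ] <- c(2 * pi * f0, mean(Mod(c1)), mean(C2s),
                   circ_mean(phi_s),
                   field$t_grid[idx[1]] + (w - 1) * dt / 2)
  }
  list(t_grid = res[, 5], omega0 = res[, 1], C1 = res[, 2],
       C2 = res[, 3], phi = res[, 4], window_length = l, hop = hop)
}

#' Full beat-analysis pipeline for a tracked cell
#'
#' Runs the complete waveform analysis: curvature from coordinates,
#' principal-component denoising, short-time Fourier analysis
#' ([windowed_spectrum()]), the mean-curvature series, and the rotational
#' velocity from the head orientation, all resampled onto the spectral
#' window centres and Gaussian-smoothed. Two presets bundle the window and
#' filter sizes: `"sea_urchin"` (window 250 ms, filter 250 ms) and
#' `"human"` (window 500 ms, filter 300 ms).
#'
#' @param cell a [tracked_cell()].
#' @param preset `"sea_urchin"` (default) or `"human"`; individual values
#'   can be overridden with `l` and `smooth`.
#' @param l spectral window length (s); overrides the preset.
#' @param smooth Gaussian filter FWHM (s); overrides the preset.
#' @param threshold PCA variance-fraction threshold (default 0.05).
#' @param n_s arc-length stations (default 50).
#' @param ... passed on to [windowed_spectrum()].
#' @return An object of class `beat_spectrum`: list with `t_grid`,
#'   time series `omega0`, `C1`, `C2`, `phi`, `C0`, `Omega`, `Omega_ratio`
#'   (= `Omega/omega0`), the `window_length`, and (filled by
#'   [effective_phase()]) `phi_eff`, `r_2nd`, `r_C0`.
#' @export
analyze_beat <- function(cell, preset = c("sea_urchin", "human"), l = NULL,
                         smooth = NULL, threshold = 0.05, n_s = 50, ...) {
  preset <- match.arg(preset)
  l <- l %||% switch(preset, sea_urchin = 0.25, human = 0.5)
  smooth <- smooth %||% switch(preset, sea_urchin = 0.25, human = 0.3)
  field <- curvature_from_coordinates(cell, n_s = n_s)
  field <- pca_denoise(field, threshold)
  sp <- windowed_spectrum(field, l = l, ...)
  # frame-rate series, resampled at the window centres
  c0 <- mean_curvature_series(field, smooth = smooth)
  om <- rotation_velocity(cell, smooth = smooth)
  ft <- field$t_grid
  c0_w <- stats::approx(ft, c0, xout = sp$t_grid, rule = 2)$y
  om_w <- stats::approx(ft, om, xout = sp$t_grid, rule = 2)$y
  # smooth the spectral series on the hop grid
  hop_rate <- cell$frame_rate / sp$hop
  sm <- function(x) gaussian_smooth(x, .fwhm_sd(smooth, hop_rate))
  out <- list(t_grid = sp$t_grid, omega0 = sm(sp$omega0), C1 = sm(sp$C1),
              C2 = sm(sp$C2), phi = wrap_pi(sm(signal::unwrap(sp$phi))),
              C0 = c0_w, Omega = om_w,
              Omega_ratio = om_w / sm(sp$omega0),
              window_length = l, smooth = smooth,
              cell_id = cell$cell_id,
              phi_eff = NA_real_, r_2nd = NA_real_, r_C0 = NA_real_)
  class(out) <- "beat_spectrum"
  out
}

#' @export
print.beat_spectrum <- function(x, ...) {
  cat(sprintf("Beat spectrum '%s': %d windows of %g s\n", x$cell_id,
              length(x$t_grid), x$window_length))
  cat(sprintf("  median omega0 = %.4g rad/s (%.3g Hz), C1 = %.4g, C2 = %.4g 1/um\n",
              stats::median(x$omega0), stats::median(x$omega0) / (2 * pi),
              stats::median(x$C1), stats::median(x$C2)))
  if (is.finite(x$phi_eff))
    cat(sprintf("  phi_eff = %.4g rad (r = %.3g)\n", x$phi_eff, x$r_2nd))
  invisible(x)
}

#' Effective second-harmonic phase by correlation maximization
#'
#' The combination `C2 sin(phi + phi_eff)` is the effective steering
#' strength of the second harmonic; the offset `phi_eff` is not observable
#' directly and is determined by scanning it over `[0, 2*pi)` and
#' maximizing the Pearson correlation between `C2(t) sin(phi(t) + phi_eff)`
#' and the normalized rotational velocity `Omega(t)/omega0(t)`.
#'
#' @param spec a [analyze_beat()] result.
#' @param resolution scan step (rad), at most 0.01.
#' @return `spec` with `phi_eff`, `r_2nd` (the maximized correlation) and
#'   `r_C0` (correlation of `Omega/omega0` with `C0`) filled in.
#' @export
effective_phase <- function(spec, resolution = 0.01) {
  y <- spec$Omega_ratio
  if (stats::sd(y) == 0 || stats::sd(spec$C2 * sin(spec$phi)) == 0)
    stop_domain("constant series: correlation undefined")
  grid <- seq(0, 2 * pi, by = min(resolution, 0.01))
  r <- vapply(grid, function(pe)
    stats::cor(spec$C2 * sin(spec$phi + pe), y), 0)
  best <- which.max(r)
  spec$phi_eff <- grid[best]
  spec$r_2nd <- r[best]
  spec$r_C0 <- if (stats::sd(spec$C0) > 0) stats::cor(spec$C0, y) else NA_real_
  spec
}

#' Linear steering fits
#'
#' Least-squares slopes of the normalized rotational velocity against the
#' mean curvature and against the effective second-harmonic strength
#' `C2 sin(phi + phi_eff)`, per cell and (for a list of spectra) pooled.
#' Under the tethered steering laws the slopes estimate
#' `B0 k^-3 C1^2` and `B2 k^-3 C1^2`.
#'
#' @param spec a `beat_spectrum`, or a list of them for a pooled fit.
#' @return data frame with one row per cell plus (for a list) a `"pooled"`
#'   row: columns `cell_id`, `slope_C0`, `r_C0`, `slope_2nd`, `r_2nd`,
#'   `phi_eff`, `n`.
#' @export
steering_fits <- function(spec) {
  specs <- if (inherits(spec, "beat_spectrum")) list(spec) else spec
  specs <- lapply(specs, function(s)
    if (is.finite(s$phi_eff)) s else effective_phase(s))
  one <- function(s, id = s$cell_id) {
    y <- s$Omega_ratio
    x2 <- s$C2 * sin(s$phi + s$phi_eff)
    if (stats::sd(s$C0) == 0 && stats::sd(x2) == 0)
      stop_domain("degenerate (constant) predictors")
    s0 <- if (stats::sd(s$C0) > 0)
      stats::coef(stats::lm(y ~ s$C0))[2] else NA_real_
    s2 <- if (stats::sd(x2) > 0)
      stats::coef(stats::lm(y ~ x2))[2] else NA_real_
    data.frame(cell_id = id, slope_C0 = unname(s0),
               r_C0 = if (stats::sd(s$C0) > 0) stats::cor(s$C0, y) else NA,
               slope_2nd = unname(s2),
               r_2nd = if (stats::sd(x2) > 0) stats::cor(x2, y) else NA,
               phi_eff = s$phi_eff, n = length(y))
  }
  out <- do.call(rbind, lapply(specs, one))
  if (length(specs) > 1) {
    pooled <- list(
      C0 = unlist(lapply(specs, `[[`, "C0")),
      C2 = unlist(lapply(specs, `[[`, "C2")),
      phi = unlist(lapply(specs, `[[`, "phi")),
      phi_eff = stats::median(out$phi_eff),
      Omega_ratio = unlist(lapply(specs, `[[`, "Omega_ratio")),
      cell_id = "pooled")
    out <- rbind(out, one(pooled, "pooled"))
  }
  rownames(out) <- NULL
  out
}
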