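make_cell_from_shapes <- function(shapes, frame_rate = 500,
                                  head = NULL) {
  n <- length(shapes)
  if (is.null(head)) head <- cbind(0, 0, rep(0, n))
  tracked_cell(frame_rate, shapes, head)
}

test_that("curvature extraction handles lines, circles and beats", {
  # straight line
  pts <- lapply(1:12, function(i) cbind(seq(0, 40, length.out = 60),
                                        rep(0, 60)))
  f <- curvature_from_coordinates(make_cell_from_shapes(pts), n_s = 40)
  expect_lt(max(abs(f$values)), 1e-8)

  # circle of radius 20: curvature 0.05 on the interior
  th <- seq(0, 1.5, length.out = 80)
  circ <- lapply(1:12, function(i) cbind(20 * cos(th), 20 * sin(th)))
  fc <- curvature_from_coordinates(make_cell_from_shapes(circ), n_s = 50)
  expect_equal(abs(fc$values[1, 5:46]), rep(0.05, 42), tolerance = 0.01)

  # beat-driven synthetic shapes recover the mean curvature
  g <- tethered_cell_clean()
  ff <- curvature_from_coordinates(g$cell, n_s = 50)
  expect_equal(mean(rowMeans(ff$values)), -0.0375, tolerance = 0.05)
})

test_that("flagged frames are excluded and interpolated", {
  p <- fig2_pattern()
  s <- seq(0, 40, length.out = 60)
  shapes <- lapply(seq(0, 0.022, by = 0.002), function(t)
    flagellar_shape(s, eval_curvature(p, "full", s, t))$points)
  shapes[[5]][10, ] <- shapes[[5]][9, ]  # duplicate point
  f <- curvature_from_coordinates(make_cell_from_shapes(shapes), n_s = 40)
  expect_identical(attr(f, "flagged_frames"), 5L)
  expect_true(all(is.finite(f$values)))
})

test_that("PCA denoising keeps the beat and drops the noise", {
  p <- fig2_pattern()
  f <- sample_beat(p, "full", n_s = 30, n_t = 100)
  expect_error(pca_denoise(f, threshold = 1.2), "0, 1")
  expect_error(pca_denoise(f, threshold = -0.1), "0, 1")

  # threshold 0 keeps everything (identity)
  expect_equal(pca_denoise(f, 0)$values, f$values, tolerance = 1e-12)

  # travelling wave = two standing modes: >= 99% variance in 2 components
  fs <- sample_beat(beat_pattern(C1 = 0.1, omega0 = 2 * pi, L = 40),
                    "sine", n_s = 30, n_t = 100)
  fr <- attr(pca_denoise(fs, 0.05), "variance_fraction")
  expect_gte(sum(fr[1:2]), 0.99)

  # rank-2 field plus noise: reconstruction closer to clean than to noisy
  set.seed(3)
  tt <- seq_len(200)
  clean <- outer(sin(2 * pi * tt / 40), sin(seq(0, pi, length.out = 30))) +
    outer(cos(2 * pi * tt / 40), cos(seq(0, 2, length.out = 30)))
  noisy <- clean + matrix(rnorm(length(clean), sd = 0.2), nrow = 200)
  fn <- curvature_field(seq(0, 40, length.out = 30), (tt - 1) / 500, noisy)
  den <- pca_denoise(fn, 0.05)$values
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))
})

test_that("rotation velocity differentiates the head angle", {
  n <- 400
  hd0 <- cbind(0, 0, rep(1.3, n))
  pts <- lapply(seq_len(n), function(i) cbind(seq(0, 40, length.out = 20),
                                              0))
  expect_equal(rotation_velocity(tracked_cell(500, pts, hd0)),
               rep(0, n))
  tt <- (seq_len(n) - 1) / 500
  hd1 <- cbind(0, 0, 2 * pi * tt / 10)
  om <- rotation_velocity(tracked_cell(500, pts, hd1))
  expect_equal(om, rep(0.6283, n), tolerance = 1e-3)
})

test_that("mean curvature series averages over arc length", {
  sg <- seq(0, 40, length.out = 30)
  tg <- (0:99) / 500
  fc <- curvature_field(sg, tg, matrix(0.042, 100, 30))
  expect_equal(mean_curvature_series(fc), rep(0.042, 100))
  # a full spatial wavelength averages to ~0
  fw <- curvature_field(sg, tg,
                        matrix(rep(0.1 * sin(2 * pi * sg / 40), each = 100),
                               nrow = 100))
  expect_lt(max(abs(mean_curvature_series(fw))), 2e-3)
})

test_that("windowed spectra resolve the harmonics and their phase", {
  g <- tethered_cell_clean()
  p <- fig2_pattern()
  field <- curvature_from_coordinates(g$cell, n_s = 50)
  sp <- windowed_spectrum(field, l = 0.25)
  expect_equal(stats::median(sp$omega0), p$omega0, tolerance = 0.02)
  expect_equal(stats::median(sp$C2) / stats::median(sp$C1), 0.5,
               tolerance = 0.1)
  expect_equal(atan2(mean(sin(sp$phi)), mean(cos(sp$phi))), pi / 2,
               tolerance = 0.1)

  # a single-harmonic beat shows only the leakage floor at 2 omega0
  ps <- beat_pattern(C1 = 0.75 * 2 * pi / 40, omega0 = 2 * pi * 30, L = 40)
  fs <- sample_beat(ps, "sine", n_s = 40, n_t = round(500 / 30),
                    n_periods = 18)
  fs$t_grid <- (seq_along(fs$t_grid) - 1) / 500  # relabel as 500 fps
  sps <- windowed_spectrum(fs, l = 0.25)
  expect_lt(stats::median(sps$C2) / stats::median(sps$C1), 0.02)

  expect_error(windowed_spectrum(field, l = 10), "longer than")
})

test_that("the pipeline is equivariant under lab-frame motions", {
  g <- tethered_cell_clean()
  th <- 0.77
  R <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  shift <- c(12, -5)
  moved <- lapply(g$cell$flagella, function(m)
    sweep(m %*% t(R), 2, shift, "+"))
  hd <- g$cell$head
  hd2 <- cbind(sweep(hd[, 1:2] %*% t(R), 2, shift, "+"), hd[, 3] + th)
  cell2 <- tracked_cell(500, moved, hd2)
  f1 <- curvature_from_coordinates(g$cell, n_s = 40)
  f2 <- curvature_from_coordinates(cell2, n_s = 40)
  expect_equal(f2$values, f1$values, tolerance = 1e-8)
  expect_equal(rotation_velocity(cell2), rotation_velocity(g$cell),
               tolerance = 1e-10)
})

test_that("doubling the window barely moves stationary amplitudes", {
  g <- cached("tethered_cell_long", function()
    generate_tracked_cell(synth_config(fig2_pattern(), mode = "tethered",
                                       duration = 1.2, noise_sd = 0,
                                       seed = 5, cell_id = "long")))
  field <- curvature_from_coordinates(g$cell, n_s = 50)
  a <- windowed_spectrum(field, l = 0.25)
  b <- windowed_spectrum(field, l = 0.5)
  expect_equal(stats::median(b$C1), stats::median(a$C1), tolerance = 0.02)
  expect_equal(stats::median(b$C2), stats::median(a$C2), tolerance = 0.02)
})

test_that("effective phase is identified by correlation maximization", {
  set.seed(11)
  n <- 400
  tt <- seq(0, 8, length.out = n)
  base <- list(t_grid = tt,
               C2 = 0.05 + 0.02 * sin(2 * pi * tt / 5),
               phi = pi * (tt / 8),
               C0 = rep(0, n), omega0 = rep(60, n), C1 = rep(0.1, n),
               window_length = 0.25, cell_id = "constructed",
               phi_eff = NA_real_, r_2nd = NA_real_, r_C0 = NA_real_)

  # self-consistency: the target built with phi_eff = 0
  s0 <- base
  s0$Omega_ratio <- s0$C2 * sin(s0$phi)
  s0$Omega <- s0$Omega_ratio * 60
  class(s0) <- "beat_spectrum"
  r0 <- effective_phase(s0)
  expect_lt(min(abs(c(r0$phi_eff, r0$phi_eff - 2 * pi))), 0.02)
  expect_gt(r0$r_2nd, 0.999)

  # a target with the tethered offset baked in
  s1 <- base
  s1$Omega_ratio <- s1$C2 * sin(s1$phi + 0.56 * pi)
  s1$Omega <- s1$Omega_ratio * 60
  class(s1) <- "beat_spectrum"
  r1 <- effective_phase(s1)
  expect_equal(r1$phi_eff, 0.56 * pi, tolerance = 0.02)

  # independent noise: correlation stays at chance level
  s2 <- base
  s2$Omega_ratio <- rnorm(n)
  class(s2) <- "beat_spectrum"
  r2 <- effective_phase(s2)
  expect_lt(abs(r2$r_2nd), 4 / sqrt(n))

  s3 <- base
  s3$Omega_ratio <- rep(1, n)
  class(s3) <- "beat_spectrum"
  expect_error(effective_phase(s3), "constant")
})

test_that("steering fits recover linear relations exactly", {
  n <- 300
  tt <- seq(0, 6, length.out = n)
  sp <- list(t_grid = tt, C0 = 0.03 * sin(tt), C2 = rep(0.05, n),
             phi = rep(pi / 2, n), omega0 = rep(60, n), C1 = rep(0.1, n),
             window_length = 0.25, cell_id = "lin",
             phi_eff = 0, r_2nd = NA_real_, r_C0 = NA_real_)
  sp$Omega_ratio <- -2.5 * sp$C0
  sp$Omega <- sp$Omega_ratio * 60
  class(sp) <- "beat_spectrum"
  fit <- steering_fits(sp)
  expect_equal(fit$slope_C0, -2.5, tolerance = 1e-10)
  expect_equal(abs(fit$r_C0), 1, tolerance = 1e-10)

  # zero-steering series gives a zero slope
  sp0 <- sp
  sp0$Omega_ratio <- rep(0, n) + 1e-12 * sin(tt)
  class(sp0) <- "beat_spectrum"
  expect_lt(abs(steering_fits(sp0)$slope_C0), 1e-9)
})

test_that("tracked-cell files round-trip exactly at declared precision", {
  g <- tethered_cell_clean()
  path <- tempfile(fileext = ".tsv")
  write_tracked_cell(g$cell, path)
  back <- read_tracked_cell(path)
  expect_equal(back$frame_rate, 500)
  expect_identical(back$cell_id, "clean")
  expect_equal(back$flagella[[3]],
               matrix(signif(g$cell$flagella[[3]], 6), ncol = 2,
                      dimnames = list(NULL, c("x", "y"))))
  expect_equal(back$head[, "angle"], g$cell$head[, "angle"],
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("end-to-end fits recover the tethered steering slopes", {
  # modulated synthetic cells at the parameter-sweep amplitude; fitted
  # slopes estimate B0 k^-3 C1^2 and B2 k^-3 C1^2
  k <- 2 * pi / 40
  C1 <- 0.05
  co <- tethered_coeffs()

  p1 <- beat_pattern(C1 = C1, omega0 = 2 * pi * 30, L = 40)
  g1 <- generate_tracked_cell(synth_config(
    p1, "tethered", duration = 2,
    schedule = list(C0 = function(t) 0.5 * C1 * sin(2 * pi * t / 0.9)),
    noise_sd = 0, seed = 21, cell_id = "c0mod"))
  f1 <- steering_fits(analyze_beat(g1$cell))
  expect_equal(f1$slope_C0, co$B0 * k^-3 * C1^2, tolerance = 0.15)
  expect_lt(f1$r_C0, 0)   # B0 < 0: clockwise response to positive C0

  p2 <- beat_pattern(C1 = C1, omega0 = 2 * pi * 30, L = 40, C2 = 0.5 * C1)
  g2 <- generate_tracked_cell(synth_config(
    p2, "tethered", duration = 2,
    schedule = list(phi = function(t) 2 * pi * t / 2),
    noise_sd = 0, seed = 22, cell_id = "phimod"))
  f2 <- steering_fits(analyze_beat(g2$cell))
  expect_equal(f2$slope_2nd, co$B2 * k^-3 * C1^2, tolerance = 0.15)
  expect_gt(f2$r_2nd, 0)
})
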