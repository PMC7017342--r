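test_that("prototypical curvature variants evaluate correctly", {
  L <- 40
  k <- 2 * pi / L
  p <- beat_pattern(C1 = 0.1, omega0 = 2 * pi, L = L, C0 = -1.5 / L,
                    C2 = 0.05, phi = pi / 2)
  # wavelength-equals-length default
  expect_equal(p$k, k)
  expect_equal(p$period, 1)

  # pure travelling wave vanishes where its argument does
  expect_equal(eval_curvature(p, "sine", s = 0, t = 0), 0)
  # mean variant adds the arc curvature: at (0, 0) the sine term is zero
  expect_equal(eval_curvature(p, "mean", s = 0, t = 0), -0.0375)
  # second harmonic at s = 0, t = 0 contributes C2 sin(phi)
  p2 <- beat_pattern(C1 = 0.1, omega0 = 2 * pi, L = L, C2 = 0.05,
                     phi = pi / 2)
  expect_equal(eval_curvature(p2, "second_harmonic", 0, 0), 0.05)

  expect_error(eval_curvature(p, "sine", s = L + 1, t = 0), "outside")
  expect_error(eval_curvature(p, "sine", s = -0.1, t = 0), "outside")
  expect_error(beat_pattern(C1 = 0.1, omega0 = -1, L = 40), "omega0")
  expect_error(beat_pattern(C1 = Inf, omega0 = 1, L = 40), "finite")
})

test_that("temporal Fourier modes recover the analytic coefficients", {
  L <- 40
  k <- 2 * pi / L
  p <- beat_pattern(C1 = 0.12, omega0 = 2 * pi, L = L, C0 = -0.03)
  f <- sample_beat(p, "mean", n_s = 41, n_t = 64)
  fm <- fourier_modes(f, 3)
  s <- fm$s_grid
  expect_equal(fm$c0, rep(-0.03, 41), tolerance = 1e-12)
  expect_equal(fm$cn[1, ], 0.12 * sin(k * s), tolerance = 1e-12)
  expect_equal(fm$cn_bar[1, ], -0.12 * cos(k * s), tolerance = 1e-12)
  expect_lt(max(abs(fm$cn[2:3, ]), abs(fm$cn_bar[2:3, ])), 1e-12)

  # constant field: only mode 0
  fc <- curvature_field(s, f$t_grid, matrix(0.07, 64, 41), period = 1)
  fmc <- fourier_modes(fc, 2)
  expect_equal(fmc$c0, rep(0.07, 41))
  expect_lt(max(abs(fmc$cn), abs(fmc$cn_bar)), 1e-14)

  # second harmonic: mode-2 amplitude equals C2 at every arc position
  p2 <- beat_pattern(C1 = 0.1, omega0 = 2 * pi, L = L, C2 = 0.04,
                     phi = 0.7)
  f2 <- sample_beat(p2, "second_harmonic", n_s = 41, n_t = 64)
  fm2 <- fourier_modes(f2, 2)
  amp2 <- sqrt(fm2$cn[2, ]^2 + fm2$cn_bar[2, ]^2)
  expect_equal(amp2, rep(0.04, 41), tolerance = 1e-10)

  # non-integer period coverage must error, not leak
  bad <- curvature_field(s, f$t_grid[1:50], f$values[1:50, ], period = 1)
  expect_error(fourier_modes(bad, 2), "integer number")
})

test_that("Fourier synthesis reconstructs band-limited fields", {
  p <- beat_pattern(C1 = 0.1, omega0 = 2 * pi, L = 40, C0 = 0.02,
                    C2 = 0.05, phi = 1.1)
  f <- sample_beat(p, "full", n_s = 31, n_t = 32)
  fm <- fourier_modes(f, 4)
  rec <- synthesize_field(fm, f$t_grid)
  expect_lt(max(abs(rec$values - f$values)) / max(abs(f$values)), 1e-10)
})

test_that("the half-period mirror symmetry detects steering beats", {
  p_sine <- beat_pattern(C1 = 0.1, omega0 = 2 * pi, L = 40)
  expect_true(is_symmetric(sample_beat(p_sine, "sine", 31, 64)))

  # mean curvature breaks the symmetry condition
  p_mean <- beat_pattern(C1 = 0.1, omega0 = 2 * pi, L = 40, C0 = 0.02)
  expect_false(is_symmetric(sample_beat(p_mean, "mean", 31, 64)))

  # the second harmonic is invariant under the half-period shift, so the
  # shifted sum cannot flip sign
  p_2nd <- beat_pattern(C1 = 0.1, omega0 = 2 * pi, L = 40, C2 = 0.05,
                        phi = 0)
  expect_false(is_symmetric(sample_beat(p_2nd, "second_harmonic", 31, 64)))

  # invariant to the time origin of the record
  expect_true(is_symmetric(sample_beat(p_sine, "sine", 31, 64,
                                       t0 = 0.1234)))
  expect_false(is_symmetric(sample_beat(p_mean, "mean", 31, 64,
                                        t0 = 0.567)))
})

test_that("tangent-angle construction realizes shapes correctly", {
  s <- seq(0, 40, length.out = 101)

  # zero curvature: straight segment along x
  sh0 <- flagellar_shape(s, rep(0, 101))
  expect_equal(sh0$points[, "x"], s)
  expect_equal(sh0$points[, "y"], rep(0, 101))

  # constant curvature c: circular arc, endpoint at 2/|c| |sin(cL/2)|
  cc <- 0.05
  shc <- flagellar_shape(s, rep(cc, 101))
  endd <- sqrt(sum(shc$points[101, ]^2))
  expect_equal(endd, (2 / cc) * abs(sin(cc * 40 / 2)), tolerance = 1e-4)

  # arc length preserved within 1e-3 relative at 100 segments
  p <- fig2_pattern()
  f <- sample_beat(p, "full", n_s = 101, n_t = 8)
  for (i in c(1, 4, 8)) {
    sh <- shape_from_curvature(f, i)
    chord <- sum(sqrt(diff(sh$points[, 1])^2 + diff(sh$points[, 2])^2))
    expect_lt(abs(chord - 40) / 40, 1e-3)
  }
  expect_error(shape_from_curvature(f, 99), "out of range")
})

test_that("deformation velocity matches a finite-difference oracle", {
  p <- fig2_pattern(omega0 = 2 * pi)
  s <- seq(0, p$L, length.out = 101)
  t <- 0.2137
  dt <- p$period / 1e4

  v <- deformation_velocity(p, "full", t, s)
  shp <- function(tt) flagellar_shape(
    s, eval_curvature(p, "full", s, tt))$points
  v_fd <- (shp(t + dt / 2) - shp(t - dt / 2)) / dt
  scale <- max(abs(v_fd))
  expect_lt(max(abs(v - v_fd)) / scale, 1e-4)

  # base point is clamped by the gauge
  expect_equal(v[1, ], c(x = 0, y = 0))

  # a non-deforming profile has zero velocity everywhere
  p0 <- beat_pattern(C1 = 0, omega0 = 2 * pi, L = 40, C0 = 0.03)
  expect_equal(max(abs(deformation_velocity(p0, "mean", 0.3, s))), 0)
})

test_that("beat configuration files round-trip through YAML", {
  cfg <- tempfile(fileext = ".yml")
  writeLines(c("C0: -0.0375", "C1: 0.118", "C2: 0.059", "phi: 1.5708",
               "omega0: 188.5", "L: 40", "variant: full"), cfg)
  bp <- read_beat_config(cfg)
  expect_s3_class(bp$pattern, "beat_pattern")
  expect_equal(bp$pattern$C1, 0.118)
  expect_equal(bp$pattern$k, 2 * pi / 40)  # defaulted
  expect_identical(bp$variant, "full")
  writeLines(c("C1: 0.1", "L: 40"), cfg)
  expect_error(read_beat_config(cfg), "omega0")
})
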