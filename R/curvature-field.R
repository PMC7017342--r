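#' Discretized curvature field C(s, t)
#'
#' Container for a flagellar curvature wave sampled on an arc-length x time
#' grid. Rows of `values` index time, columns index arc length.
#'
#' @param s_grid strictly increasing arc-length samples (micron), covering
#'   `[0, L]`.
#' @param t_grid strictly increasing, uniformly spaced time samples (s).
#' @param values numeric matrix, `length(t_grid)` rows by `length(s_grid)`
#'   columns, finite.
#' @param period optional beat period (s) associated with the field; kept as
#'   an attribute and used as the default by [fourier_modes()] and
#'   [is_symmetric()].
#' @return An object of class `curvature_field`.
#' @seealso [sample_beat()] to build one from a [beat_pattern()].
#' @export
curvature_field <- function(s_grid, t_grid, values, period = NULL) {
  values <- as.matrix(values)
  if (length(s_grid) < 2 || any(diff(s_grid) <= 0))
    stop_domain("`s_grid` must be strictly increasing with >= 2 samples")
  if (length(t_grid) > 1) {
    dt <- diff(t_grid)
    if (any(dt <= 0)) stop_domain("`t_grid` must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9 * mean(dt))
      stop_domain("`t_grid` must be uniformly spaced")
  }
  if (nrow(values) != length(t_grid) || ncol(values) != length(s_grid))
    stop_domain("`values` must be length(t_grid) x length(s_grid)")
  if (!all(is.finite(values))) stop_domain("curvature values must be finite")
  structure(list(s_grid = as.numeric(s_grid), t_grid = as.numeric(t_grid),
                 values = values, period = period),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf(
    "Curvature field: %d frames x %d arc-length samples, s in [%g, %g] um\n",
    nrow(x$values), ncol(x$values), min(x$s_grid), max(x$s_grid)))
  if (!is.null(x$period))
    cat(sprintf("  beat period %.5g s, record %.5g s\n", x$period,
                diff(range(x$t_grid))))
  invisible(x)
}

#' Sample a beat pattern onto a curvature field
#'
#' Evaluates the prototypical wave on a uniform grid: `n_s` arc-length
#' samples on `[0, L]` and `n_t` time samples per beat period, with the
#' period endpoint excluded so that `n_periods` periods are covered by
#' exactly `n_periods * n_t` rows (integer-period coverage, as required by
#' the Fourier-mode projection).
#'
#' @inheritParams eval_curvature
#' @param n_s number of arc-length samples (default 101, i.e. 100 segments).
#' @param n_t time samples per beat period (default 500).
#' @param n_periods number of beat periods covered (default 1).
#' @param t0 time origin of the first sample (s).
#' @return a [curvature_field()] with the beat period attached.
#' @export
sample_beat <- function(pattern, variant = "full", n_s = 101, n_t = 500,
                        n_periods = 1, t0 = 0) {
  variant <- .check_variant(variant)
  s <- seq(0, pattern$L, length.out = n_s)
  T0 <- pattern$period
  tt <- t0 + (seq_len(n_t * n_periods) - 1) * T0 / n_t
  vals <- outer(tt, s, function(t, s) eval_curvature(pattern, variant, s, t))
  curvature_field(s, tt, vals, period = T0)
}

.field_period <- function(field, period) {
  period <- period %||% field$period
  if (is.null(period))
    stop_domain("field carries no beat period; supply `period`")
  period
}

# rows per period and integer-coverage check
.rows_per_period <- function(field, period, what = "operation") {
  nt <- length(field$t_grid)
  dt <- if (nt > 1) field$t_grid[2] - field$t_grid[1] else NA_real_
  m <- period / dt
  if (abs(m - round(m)) > 1e-6 * m)
    stop_domain(what, " requires the time step to divide the beat period")
  m <- round(m)
  if (nt %% m != 0)
    stop_domain(what, " requires an integer number of beat periods (got ",
                nt, " samples, ", m, " per period)")
  m
}

#' Temporal Fourier modes of a curvature field
#'
#' Projects the curvature at every arc-length position onto
#' `cos(2*pi*n*t/T)` and `sin(2*pi*n*t/T)` for `n = 1..n_max`; mode 0 is the
#' time mean. Requires the record to cover an integer number of beat periods
#' (otherwise spectral leakage corrupts the modes, and an error is thrown).
#' For a symmetric beat all even modes vanish; steering requires a non-zero
#' mean curvature (mode 0) or even harmonics.
#'
#' @param field a [curvature_field()].
#' @param n_max highest harmonic to compute.
#' @param period beat period (s); defaults to the period stored in `field`.
#' @return An object of class `fourier_modes`: list with `s_grid`, `c0`
#'   (mean profile), matrices `cn` and `cn_bar` (`n_max` rows: cosine and
#'   sine coefficient profiles), and `period`.
#' @export
fourier_modes <- function(field, n_max, period = NULL) {
  period <- .field_period(field, period)
  .rows_per_period(field, period, "fourier_modes()")
  tt <- field$t_grid
  V <- field$values
  c0 <- colMeans(V)
  cn <- matrix(0, n_max, ncol(V))
  cn_bar <- matrix(0, n_max, ncol(V))
  for (n in seq_len(n_max)) {
    w <- 2 * pi * n / period
    cn[n, ] <- 2 * colMeans(V * cos(w * tt))
    cn_bar[n, ] <- 2 * colMeans(V * sin(w * tt))
  }
  structure(list(s_grid = field$s_grid, c0 = c0, cn = cn, cn_bar = cn_bar,
                 period = period, n_max = n_max),
            class = "fourier_modes")
}

#' Reconstruct a curvature field from its Fourier modes
#'
#' Inverse synthesis of [fourier_modes()] on a given time grid.
#'
#' @param modes a `fourier_modes` object.
#' @param t_grid time samples (s).
#' @return a [curvature_field()].
#' @export
synthesize_field <- function(modes, t_grid) {
  V <- matrix(rep(modes$c0, each = length(t_grid)), nrow = length(t_grid))
  for (n in seq_len(modes$n_max)) {
    w <- 2 * pi * n / modes$period
    V <- V + outer(cos(w * t_grid), modes$cn[n, ]) +
      outer(sin(w * t_grid), modes$cn_bar[n, ])
  }
  curvature_field(modes$s_grid, t_grid, V, period = modes$period)
}

#' Test the beat-symmetry condition
#'
#' A beat is symmetric when the flagellum becomes its own mirror image after
#' half a beat period, `C(s, t) = -C(s, t + T/2)`; such beats produce no net
#' rotation per beat cycle. Checks the condition on the sampled grid by
#' wrapping the half-period shift around the (integer-period) record.
#'
#' @param field a [curvature_field()] covering an integer number of beat
#'   periods with an even number of samples per period.
#' @param tol tolerance on `max |C(s,t) + C(s,t+T/2)|` (1/micron).
#' @param period beat period (s); defaults to the stored period.
#' @return `TRUE` or `FALSE`.
#' @export
is_symmetric <- function(field, tol = 1e-9, period = NULL) {
  period <- .field_period(field, period)
  m <- .rows_per_period(field, period, "is_symmetric()")
  if (m %% 2 != 0)
    stop_domain("is_symmetric() needs an even number of samples per period")
  nt <- nrow(field$values)
  shift <- ((seq_len(nt) - 1 + m %/% 2) %% nt) + 1
  max(abs(field$values + field$values[shift, , drop = FALSE])) <= tol
}
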