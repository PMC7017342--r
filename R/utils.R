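# Internal numerical helpers.

# cumulative trapezoid returning a plain vector
cumtrapz1 <- function(x, y) drop(pracma::cumtrapz(x, y))

# minimum 4-term Blackman-Harris window (symmetric), standard coefficients
blackman_harris <- function(n) {
  stopifnot(n >= 2)
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  j <- seq_len(n) - 1
  a[1] - a[2] * cos(2 * pi * j / (n - 1)) +
    a[3] * cos(4 * pi * j / (n - 1)) - a[4] * cos(6 * pi * j / (n - 1))
}

# Gaussian kernel smoothing; sd in sample units. At the edges the kernel is
# truncated to the available samples and renormalized (no padding, so an
# oscillating series is not biased by invented boundary values).
# sd <= 0 returns x unchanged. NA-free input assumed.
gaussian_smooth <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- stats::filter(xp, k, sides = 2)
  den <- stats::filter(wp, k, sides = 2)
  as.numeric(num[(half + 1):(half + n)]) /
    as.numeric(den[(half + 1):(half + n)])
}

# circular mean of angles (rad)
circ_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

# wrap angle(s) to (-pi, pi]
wrap_pi <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
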