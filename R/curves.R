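#' Causal convolution with a decaying exponential
#'
#' Computes `y(t) = integral_0^t v(s) exp(-lambda (t - s)) ds` on the
#' sample grid `times`, assuming the input is piecewise linear (default)
#' or piecewise constant (left-continuous) between samples. The update is
#' the exact solution of the underlying first-order ODE for the assumed
#' interpolant, so no additional quadrature error is introduced.
#'
#' @param values Input samples `v(times)`.
#' @param times Strictly increasing sample times (s). Need not be uniform.
#' @param lambda Decay rate of the kernel (1/s), `>= 0`. `lambda = 0`
#'   degenerates to the running integral of `v`.
#' @param interp `"linear"` or `"constant"` inter-sample interpolation.
#' @return Numeric vector `y(times)`.
#' @keywords internal
exp_convolve <- function(values, times, lambda, interp = c("linear", "constant")) {
  interp <- match.arg(interp)
  n <- length(times)
  stopifnot(length(values) == n, n >= 2L, lambda >= 0)
  h <- diff(times)
  if (any(h <= 0)) stop("times must be strictly increasing", call. = FALSE)
  y <- numeric(n)
  lh <- lambda * h
  alpha <- exp(-lh)
  small <- lh < 1e-8
  if (interp == "linear") {
    m <- diff(values) / h
    # exact integral of exp(-lambda(h-s)) * (C_n + m s) over [0, h]
    i0 <- ifelse(small, h * (1 - lh / 2), (1 - alpha) / lambda)
    i1 <- ifelse(small, h^2 / 2 * (1 - lh / 3),
                 h / lambda - (1 - alpha) / lambda^2)
    inc <- values[-n] * i0 + m * i1
  } else {
    i0 <- ifelse(small, h * (1 - lh / 2), (1 - alpha) / lambda)
    inc <- values[-n] * i0
  }
  for (k in seq_len(n - 1L)) y[k + 1L] <- y[k] * alpha[k] + inc[k]
  y
}

#' Forward single-exponential dispersion
#'
#' Applies the dispersion operator of peripheral arterial measurement:
#' convolution with the normalized kernel `(1/tau) exp(-t/tau)`. With
#' `tau <= 0` dispersion is disabled and the curve is returned unchanged.
#'
#' @param values Undispersed samples (kBq/mL).
#' @param times Sample times (s), strictly increasing.
#' @param tau Dispersion time constant (s).
#' @inheritParams exp_convolve
#' @return Dispersed samples on the same grid.
#' @export
disperse_curve <- function(values, times, tau, interp = c("linear", "constant")) {
  interp <- match.arg(interp)
  if (tau <= 0) return(values)
  exp_convolve(values, times, 1 / tau, interp = interp) / tau
}

#' Gamma-variate bolus curve
#'
#' `c(t) = peak_value * (t / peak_time)^shape * exp(shape (1 - t/peak_time))`
#' for `t >= 0`; peaks at `peak_time` with height `peak_value`.
#'
#' @param times Evaluation times (s).
#' @param peak_time Time of peak (s), `> 0`.
#' @param peak_value Peak height (kBq/mL).
#' @param shape Gamma-variate shape (dimensionless, default 3).
#' @return Numeric vector.
#' @export
gamma_variate <- function(times, peak_time, peak_value, shape = 3) {
  stopifnot(peak_time > 0, shape > 0)
  x <- pmax(times, 0) / peak_time
  peak_value * x^shape * exp(shape * (1 - x))
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Average a densely sampled curve over schedule frames
#'
#' Frame value = (1/duration) * integral of the curve over the frame,
#' trapezoidal on the dense grid with exact frame-boundary interpolation.
#'
#' @param times Dense sample times (s) covering the schedule.
#' @param values Curve samples.
#' @param schedule A [frame_schedule()].
#' @return One value per frame.
#' @keywords internal
frame_average <- function(times, values, schedule) {
  f <- stats::approxfun(times, values, rule = 2)
  vapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$start[i]; b <- a + schedule$duration[i]
    grid <- unique(sort(c(a, times[times > a & times < b], b)))
    trapz(grid, f(grid)) / (b - a)
  }, numeric(1))
}
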