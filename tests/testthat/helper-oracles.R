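# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths.

# Frame-averaged 1TCM tissue curve by direct ODE integration (deSolve,
# fine fixed grid), with the plasma input interpolated linearly.
ode_tac_oracle <- function(k1, k2, cp_times, cp_values, schedule,
                           dt = 0.1, t_end = 180) {
  if (cp_times[1] > 0) {
    cp_times <- c(0, cp_times); cp_values <- c(0, cp_values)
  }
  cpf <- stats::approxfun(cp_times, cp_values, rule = 2)
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(
    y = c(C = 0), times = times,
    func = function(t, y, p) list((k1 / 60) * cpf(t) - (k2 / 60) * y[1]),
    method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  ct <- sol[, "C"]
  keep <- schedule$mid < t_end
  vapply(which(keep), function(i) {
    a <- schedule$start[i]; b <- a + schedule$duration[i]
    mean(ct[times >= a & times <= b])
  }, numeric(1))
}

# Closed-form convolution of a rectangle of height A on [a, b] with the
# normalized exponential kernel (1/tau) exp(-t/tau).
rect_dispersion_oracle <- function(t, A, a, b, tau) {
  out <- numeric(length(t))
  mid <- t >= a & t <= b
  post <- t > b
  out[mid] <- A * (1 - exp(-(t[mid] - a) / tau))
  out[post] <- A * (exp(-(t[post] - b) / tau) - exp(-(t[post] - a) / tau))
  out
}

# Recursive flood fill over an 18-connected neighbourhood, set-based;
# independent of the package's BFS labelling.
flood_fill_oracle <- function(mask) {
  d <- dim(mask)
  idx <- which(mask != 0)
  ijk <- arrayInd(idx, d)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  remaining <- stats::setNames(seq_along(idx), key(ijk))
  comp <- array(0L, d)
  lab <- 0L
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[rowSums(abs(off)) > 0 & rowSums(abs(off)) <= 2, ]
  while (length(remaining) > 0L) {
    lab <- lab + 1L
    seed <- remaining[1]
    stack <- idx[seed]
    remaining <- remaining[-1]
    while (length(stack) > 0L) {
      cur <- stack[1]; stack <- stack[-1]
      comp[cur] <- lab
      c_ijk <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        n_ijk <- c_ijk + c(off$dx[r], off$dy[r], off$dz[r])
        if (any(n_ijk < 1) || any(n_ijk > d)) next
        k <- paste(n_ijk[1], n_ijk[2], n_ijk[3])
        if (k %in% names(remaining)) {
          stack <- c(stack, idx[remaining[[k]]])
          remaining <- remaining[names(remaining) != k]
        }
      }
    }
  }
  comp
}

# A small phantom spec shared by tests (noise off unless stated).
tiny_spec <- function(noise_scale = 0, seed = 7, ...) {
  phantom_spec(grid_shape = c(18, 18, 12), noise_scale = noise_scale,
               seed = seed, ...)
}

# Short contiguous schedule covering 0..t seconds in equal frames.
flat_schedule <- function(t_total = 200, n = 40) {
  dur <- rep(t_total / n, n)
  frame_schedule(cumsum(c(0, dur[-n])), dur)
}
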