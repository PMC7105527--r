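#' Configuration for one-tissue-compartment CBF estimation
#'
#' @param extraction Extraction fraction `E` in `K1 = E * CBF / 100`
#'   (default 0.65).
#' @param fit_window Kinetic fit window in seconds (default 0-180, the
#'   initial 21 frames of the default schedule).
#' @param k2_grid Efflux-rate grid (min^-1) for the weighted-integral
#'   lookup; default 200 log-spaced points over 0.001-1.0.
#' @return An object of class `kinetic_config`. The three weight
#'   functions of the integral method are `w1 = 1`, `w2 = t`, `w3 = t^2`
#'   on the fit window.
#' @export
kinetic_config <- function(extraction = 0.65, fit_window = c(0, 180),
                           k2_grid = exp(seq(log(0.001), log(1),
                                             length.out = 200))) {
  stopifnot(extraction > 0, extraction <= 1,
            length(fit_window) == 2L, fit_window[2] > fit_window[1],
            all(diff(k2_grid) > 0))
  structure(list(extraction = extraction, fit_window = fit_window,
                 k2_grid = k2_grid),
            class = "kinetic_config")
}

# Dense time grid for convolving a sampled plasma input. The input is
# treated as piecewise linear; if its first sample is after t = 0 a zero
# sample at t = 0 is prepended (pre-arrival blood activity).
dense_cp_grid <- function(cp, t_end, dt = 0.5) {
  times <- cp$time; vals <- cp$plasma
  if (times[1] > 0) {
    times <- c(0, times); vals <- c(0, vals)
  }
  grid <- sort(unique(c(times[times <= t_end], seq(0, t_end, by = dt), t_end)))
  list(times = grid,
       values = stats::approx(times, vals, xout = grid, rule = 2)$y)
}

#' Frame-averaged one-tissue-compartment tissue curve
#'
#' Evaluates `C(t) = K1 * integral_0^t Cp(s) exp(-k2 (t - s)) ds`
#' (rates in min^-1, times in s) and averages it over the frames of the
#' schedule whose mid-time lies inside the fit window.
#'
#' @param k1,k2 Influx and efflux rate constants (min^-1, >= 0).
#' @param cp An [input_function()]; the plasma channel drives the model.
#' @param schedule A [frame_schedule()].
#' @param fit_window Seconds, default 0-180.
#' @return Numeric vector, one value per frame in the window.
#' @export
model_tac <- function(k1, k2, cp, schedule, fit_window = c(0, 180)) {
  stopifnot(k1 >= 0, k2 >= 0, inherits(cp, "input_function"))
  idx <- frames_in_window(schedule, fit_window)
  if (length(idx) == 0L) stop("no frames inside the fit window", call. = FALSE)
  t_end <- max(schedule$start[idx] + schedule$duration[idx])
  g <- dense_cp_grid(cp, t_end)
  conv <- exp_convolve(g$values, g$times, k2 / 60)
  ct <- (k1 / 60) * conv
  sub <- schedule[idx, , drop = FALSE]
  frame_average(g$times, ct, sub)
}

# Lookup tables of the three-weighted-integral method for a given input
# function and schedule. Because the tissue model is linear in k1 the
# ratio I2/I1 of the t- and 1-weighted integrals depends on k2 only; it
# is tabulated over the k2 grid (and asserted strictly monotone), so a
# measured ratio inverts to k2 by monotone interpolation. D1 and D3 are
# the unit-k1 weighted integrals used to recover k1 and to form the
# third-integral consistency check.
build_wi_lookup <- function(cp, schedule, cfg) {
  idx <- frames_in_window(schedule, cfg$fit_window)
  sub <- schedule[idx, , drop = FALSE]
  dt <- sub$duration; tm <- sub$mid
  k2g <- cfg$k2_grid
  D1 <- D2 <- D3 <- numeric(length(k2g))
  for (i in seq_along(k2g)) {
    m <- model_tac(1, k2g[i], cp, schedule, cfg$fit_window)
    D1[i] <- sum(m * dt)
    D2[i] <- sum(tm * m * dt)
    D3[i] <- sum(tm^2 * m * dt)
  }
  ratio <- D2 / D1
  if (any(diff(ratio) >= 0)) {
    stop("weighted-integral ratio I2/I1 is not strictly monotone in k2; ",
         "input function may be degenerate", call. = FALSE)
  }
  inv <- stats::splinefun(rev(ratio), rev(log(k2g)), method = "monoH.FC")
  d1f <- stats::splinefun(log(k2g), D1, method = "monoH.FC")
  d3f <- stats::splinefun(log(k2g), D3, method = "monoH.FC")
  list(frames = idx, dt = dt, tm = tm,
       k2_grid = k2g, ratio = ratio,
       k2_of_ratio = function(r) exp(inv(r)),
       d1_of_k2 = function(k2) d1f(log(k2)),
       d3_of_k2 = function(k2) d3f(log(k2)),
       ratio_range = range(ratio))
}

#' Weighted-integral estimation of (K1, k2) from a tissue curve
#'
#' Computes the three weighted integrals `I_j = sum_f w_j(t_f) C_f dt_f`
#' with `w = {1, t, t^2}` over the fit-window frames. Since the tissue
#' model is linear in K1, the ratio `I2/I1` depends only on k2 and is
#' inverted through a precomputed monotone lookup; K1 then follows as
#' `I1` divided by the unit-K1 integral at the recovered k2. The third
#' integral serves as a consistency check (`consistency` is the relative
#' deviation of the observed `I3` from its model prediction).
#'
#' @param tac Per-frame tissue activity, aligned with `schedule` (full
#'   length or fit-window frames only).
#' @param cp An [input_function()] (plasma- and dispersion-corrected).
#' @param cfg A [kinetic_config()].
#' @param schedule A [frame_schedule()].
#' @param lookup Optional precomputed lookup (from repeated calls with
#'   the same input function).
#' @return A list: `k1`, `k2` (min^-1), `flag` (TRUE when the measured
#'   ratio fell outside the lookup range and was clamped), `consistency`.
#' @export
fit_weighted_integral <- function(tac, cp, cfg = kinetic_config(),
                                  schedule = default_schedule(),
                                  lookup = NULL) {
  if (is.null(lookup)) lookup <- build_wi_lookup(cp, schedule, cfg)
  nfw <- length(lookup$frames)
  if (length(tac) == nrow(schedule)) tac <- tac[lookup$frames]
  if (length(tac) != nfw) {
    stop(sprintf("tac length %d matches neither the schedule (%d) nor the fit window (%d)",
                 length(tac), nrow(schedule), nfw), call. = FALSE)
  }
  I1 <- sum(tac * lookup$dt)
  I2 <- sum(lookup$tm * tac * lookup$dt)
  I3 <- sum(lookup$tm^2 * tac * lookup$dt)
  if (I1 <= 0 || all(tac == 0)) {
    return(list(k1 = 0, k2 = 0, flag = FALSE, consistency = NA_real_))
  }
  r <- I2 / I1
  flag <- r < lookup$ratio_range[1] || r > lookup$ratio_range[2]
  r <- min(max(r, lookup$ratio_range[1]), lookup$ratio_range[2])
  k2 <- lookup$k2_of_ratio(r)
  k1 <- I1 / lookup$d1_of_k2(k2)
  cons <- I3 / (k1 * lookup$d3_of_k2(k2)) - 1
  if (k1 < 0) { k1 <- 0; flag <- TRUE }
  list(k1 = k1, k2 = k2, flag = flag, consistency = cons)
}

#' Nonlinear least-squares (K1, k2) fit (reference estimator)
#'
#' Direct Levenberg-Marquardt minimization of the frame-domain residual
#' `sum_f (C_f - model_f(K1, k2))^2`, bounded below at zero. Used as the
#' reference against which the weighted-integral estimator is validated.
#'
#' @inheritParams fit_weighted_integral
#' @param init Starting values `c(k1, k2)` in min^-1.
#' @return List: `k1`, `k2`, `converged`, `rss`.
#' @export
fit_nlls <- function(tac, cp, cfg = kinetic_config(),
                     schedule = default_schedule(), init = c(0.2, 0.1)) {
  idx <- frames_in_window(schedule, cfg$fit_window)
  if (length(tac) == nrow(schedule)) tac <- tac[idx]
  stopifnot(length(tac) == length(idx))
  resid_fun <- function(p) {
    tac - model_tac(p[1], p[2], cp, schedule, cfg$fit_window)
  }
  fit <- minpack.lm::nls.lm(par = init, lower = c(0, 1e-6), upper = c(5, 5),
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  list(k1 = fit$par[1], k2 = fit$par[2],
       converged = fit$info %in% 1:4,
       rss = sum(fit$fvec^2))
}

#' Convert a K1 map (or value) to CBF
#'
#' `CBF = 100 * K1 / E` in mL/min/100 g for K1 in min^-1, assuming
#' tissue density 1 g/mL.
#'
#' @param k1 A [parametric_map()] tagged `"K1"` or a numeric vector.
#' @param extraction Extraction fraction (default 0.65).
#' @return Same shape as the input, tagged `"CBF"` for maps.
#' @export
k1_to_cbf <- function(k1, extraction = 0.65) {
  stopifnot(extraction > 0, extraction <= 1)
  if (inherits(k1, "parametric_map")) {
    parametric_map(100 * k1$data / extraction, k1$affine, "CBF")
  } else {
    100 * k1 / extraction
  }
}

#' Voxelwise CBF image from dynamic PET and an input function
#'
#' Applies the weighted-integral (K1, k2) estimator to every voxel inside
#' the brain mask and converts K1 to CBF. Voxels outside the mask, and
#' all-zero voxel series, yield zero. Negative K1 estimates are floored
#' at zero and flagged, as are voxels whose integral ratio fell outside
#' the lookup range.
#'
#' @param dyn A [dynamic_image()].
#' @param cp A plasma- and dispersion-corrected [input_function()].
#' @param cfg A [kinetic_config()].
#' @param brain_mask Logical/0-1 3D array on the image grid, or `NULL`
#'   for all voxels.
#' @return An object of class `kinetic_result`: list with
#'   [parametric_map()]s `k1_map`, `k2_map`, `cbf_map`, a logical
#'   `flag_map`, and the `config`.
#' @export
cbf_image <- function(dyn, cp, cfg = kinetic_config(), brain_mask = NULL) {
  stopifnot(inherits(dyn, "dynamic_image"))
  lookup <- build_wi_lookup(cp, dyn$schedule, cfg)
  d <- dim(dyn$data)
  nvox <- prod(d[1:3])
  if (is.null(brain_mask)) {
    vox <- seq_len(nvox)
  } else {
    if (!all(dim(brain_mask) == d[1:3])) stop("brain mask grid mismatch", call. = FALSE)
    vox <- which(as.vector(brain_mask) != 0)
  }
  flat <- matrix(dyn$data, nvox, d[4])[vox, lookup$frames, drop = FALSE]
  I1 <- as.vector(flat %*% lookup$dt)
  I2 <- as.vector(flat %*% (lookup$tm * lookup$dt))
  k1 <- numeric(length(vox)); k2 <- numeric(length(vox))
  flag <- logical(length(vox))
  live <- I1 > 0 & rowSums(abs(flat)) > 0
  if (any(live)) {
    r <- I2[live] / I1[live]
    out_of_range <- r < lookup$ratio_range[1] | r > lookup$ratio_range[2]
    r <- pmin(pmax(r, lookup$ratio_range[1]), lookup$ratio_range[2])
    k2v <- lookup$k2_of_ratio(r)
    k1v <- I1[live] / lookup$d1_of_k2(k2v)
    neg <- k1v < 0
    k1v[neg] <- 0
    k1[live] <- k1v; k2[live] <- k2v
    flag[live] <- out_of_range | neg
  }
  to_map <- function(vals, quantity) {
    full <- numeric(nvox); full[vox] <- vals
    parametric_map(array(full, d[1:3]), dyn$affine, quantity)
  }
  flag_full <- logical(nvox); flag_full[vox] <- flag
  structure(list(
    k1_map = to_map(k1, "K1"),
    k2_map = to_map(k2, "K1"),
    cbf_map = to_map(k1_to_cbf(k1, cfg$extraction), "CBF"),
    flag_map = array(flag_full, d[1:3]),
    config = cfg
  ), class = "kinetic_result")
}

#' @export
print.kinetic_result <- function(x, ...) {
  cbf <- x$cbf_map$data
  cat(sprintf("<kinetic_result: CBF %dx%dx%d, in-mask mean %.1f mL/min/100 g, %d flagged>\n",
              dim(cbf)[1], dim(cbf)[2], dim(cbf)[3],
              mean(cbf[cbf > 0]), sum(x$flag_map)))
  invisible(x)
}
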