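#' Configuration for ALFF/fALFF computation
#'
#' @param discard_volumes Initial volumes to drop (default 10).
#' @param band Low-frequency band in Hz, inclusive at both edges
#'   (default 0.01-0.08).
#' @param tr Repetition time (s).
#' @param detrend Remove the per-voxel linear trend (default TRUE).
#' @param nuisance_regressors Optional time-by-k numeric matrix (after
#'   volume discard) to residualize against by ordinary least squares,
#'   e.g. externally estimated motion or tissue signals.
#' @return An object of class `falff_config`.
#' @export
falff_config <- function(discard_volumes = 10, band = c(0.01, 0.08),
                         tr = 2.3, detrend = TRUE,
                         nuisance_regressors = NULL) {
  stopifnot(tr > 0, length(band) == 2L, band[1] > 0, band[2] > band[1])
  if (band[2] > 1 / (2 * tr)) {
    stop(sprintf("band upper edge %.3f Hz exceeds Nyquist %.3f Hz",
                 band[2], 1 / (2 * tr)), call. = FALSE)
  }
  structure(list(discard_volumes = as.integer(discard_volumes), band = band,
                 tr = tr, detrend = detrend,
                 nuisance_regressors = nuisance_regressors),
            class = "falff_config")
}

series_matrix <- function(series) {
  d <- dim(series)
  stopifnot(length(d) == 4L)
  matrix(series, prod(d[1:3]), d[4])
}

#' Preprocess a resting-state series for fALFF
#'
#' Drops the initial volumes, removes the per-voxel linear trend, and,
#' if nuisance regressors are supplied, residualizes each voxel series
#' against them (with an intercept) by ordinary least squares.
#'
#' @param series 4D numeric array (x, y, z, time).
#' @param cfg A [falff_config()].
#' @return 4D array with `length(time) - discard_volumes` volumes.
#' @export
preprocess_bold <- function(series, cfg = falff_config()) {
  d <- dim(series)
  stopifnot(length(d) == 4L)
  if (d[4] <= cfg$discard_volumes) {
    stop("series shorter than the number of discarded volumes", call. = FALSE)
  }
  keep <- (cfg$discard_volumes + 1):d[4]
  mat <- series_matrix(series)[, keep, drop = FALSE]
  nt <- length(keep)
  X <- cbind(intercept = rep(1, nt))
  if (cfg$detrend) X <- cbind(X, trend = seq_len(nt))
  if (!is.null(cfg$nuisance_regressors)) {
    R <- as.matrix(cfg$nuisance_regressors)
    if (nrow(R) != nt) {
      stop(sprintf("nuisance regressors have %d rows; need %d", nrow(R), nt),
           call. = FALSE)
    }
    X <- cbind(X, R)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("nuisance regressor matrix is rank deficient", call. = FALSE)
  }
  # residualize all voxels at once: M = I - X (X'X)^-1 X'
  coef <- solve(crossprod(X), crossprod(X, t(mat)))
  res <- t(mat) - X %*% coef
  array(t(res), c(d[1:3], nt))
}

#' ALFF and fALFF maps
#'
#' Per voxel, the amplitude spectrum is the modulus of the DFT over the
#' positive-frequency bins (square root of the periodogram, no taper).
#' ALFF is the sum of amplitudes over bins with frequency inside the
#' band (inclusive edges); fALFF divides it by the amplitude sum over
#' all positive-frequency bins, so fALFF lies in [0, 1]. Zero-variance
#' voxels get fALFF 0 and are flagged.
#'
#' @param series Preprocessed 4D array (see [preprocess_bold()]).
#' @param cfg A [falff_config()] (supplies `tr` and `band`).
#' @param affine Optional 4x4 affine for the output maps.
#' @return List: `alff`, `falff` ([parametric_map()]s), `flag_map`
#'   (logical 3D array of undefined voxels).
#' @export
falff_map <- function(series, cfg = falff_config(), affine = NULL) {
  d <- dim(series)
  stopifnot(length(d) == 4L)
  affine <- affine %||% default_affine()
  n <- d[4]
  half <- floor(n / 2)
  freqs <- (1:half) / (n * cfg$tr)
  inb <- freqs >= cfg$band[1] & freqs <= cfg$band[2]
  if (!any(inb)) stop("no frequency bins inside the band", call. = FALSE)
  mat <- series_matrix(series)
  amp <- Mod(stats::mvfft(t(mat)))[2:(half + 1), , drop = FALSE]
  alff <- colSums(amp[inb, , drop = FALSE])
  total <- colSums(amp)
  flag <- total == 0
  falff <- ifelse(flag, 0, alff / ifelse(flag, 1, total))
  list(alff = parametric_map(array(alff, d[1:3]), affine, "ALFF"),
       falff = parametric_map(array(falff, d[1:3]), affine, "fALFF"),
       flag_map = array(flag, d[1:3]))
}

#' Standardize a map to a subject-level z-score map
#'
#' `(v - mean) / sd` with mean and SD taken over the mask voxels;
#' voxels outside the mask are set to 0.
#'
#' @param map A [parametric_map()].
#' @param mask Logical/0-1 3D array (>= 2 voxels in mask); `NULL` uses
#'   all voxels.
#' @return A [parametric_map()] tagged `"z"`.
#' @export
zscore_map <- function(map, mask = NULL) {
  stopifnot(inherits(map, "parametric_map"))
  if (is.null(mask)) mask <- array(TRUE, dim(map$data))
  if (!all(dim(mask) == dim(map$data))) stop("mask grid mismatch", call. = FALSE)
  inm <- as.vector(mask) != 0
  if (sum(inm) < 2L) stop("mask must contain at least 2 voxels", call. = FALSE)
  v <- as.vector(map$data)
  mu <- mean(v[inm]); sdv <- stats::sd(v[inm])
  if (sdv == 0) stop("zero variance inside mask; z-map undefined", call. = FALSE)
  z <- numeric(length(v))
  z[inm] <- (v[inm] - mu) / sdv
  parametric_map(array(z, dim(map$data)), map$affine, "z")
}
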