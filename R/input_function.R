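#' Arterial input function
#'
#' Sampled whole-blood activity with its plasma-corrected channel. During
#' the initial minutes of a PiB scan the unmetabolized (plasma-available)
#' fraction of whole-blood activity is taken as a fixed multiplicative
#' factor, 0.95 by default, so `plasma = plasma_fraction * whole_blood`
#' at every sample.
#'
#' @param times Sample times (s), strictly increasing.
#' @param whole_blood Whole-blood activity (kBq/mL), same length.
#' @param plasma_fraction Plasma-to-whole-blood factor (default 0.95).
#' @param mask_voxels Optional integer voxel indices the curve was
#'   extracted from (IDIF provenance).
#' @return An object of class `input_function`: a tibble with columns
#'   `time`, `whole_blood`, `plasma`, plus attributes `plasma_fraction`
#'   and `mask_voxels`.
#' @export
input_function <- function(times, whole_blood, plasma_fraction = 0.95,
                           mask_voxels = NULL) {
  times <- as.numeric(times); whole_blood <- as.numeric(whole_blood)
  stopifnot(length(times) == length(whole_blood))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(whole_blood))) stop("non-finite activity values", call. = FALSE)
  out <- tibble::tibble(time = times, whole_blood = whole_blood,
                        plasma = plasma_fraction * whole_blood)
  attr(out, "plasma_fraction") <- plasma_fraction
  attr(out, "mask_voxels") <- mask_voxels
  class(out) <- c("input_function", class(out))
  out
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function: %d samples over %.1f-%.1f s, peak %.3g kBq/mL>\n",
              nrow(x), min(x$time), max(x$time), max(x$whole_blood)))
  invisible(x)
}

#' Write / read an input function as a 3-column CSV
#'
#' Columns `time_s, whole_blood, plasma`.
#' @param f An [input_function()].
#' @param path CSV path.
#' @export
write_input_function <- function(f, path) {
  stopifnot(inherits(f, "input_function"))
  readr::write_csv(tibble::tibble(time_s = f$time, whole_blood = f$whole_blood,
                                  plasma = f$plasma), path)
  invisible(path)
}

#' @rdname write_input_function
#' @export
read_input_function <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  frac <- if (all(tbl$whole_blood == 0)) 0.95 else
    stats::median(tbl$plasma[tbl$whole_blood > 0] / tbl$whole_blood[tbl$whole_blood > 0])
  input_function(tbl$time_s, tbl$whole_blood, plasma_fraction = frac)
}

#' Early-phase average image
#'
#' Duration-weighted mean of the dynamic frames whose mid-time falls in
#' the window (default 10-40 s after injection), used to localize the
#' intracarotid hot voxels for the image-derived input function.
#'
#' @param dyn A [dynamic_image()].
#' @param window Length-2 numeric, `[from, to)` seconds.
#' @return A [parametric_map()] of mean early activity.
#' @export
early_average <- function(dyn, window = c(10, 40)) {
  stopifnot(inherits(dyn, "dynamic_image"))
  idx <- frames_in_window(dyn$schedule, window)
  if (length(idx) == 0L) {
    stop(sprintf("no frame mid-time inside [%g, %g) s", window[1], window[2]),
         call. = FALSE)
  }
  w <- dyn$schedule$duration[idx]
  d <- dim(dyn$data)
  flat <- matrix(dyn$data, prod(d[1:3]), d[4])
  avg <- as.vector(flat[, idx, drop = FALSE] %*% (w / sum(w)))
  parametric_map(array(avg, d[1:3]), dyn$affine, quantity = "activity")
}

#' Extract the IDIF voxel mask
#'
#' Selects the `n_voxels` most intensely radioactive voxels of the early
#' average image inside a search region (typically the intracranial
#' artery label of the parcellation, or a user ROI around the cavernous
#' internal carotid). Ties at the cutoff are broken by ascending voxel
#' index for determinism.
#'
#' @param early A [parametric_map()] from [early_average()].
#' @param search A logical/0-1 3D array, a [parcellation()] with
#'   `search_label`, or an integer vector of candidate voxel indices.
#' @param n_voxels Number of voxels to keep (default 30).
#' @param search_label Label to use when `search` is a parcellation.
#' @return Sorted integer vector of `n_voxels` linear voxel indices.
#' @export
extract_idif_mask <- function(early, search, n_voxels = 30, search_label = NULL) {
  stopifnot(inherits(early, "parametric_map"))
  if (inherits(search, "parcellation")) {
    check_same_grid(early, search)
    if (is.null(search_label)) stop("supply `search_label` with a parcellation", call. = FALSE)
    cand <- which(as.vector(search$labels) == resolve_label(search, search_label))
  } else if (is.array(search)) {
    if (!all(dim(search) == dim(early$data))) stop("search mask grid mismatch", call. = FALSE)
    cand <- which(as.vector(search) != 0)
  } else {
    cand <- as.integer(search)
  }
  if (length(cand) < n_voxels) {
    stop(sprintf("search region has %d voxels, fewer than the %d requested",
                 length(cand), n_voxels), call. = FALSE)
  }
  vals <- as.vector(early$data)[cand]
  ord <- order(-vals, cand)
  sort(cand[ord[seq_len(n_voxels)]])
}

#' Image-derived input function from a voxel mask
#'
#' Per-frame mean activity over the mask voxels, sampled at frame
#' mid-times and truncated to the initial kinetic window (default the
#' first 3 min). The plasma channel is the whole-blood curve scaled by
#' the unmetabolized fraction.
#'
#' @param dyn A [dynamic_image()].
#' @param mask Integer vector of linear voxel indices.
#' @param plasma_fraction Plasma correction factor (default 0.95).
#' @param t_max Truncation time (s, default 180); frames whose mid-time
#'   is `<= t_max` are kept.
#' @return An [input_function()].
#' @export
idif_tac <- function(dyn, mask, plasma_fraction = 0.95, t_max = 180) {
  stopifnot(inherits(dyn, "dynamic_image"))
  mask <- as.integer(mask)
  if (length(mask) == 0L) stop("mask is empty", call. = FALSE)
  d <- dim(dyn$data)
  flat <- matrix(dyn$data, prod(d[1:3]), d[4])
  tac <- colMeans(flat[mask, , drop = FALSE])
  keep <- dyn$schedule$mid <= t_max
  input_function(dyn$schedule$mid[keep], tac[keep],
                 plasma_fraction = plasma_fraction, mask_voxels = mask)
}

#' Correct an input function for arterial dispersion
#'
#' Inverts the single-exponential dispersion of the measured curve to
#' first order: `C_true(t) = C_d(t) + tau * dC_d/dt`, with the
#' derivative taken by central differences on the sample grid (one-sided
#' at the endpoints). Negative corrected values are floored at zero. The
#' fixed default time constant is 4 s.
#'
#' @param f An [input_function()].
#' @param tau Dispersion time constant (s), `>= 0`; 0 is the identity.
#' @return A corrected [input_function()].
#' @export
correct_dispersion <- function(f, tau = 4) {
  stopifnot(inherits(f, "input_function"))
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  if (nrow(f) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (tau == 0) return(f)
  wb <- f$whole_blood
  corrected <- pmax(wb + tau * finite_gradient(wb, f$time), 0)
  input_function(f$time, corrected,
                 plasma_fraction = attr(f, "plasma_fraction"),
                 mask_voxels = attr(f, "mask_voxels"))
}

# central differences on a (possibly non-uniform) grid, one-sided ends
finite_gradient <- function(y, t) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (t[2] - t[1])
  g[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  g
}
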