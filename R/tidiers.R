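#' Tidy a kinetic result into a voxel table
#'
#' @param x A `kinetic_result` from [cbf_image()].
#' @param mask_only Keep only voxels with non-zero K1 or a flag.
#' @param ... Unused.
#' @return A tibble: voxel indices `i, j, k`, `k1`, `k2`, `cbf`, `flag`.
#' @export
tidy.kinetic_result <- function(x, mask_only = TRUE, ...) {
  d <- dim(x$k1_map$data)
  ijk <- arrayInd(seq_len(prod(d)), d)
  out <- tibble::tibble(
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    k1 = as.vector(x$k1_map$data),
    k2 = as.vector(x$k2_map$data),
    cbf = as.vector(x$cbf_map$data),
    flag = as.vector(x$flag_map)
  )
  if (mask_only) out <- dplyr::filter(out, .data$k1 > 0 | .data$flag)
  out
}

#' One-row summary of a kinetic result
#'
#' @param x A `kinetic_result`.
#' @param ... Unused.
#' @return A tibble with in-mask voxel count, mean/SD CBF, mean K1 and
#'   k2, and the flagged-voxel count.
#' @export
glance.kinetic_result <- function(x, ...) {
  cbf <- as.vector(x$cbf_map$data)
  inm <- cbf > 0
  tibble::tibble(
    n_voxels = sum(inm),
    mean_cbf = mean(cbf[inm]),
    sd_cbf = stats::sd(cbf[inm]),
    mean_k1 = mean(x$k1_map$data[inm]),
    mean_k2 = mean(x$k2_map$data[inm]),
    n_flagged = sum(x$flag_map),
    extraction = x$config$extraction
  )
}

#' Tidy a voxelwise cluster result
#'
#' @param x A `cluster_result` from [voxelwise_ttest()].
#' @param ... Unused.
#' @return The retained-cluster tibble (size, peak t, peak coordinates).
#' @export
tidy.cluster_result <- function(x, ...) {
  x$clusters
}

#' One-row summary of a cluster result
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble with thresholds, suprathreshold voxel count and
#'   cluster counts.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    height_p = x$height_p, extent = x$extent,
    n_suprathreshold = sum(x$suprathreshold),
    n_clusters = nrow(x$clusters),
    n_removed = nrow(x$removed),
    max_cluster = if (nrow(x$clusters) > 0) max(x$clusters$size) else 0L
  )
}

#' Tidy a group comparison
#' @param x A `group_comparison` from [group_compare_regions()].
#' @param ... Unused.
#' @return The per-region tibble of group means, SDs and Welch tests.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$regions
}

#' One-row summary of a group comparison
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A tibble with region count and significant-region count.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$regions),
    n_significant = sum(x$regions$significant),
    min_p = min(x$regions$p)
  )
}

#' Turn a fitted result into a tidy tibble
#'
#' Generic with methods for the package's result objects; follows the
#' broom convention (`tidy()` = per-element table, `glance()` = one-row
#' summary).
#'
#' @param x A result object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
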