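#' Regional means over a parcellation
#'
#' Unweighted mean of the map over the voxels of each legend label.
#' Empty labels yield `NA` and are flagged.
#'
#' @param map A [parametric_map()].
#' @param parc A [parcellation()] on the same grid.
#' @return A tibble: `region`, `label`, `n_voxels`, `value`, `flag`.
#' @export
regional_means <- function(map, parc) {
  stopifnot(inherits(map, "parametric_map"), inherits(parc, "parcellation"))
  check_same_grid(map, parc)
  labv <- as.vector(parc$labels)
  vals <- as.vector(map$data)
  purrr::map_dfr(names(parc$legend), function(nm) {
    lab <- as.integer(parc$legend[[nm]])
    vox <- labv == lab
    n <- sum(vox)
    tibble::tibble(region = nm, label = lab, n_voxels = n,
                   value = if (n > 0) mean(vals[vox]) else NA_real_,
                   flag = n == 0)
  })
}

#' Atrophy-style regional z-score
#'
#' `z = (control mean - individual value) / control SD`: values below
#' the control mean give positive z, so larger z means more atrophy (or
#' more reduction) relative to controls.
#'
#' @param value Individual regional value(s).
#' @param control_mean,control_sd Control-group mean and SD
#'   (`control_sd > 0`).
#' @return Numeric z, same length as `value`.
#' @examples
#' vsrad_z(6, control_mean = 10, control_sd = 2)  # +2
#' @export
vsrad_z <- function(value, control_mean, control_sd) {
  if (any(control_sd <= 0)) stop("control SD must be positive", call. = FALSE)
  (control_mean - value) / control_sd
}

#' Region-wise group comparison
#'
#' Per region (x hemisphere x quantity): group means and SDs, Welch
#' two-sample t-test AD vs CTL across subjects, flagged at P < 0.05; plus
#' a one-way ANOVA of value on region within each group x quantity as an
#' across-region heterogeneity summary.
#'
#' @param table Regional table tibble with columns `subject`, `region`,
#'   `value`, optionally `hemisphere` and `quantity`.
#' @param groups Named vector or tibble mapping subject to group
#'   (`AD`/`CTL`): either `c(sub1 = "AD", ...)` or a tibble with columns
#'   `id`/`subject` and `group`.
#' @return An object of class `group_comparison`: list with tibbles
#'   `regions` (per-region Welch t) and `anova` (per group x quantity).
#' @export
group_compare_regions <- function(table, groups) {
  if (is.data.frame(groups)) {
    key <- if ("id" %in% names(groups)) "id" else "subject"
    groups <- stats::setNames(groups$group, groups[[key]])
  }
  tbl <- dplyr::mutate(table, group = unname(groups[.data$subject]))
  if (any(is.na(tbl$group))) stop("subjects missing from group map", call. = FALSE)
  if (!"hemisphere" %in% names(tbl)) tbl$hemisphere <- NA_character_
  if (!"quantity" %in% names(tbl)) tbl$quantity <- NA_character_
  counts <- dplyr::count(dplyr::distinct(tbl, .data$subject, .data$group), .data$group)
  if (any(counts$n < 2L)) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  regions <- tbl |>
    dplyr::group_by(.data$quantity, .data$region, .data$hemisphere) |>
    dplyr::group_modify(function(d, key) {
      a <- d$value[d$group == "AD"]; c <- d$value[d$group == "CTL"]
      tt <- stats::t.test(a, c)
      tibble::tibble(
        mean_ad = mean(a), sd_ad = stats::sd(a), n_ad = length(a),
        mean_ctl = mean(c), sd_ctl = stats::sd(c), n_ctl = length(c),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
        significant = tt$p.value < 0.05
      )
    }) |>
    dplyr::ungroup()
  anova_tbl <- tbl |>
    dplyr::group_by(.data$quantity, .data$group) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$region)) < 2L) {
        return(tibble::tibble(f = NA_real_, df1 = NA_real_, df2 = NA_real_,
                              p = NA_real_))
      }
      fit <- stats::aov(value ~ region, data = d)
      s <- summary(fit)[[1]]
      tibble::tibble(f = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
                     p = s$`Pr(>F)`[1])
    }) |>
    dplyr::ungroup()
  structure(list(regions = regions, anova = anova_tbl),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %d regions, %d significant at P<0.05>\n",
              nrow(x$regions), sum(x$regions$significant)))
  print(x$regions)
  invisible(x)
}

# 18-connectivity neighbourhood offsets (face + edge neighbours)
neighbour_offsets_18 <- function() {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  off[abs(off$dx) + abs(off$dy) + abs(off$dz) <= 2, ]
}

#' Label connected components of a 3D mask
#'
#' Breadth-first labelling under 18-connectivity (voxels sharing a face
#' or an edge are neighbours), the usual convention of neuroimaging
#' cluster software.
#'
#' @param mask Logical/0-1 3D array.
#' @return Integer 3D array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  off <- neighbour_offsets_18()
  comp <- array(0L, d)
  maskv <- as.vector(mask) != 0
  todo <- which(maskv)
  nxt <- 0L
  for (start in todo) {
    if (comp[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    comp[start] <- nxt
    while (length(queue) > 0L) {
      cur <- queue
      queue <- integer(0)
      ijk <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        ni <- ijk[, 1] + off$dx[r]; nj <- ijk[, 2] + off$dy[r]
        nk <- ijk[, 3] + off$dz[r]
        ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
        if (!any(ok)) next
        lin <- ni[ok] + (nj[ok] - 1L) * d[1] + (nk[ok] - 1L) * d[1] * d[2]
        new <- lin[maskv[lin] & comp[lin] == 0L]
        if (length(new) > 0L) {
          new <- unique(new)
          comp[new] <- nxt
          queue <- c(queue, new)
        }
      }
    }
  }
  comp
}

#' Voxelwise two-sample t-map with cluster-extent thresholding
#'
#' Welch two-sample t per voxel (group A minus group B), thresholded at
#' the uncorrected height `p < height_p` (one-sided upper tail by
#' default, matching a directional contrast such as CTL > AD), followed
#' by 18-connectivity component labelling and removal of clusters
#' smaller than `extent` voxels. Optional permutation of group labels
#' yields cluster-level p-values from the null distribution of the
#' maximum cluster size.
#'
#' @param maps_a,maps_b Lists of [parametric_map()]s (or 3D arrays) per
#'   group, all on a common grid; at least 2 per group.
#' @param mask Logical 3D array restricting the analysis; `NULL` = all.
#' @param height_p Uncorrected voxel height threshold (default 0.005).
#' @param extent Minimum cluster size in voxels (default 50).
#' @param alternative `"greater"` (A > B, default) or `"two.sided"`.
#' @param n_perm Number of group-label permutations for cluster-level
#'   p-values (0 disables; use >= 1000 for inference).
#' @param seed Seed for the permutation draw.
#' @return An object of class `cluster_result`: list with `t_map`
#'   ([parametric_map()]), `p_map` (3D array), `suprathreshold` (logical
#'   3D array), `clusters` tibble (`cluster`, `size`, `peak_t`,
#'   `peak_ijk`, `peak_xyz`, and `p_cluster` when permuting), `removed`
#'   tibble of subthreshold-extent clusters, and the thresholds used.
#' @export
voxelwise_ttest <- function(maps_a, maps_b, mask = NULL,
                            height_p = 0.005, extent = 50,
                            alternative = c("greater", "two.sided"),
                            n_perm = 0, seed = 1) {
  alternative <- match.arg(alternative)
  A <- stack_maps(maps_a); B <- stack_maps(maps_b)
  if (ncol(A$mat) < 2L || ncol(B$mat) < 2L) {
    stop("need at least 2 maps per group", call. = FALSE)
  }
  if (!all(A$dim == B$dim)) stop("group grids differ", call. = FALSE)
  d <- A$dim
  if (is.null(mask)) mask <- array(TRUE, d)
  maskv <- as.vector(mask) != 0

  tres <- welch_t_rows(A$mat, B$mat)
  pv <- if (alternative == "greater") {
    stats::pt(tres$t, tres$df, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(tres$t), tres$df, lower.tail = FALSE)
  }
  supra <- maskv & !is.na(pv) & pv < height_p
  comp <- label_components(array(supra, d))
  sizes <- tabulate(comp)
  keep_ids <- which(sizes >= extent)
  cl_tbl <- cluster_table(comp, sizes, tres$t, d, A$affine)
  removed <- dplyr::filter(cl_tbl, !.data$cluster %in% keep_ids)
  clusters <- dplyr::filter(cl_tbl, .data$cluster %in% keep_ids)

  if (n_perm > 0 && nrow(clusters) > 0) {
    null_max <- perm_max_cluster(A$mat, B$mat, maskv, d, height_p, extent = 1,
                                 alternative, n_perm, seed)
    clusters$p_cluster <- vapply(clusters$size, function(s) {
      (1 + sum(null_max >= s)) / (n_perm + 1)
    }, numeric(1))
  }

  keep_mask <- array(comp %in% keep_ids & comp > 0, d)
  structure(list(
    t_map = parametric_map(array(ifelse(is.na(tres$t), 0, tres$t), d),
                           A$affine, "t"),
    p_map = array(pv, d),
    suprathreshold = array(supra, d),
    cluster_mask = keep_mask,
    clusters = clusters, removed = removed,
    height_p = height_p, extent = extent, alternative = alternative,
    n_perm = n_perm
  ), class = "cluster_result")
}

stack_maps <- function(maps) {
  if (inherits(maps, "parametric_map")) maps <- list(maps)
  arrs <- lapply(maps, function(m) if (inherits(m, "parametric_map")) m$data else m)
  d <- dim(arrs[[1]])
  for (a in arrs) {
    if (!all(dim(a) == d)) stop("maps are not on a common grid", call. = FALSE)
  }
  aff <- if (inherits(maps[[1]], "parametric_map")) maps[[1]]$affine else default_affine()
  list(mat = vapply(arrs, as.vector, numeric(prod(d))), dim = d, affine = aff)
}

welch_t_rows <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  t[se2 == 0] <- NA_real_
  list(t = t, df = df)
}

cluster_table <- function(comp, sizes, tvals, d, affine) {
  ids <- which(sizes > 0)
  purrr::map_dfr(ids, function(id) {
    vox <- which(comp == id)
    peak <- vox[which.max(tvals[vox])]
    ijk <- arrayInd(peak, d)
    xyz <- as.vector(affine %*% c(ijk - 1L, 1))[1:3]
    tibble::tibble(cluster = id, size = sizes[id],
                   peak_t = max(tvals[vox], na.rm = TRUE),
                   peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
                   peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3])
  })
}

perm_max_cluster <- function(A, B, maskv, d, height_p, extent, alternative,
                             n_perm, seed) {
  set.seed(seed)
  all_mat <- cbind(A, B)
  na <- ncol(A); n <- ncol(all_mat)
  vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, na)
    tres <- welch_t_rows(all_mat[, idx, drop = FALSE],
                         all_mat[, -idx, drop = FALSE])
    pv <- if (alternative == "greater") {
      stats::pt(tres$t, tres$df, lower.tail = FALSE)
    } else {
      2 * stats::pt(abs(tres$t), tres$df, lower.tail = FALSE)
    }
    supra <- maskv & !is.na(pv) & pv < height_p
    if (!any(supra)) return(0)
    max(tabulate(label_components(array(supra, d))))
  }, numeric(1))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: height p<%g, extent >=%d voxels, %d cluster(s) retained, %d removed>\n",
              x$height_p, x$extent, nrow(x$clusters), nrow(x$removed)))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}
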