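#' Standardized uptake value image
#'
#' `SUV = activity / (injected dose / body weight)`: a voxel whose
#' concentration (kBq/mL, density 1 g/mL) equals the injected dose per
#' gram of body weight maps to 1.
#'
#' @param static A [parametric_map()] of late-frame activity (kBq/mL;
#'   the 50-70 min static image).
#' @param dose_mbq Injected dose (MBq, > 0).
#' @param weight_kg Body weight (kg, > 0).
#' @return A [parametric_map()] tagged `"SUV"`.
#' @export
suv_image <- function(static, dose_mbq, weight_kg) {
  stopifnot(inherits(static, "parametric_map"))
  if (dose_mbq <= 0 || weight_kg <= 0) {
    stop("dose and weight must be positive", call. = FALSE)
  }
  # MBq/kg equals kBq/g, so the ratio is unit-consistent with kBq/mL
  parametric_map(static$data / (dose_mbq / weight_kg), static$affine, "SUV")
}

#' SUV ratio image against a reference region
#'
#' Voxelwise division by the mean SUV over the reference label
#' (cerebellar cortex by default), so the reference region's mean SUVr
#' is exactly 1.
#'
#' @param suv A [parametric_map()] tagged `"SUV"`.
#' @param parc A [parcellation()] on the same grid.
#' @param reference Reference region name or label (default
#'   `"cerebellum"`).
#' @return A [parametric_map()] tagged `"SUVr"`.
#' @export
suvr_image <- function(suv, parc, reference = "cerebellum") {
  stopifnot(inherits(suv, "parametric_map"), inherits(parc, "parcellation"))
  check_same_grid(suv, parc)
  lab <- resolve_label(parc, reference)
  vox <- parc$labels == lab
  if (!any(vox)) stop("reference region is empty", call. = FALSE)
  ref_mean <- mean(suv$data[vox])
  if (ref_mean <= 0) stop("reference-region mean SUV must be positive", call. = FALSE)
  parametric_map(suv$data / ref_mean, suv$affine, "SUVr")
}

resolve_label <- function(parc, region) {
  if (is.character(region)) {
    if (!region %in% names(parc$legend)) {
      stop(sprintf("region '%s' not in parcellation legend", region), call. = FALSE)
    }
    as.integer(parc$legend[[region]])
  } else {
    as.integer(region)
  }
}

#' Gray-to-white-matter SUVr contrast ratio
#'
#' Mean cortical SUVr divided by white-matter SUVr, an index that
#' contrasts cortical amyloid against the myelin-driven white-matter
#' signal (which does not differ between groups).
#'
#' @param regional A regional table (tibble with `region`, `value`, and
#'   optionally `hemisphere`) of SUVr values for one subject.
#' @param gm_regions Character vector of cortical region names (default
#'   the four lobes of both hemispheres).
#' @param wm_region White-matter region name (default `"white_matter"`).
#' @return Single unitless ratio.
#' @export
suvr_ratio <- function(regional, gm_regions = NULL, wm_region = "white_matter") {
  gm_regions <- gm_regions %||% cortical_regions()
  rn <- region_key(regional)
  gm <- regional$value[rn %in% gm_regions]
  wm <- regional$value[rn %in% wm_region]
  if (length(gm) == 0L || length(wm) == 0L) {
    stop("gray- or white-matter regions missing from table", call. = FALSE)
  }
  wm_val <- mean(wm)
  if (wm_val <= 0) stop("white-matter SUVr must be positive", call. = FALSE)
  mean(gm) / wm_val
}

region_key <- function(regional) {
  if ("hemisphere" %in% names(regional) &&
      !any(grepl("_(right|left)$", regional$region))) {
    paste(regional$region, regional$hemisphere, sep = "_")
  } else {
    regional$region
  }
}

#' Mean cortical SUVr for one subject
#'
#' Unweighted mean over the four lobar regions per hemisphere, then
#' averaged across hemispheres (the averaging scheme is configurable via
#' `gm_regions`).
#'
#' @inheritParams suvr_ratio
#' @return Single unitless value.
#' @export
cortical_suvr_mean <- function(regional, gm_regions = NULL) {
  gm_regions <- gm_regions %||% cortical_regions()
  rn <- region_key(regional)
  gm <- regional$value[rn %in% gm_regions]
  if (length(gm) == 0L) stop("no cortical regions in table", call. = FALSE)
  mean(gm)
}

#' Correlations of uptake measures with cognition
#'
#' Pearson correlations (with two-sided p-values) between MMSE and each
#' supplied uptake measure: cortical SUVr mean, visual score, and the
#' GM/WM SUVr ratio. Rows with missing values are dropped pairwise;
#' pairs with zero variance are flagged with `NA` correlations.
#'
#' @param subjects Subject tibble with `id`, `mmse`, `visual_score`.
#' @param measures Tibble with `subject` and one or more of
#'   `cortical_suvr`, `suvr_ratio` columns (e.g. from the uptake stage).
#' @return A tibble: `measure`, `n`, `r`, `p`, `flag`.
#' @export
score_correlations <- function(subjects, measures = NULL) {
  tbl <- subjects
  if (!is.null(measures)) {
    tbl <- dplyr::left_join(tbl, measures, by = c(id = "subject"))
  }
  candidates <- c(cortical_suvr = "cortical_suvr",
                  visual_score = "visual_score",
                  suvr_ratio = "suvr_ratio")
  candidates <- candidates[candidates %in% names(tbl)]
  purrr::map_dfr(candidates, function(col) {
    ok <- !is.na(tbl$mmse) & !is.na(tbl[[col]])
    n <- sum(ok)
    if (n < 3L) stop("need at least 3 subjects with complete pairs", call. = FALSE)
    x <- tbl$mmse[ok]; y <- as.numeric(tbl[[col]][ok])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(measure = col, n = n, r = NA_real_, p = NA_real_,
                            flag = TRUE))
    }
    ct <- stats::cor.test(y, x, method = "pearson")
    tibble::tibble(measure = col, n = n, r = unname(ct$estimate),
                   p = ct$p.value, flag = FALSE)
  })
}
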