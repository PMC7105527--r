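#' Study configuration
#'
#' Collects every tunable of the synthetic end-to-end study. All numeric
#' defaults are the pipeline's standard operating constants: plasma
#' fraction 0.95, dispersion 4 s, extraction 0.65, 30 IDIF voxels,
#' 10-40 s early window, 0-180 s fit window, 10 discarded volumes,
#' 0.01-0.08 Hz band, height P 0.005, extent 50 voxels.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed; all stage randomness derives from it.
#' @param n_ad,n_ctl Cohort sizes (defaults 27 and 16).
#' @param grid_shape Phantom grid (default 24 x 24 x 12).
#' @param noise_scale Phantom noise multiplier.
#' @param dispersion_tau Dispersion time constant (s).
#' @param plasma_fraction Plasma correction factor.
#' @param extraction Extraction fraction.
#' @param idif_n_voxels IDIF mask size.
#' @param idif_window Early-average window (s).
#' @param fit_window Kinetic fit window (s).
#' @param discard_volumes,band,tr,n_volumes Resting-state settings.
#' @param height_p,extent,n_perm Voxelwise statistics settings.
#' @param stages Character vector of stages to run, in dependency order.
#' @return An object of class `study_config` (a named list).
#' @export
study_config <- function(out_dir, seed = 1, n_ad = 27, n_ctl = 16,
                         grid_shape = c(24, 24, 12), noise_scale = 0.1,
                         dispersion_tau = 4, plasma_fraction = 0.95,
                         extraction = 0.65, idif_n_voxels = 30,
                         idif_window = c(10, 40), fit_window = c(0, 180),
                         discard_volumes = 10, band = c(0.01, 0.08),
                         tr = 2.3, n_volumes = 201,
                         height_p = 0.005, extent = 50, n_perm = 1000,
                         stages = c("phantom", "idif", "cbf", "suvr",
                                    "falff", "stats")) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_ad = n_ad, n_ctl = n_ctl,
              grid_shape = grid_shape, noise_scale = noise_scale,
              dispersion_tau = dispersion_tau,
              plasma_fraction = plasma_fraction, extraction = extraction,
              idif_n_voxels = idif_n_voxels, idif_window = idif_window,
              fit_window = fit_window, discard_volumes = discard_volumes,
              band = band, tr = tr, n_volumes = n_volumes,
              height_p = height_p, extent = extent, n_perm = n_perm,
              stages = stages)
  class(cfg) <- "study_config"
  cfg
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop("config must set out_dir", call. = FALSE)
  do.call(study_config, y)
}

#' @rdname read_study_config
#' @param config A [study_config()].
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_file <- function(cfg, ...) file.path(cfg$out_dir, ...)

require_stage_inputs <- function(cfg, stage, files, produced_by) {
  missing <- files[!file.exists(stage_file(cfg, files))]
  if (length(missing) > 0L) {
    stop(sprintf("stage '%s' requires %s (produced by stage '%s'); run that stage first",
                 stage, paste(missing, collapse = ", "), produced_by),
         call. = FALSE)
  }
}

#' Run the synthetic study end to end
#'
#' Executes the requested stages in dependency order: `phantom`
#' (synthetic dynamic PET, per-subject static PET, resting-state series,
#' subject table), `idif` (early average, hottest-voxel mask, dispersion-
#' and plasma-corrected input function), `cbf` (voxelwise weighted-
#' integral K1 and CBF), `suvr` (per-subject SUV/SUVr maps, regional
#' table, GM/WM ratio), `falff` (preprocessing, ALFF/fALFF, z-map) and
#' `stats` (regional group comparisons, cognition correlations,
#' voxelwise cluster-thresholded t-map). Writes a JSON manifest with the
#' seed, configuration and md5 checksum of every output; a rerun with
#' the same configuration and seed reproduces all checksums.
#'
#' @param config A [study_config()].
#' @param quiet Suppress per-stage messages.
#' @return The manifest (list), invisibly. Also written to
#'   `manifest.json` in the output directory.
#' @export
run_study <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()

  record <- function(stage, files) {
    paths <- stage_file(cfg, files)
    outputs[[stage]] <<- list(
      files = as.list(stats::setNames(unname(tools::md5sum(paths)), files)))
  }

  if ("phantom" %in% cfg$stages) {
    say("stage phantom")
    run_stage_phantom(cfg)
    record("phantom", phantom_outputs(cfg))
  }
  if ("idif" %in% cfg$stages) {
    say("stage idif")
    require_stage_inputs(cfg, "idif", c("dynamic.nii", "dynamic.json",
                                        "parcellation.nii"), "phantom")
    run_stage_idif(cfg)
    record("idif", c("idif_mask.nii", "input_function.csv"))
  }
  if ("cbf" %in% cfg$stages) {
    say("stage cbf")
    require_stage_inputs(cfg, "cbf", c("dynamic.nii", "input_function.csv",
                                       "parcellation.nii"), "idif")
    run_stage_cbf(cfg)
    record("cbf", c("k1.nii", "cbf.nii", "cbf_regional.csv"))
  }
  if ("suvr" %in% cfg$stages) {
    say("stage suvr")
    require_stage_inputs(cfg, "suvr", c("subjects.csv", "parcellation.nii"),
                         "phantom")
    run_stage_suvr(cfg)
    record("suvr", c("suvr_regional.csv", "uptake_measures.csv"))
  }
  if ("falff" %in% cfg$stages) {
    say("stage falff")
    require_stage_inputs(cfg, "falff", "bold.nii", "phantom")
    run_stage_falff(cfg)
    record("falff", c("falff.nii", "falff_z.nii"))
  }
  if ("stats" %in% cfg$stages) {
    say("stage stats")
    require_stage_inputs(cfg, "stats", c("subjects.csv", "suvr_regional.csv",
                                         "uptake_measures.csv"), "suvr")
    run_stage_stats(cfg)
    record("stats", c("group_stats.csv", "cbf_group_stats.csv",
                      "correlations.csv", "clusters.csv"))
  }

  manifest <- list(
    package = "pibflow",
    seed = cfg$seed,
    config = unclass(cfg),
    stages = outputs
  )
  jsonlite::write_json(manifest, stage_file(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %d stage(s) in %.1f s", length(outputs),
      as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  invisible(manifest)
}

phantom_outputs <- function(cfg) {
  subs <- make_subjects(cfg$n_ad, cfg$n_ctl, seed = cfg$seed)
  c("dynamic.nii", "dynamic.json", "parcellation.nii", "parcellation.json",
    "subjects.csv", "bold.nii",
    sprintf("static_%s.nii", subs$id))
}

phantom_spec_from_config <- function(cfg, group = "CTL") {
  phantom_spec(grid_shape = cfg$grid_shape, group = group,
               dispersion_tau = cfg$dispersion_tau,
               extraction = cfg$extraction,
               noise_scale = cfg$noise_scale, seed = cfg$seed)
}

run_stage_phantom <- function(cfg) {
  spec <- phantom_spec_from_config(cfg)
  ph <- make_dynamic_pet(spec)
  write_dynamic(ph$image, stage_file(cfg, "dynamic.nii"))
  write_parcellation(ph$parcellation, stage_file(cfg, "parcellation.nii"))
  write_map(ph$truth$true_cbf_map, stage_file(cfg, "true_cbf.nii"))
  subs <- make_subjects(cfg$n_ad, cfg$n_ctl, seed = cfg$seed)
  write_subjects(subs, stage_file(cfg, "subjects.csv"))
  for (i in seq_len(nrow(subs))) {
    sspec <- phantom_spec_from_config(cfg, group = subs$group[i])
    st <- make_static_pet(sspec, subs$dose_mbq[i], subs$weight_kg[i],
                          suvr_scale = subs$suvr_scale[i],
                          seed = cfg$seed + i)
    write_map(st$image, stage_file(cfg, sprintf("static_%s.nii", subs$id[i])))
  }
  bold <- make_bold_series(n_volumes = cfg$n_volumes, tr = cfg$tr,
                           seed = cfg$seed)
  img <- as_nifti_with_affine(bold$series, bold$affine)
  RNifti::writeNifti(img, stage_file(cfg, "bold.nii"), datatype = "float")
  invisible(NULL)
}

run_stage_idif <- function(cfg) {
  dyn <- read_dynamic(stage_file(cfg, "dynamic.nii"))
  parc <- read_parcellation(stage_file(cfg, "parcellation.nii"))
  early <- early_average(dyn, cfg$idif_window)
  mask <- extract_idif_mask(early, parc, n_voxels = cfg$idif_n_voxels,
                            search_label = "artery")
  tac <- idif_tac(dyn, mask, plasma_fraction = cfg$plasma_fraction)
  corrected <- correct_dispersion(tac, tau = cfg$dispersion_tau)
  mvol <- array(0, dim(parc$labels)); mvol[mask] <- 1
  write_map(parametric_map(mvol, parc$affine, "activity"),
            stage_file(cfg, "idif_mask.nii"))
  write_input_function(corrected, stage_file(cfg, "input_function.csv"))
  invisible(NULL)
}

run_stage_cbf <- function(cfg) {
  dyn <- read_dynamic(stage_file(cfg, "dynamic.nii"))
  parc <- read_parcellation(stage_file(cfg, "parcellation.nii"))
  cp <- read_input_function(stage_file(cfg, "input_function.csv"))
  kcfg <- kinetic_config(extraction = cfg$extraction,
                         fit_window = cfg$fit_window)
  tissue_mask <- parc$labels > 0 & parc$labels != parc$legend[["artery"]]
  res <- cbf_image(dyn, cp, kcfg, brain_mask = tissue_mask)
  write_map(res$k1_map, stage_file(cfg, "k1.nii"))
  write_map(res$cbf_map, stage_file(cfg, "cbf.nii"))
  readr::write_csv(regional_means(res$cbf_map, parc),
                   stage_file(cfg, "cbf_regional.csv"))
  invisible(NULL)
}

run_stage_suvr <- function(cfg) {
  subs <- read_subjects(stage_file(cfg, "subjects.csv"))
  parc <- read_parcellation(stage_file(cfg, "parcellation.nii"))
  regional <- list(); measures <- list()
  for (i in seq_len(nrow(subs))) {
    static <- read_map(stage_file(cfg, sprintf("static_%s.nii", subs$id[i])))
    suv <- suv_image(static, subs$dose_mbq[i], subs$weight_kg[i])
    suvr <- suvr_image(suv, parc, reference = "cerebellum")
    write_map(suvr, stage_file(cfg, sprintf("suvr_%s.nii", subs$id[i])))
    rm_tbl <- regional_means(suvr, parc) |>
      dplyr::filter(.data$region != "artery") |>
      dplyr::transmute(subject = subs$id[i], region = .data$region,
                       quantity = "SUVr", value = .data$value)
    regional[[i]] <- rm_tbl
    measures[[i]] <- tibble::tibble(
      subject = subs$id[i],
      cortical_suvr = cortical_suvr_mean(rm_tbl),
      suvr_ratio = suvr_ratio(rm_tbl))
  }
  readr::write_csv(dplyr::bind_rows(regional),
                   stage_file(cfg, "suvr_regional.csv"))
  readr::write_csv(dplyr::bind_rows(measures),
                   stage_file(cfg, "uptake_measures.csv"))
  invisible(NULL)
}

run_stage_falff <- function(cfg) {
  img <- RNifti::readNifti(stage_file(cfg, "bold.nii"))
  series <- array(as.numeric(img), dim = dim(img))
  if (length(dim(series)) != 4L) {
    stop("stage 'falff' needs a 4D resting-state series at bold.nii", call. = FALSE)
  }
  fcfg <- falff_config(discard_volumes = cfg$discard_volumes,
                       band = cfg$band, tr = cfg$tr)
  pre <- preprocess_bold(series, fcfg)
  maps <- falff_map(pre, fcfg, affine = RNifti::xform(img))
  z <- zscore_map(maps$falff)
  write_map(maps$falff, stage_file(cfg, "falff.nii"))
  write_map(z, stage_file(cfg, "falff_z.nii"))
  invisible(NULL)
}

run_stage_stats <- function(cfg) {
  subs <- read_subjects(stage_file(cfg, "subjects.csv"))
  regional <- readr::read_csv(stage_file(cfg, "suvr_regional.csv"),
                              show_col_types = FALSE)
  measures <- readr::read_csv(stage_file(cfg, "uptake_measures.csv"),
                              show_col_types = FALSE)
  lobar <- dplyr::filter(regional, .data$region %in% cortical_regions())
  gc_suvr <- group_compare_regions(lobar, subs)
  readr::write_csv(gc_suvr$regions, stage_file(cfg, "group_stats.csv"))
  cbf_cohort <- make_regional_cohort(subs, "CBF", seed = cfg$seed)
  gc_cbf <- group_compare_regions(cbf_cohort, subs)
  readr::write_csv(gc_cbf$regions, stage_file(cfg, "cbf_group_stats.csv"))
  cors <- score_correlations(subs, measures)
  readr::write_csv(cors, stage_file(cfg, "correlations.csv"))
  parc <- read_parcellation(stage_file(cfg, "parcellation.nii"))
  tissue_mask <- parc$labels > 0 & parc$labels != parc$legend[["artery"]]
  maps <- lapply(subs$id, function(id) {
    read_map(stage_file(cfg, sprintf("suvr_%s.nii", id)), "SUVr")
  })
  res <- voxelwise_ttest(maps[subs$group == "AD"], maps[subs$group == "CTL"],
                         mask = tissue_mask, height_p = cfg$height_p,
                         extent = cfg$extent, n_perm = cfg$n_perm,
                         seed = cfg$seed)
  readr::write_csv(res$clusters, stage_file(cfg, "clusters.csv"))
  write_map(res$t_map, stage_file(cfg, "t_map.nii"))
  invisible(NULL)
}

#' Build the study report from a completed manifest
#'
#' Collects the regional group table (lobe x hemisphere x quantity, mean
#' +/- SD per group with the Welch test), the cognition correlation
#' panel, and the cluster table into one report, written as
#' `report.json` (and returned). Regenerating the report from an
#' unchanged manifest is byte-identical. Missing stages are reported as
#' gaps rather than errors.
#'
#' @param out_dir Study output directory containing `manifest.json`.
#' @return A list of tibbles (`regional`, `cbf_regional`, `correlations`,
#'   `clusters`, `gaps`), invisibly; written to `report.json`.
#' @export
make_report <- function(out_dir) {
  man_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in out_dir", call. = FALSE)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  gaps <- character(0)
  grab <- function(file, stage) {
    p <- file.path(out_dir, file)
    if (!file.exists(p)) {
      gaps <<- c(gaps, sprintf("stage '%s' output %s missing", stage, file))
      return(NULL)
    }
    readr::read_csv(p, show_col_types = FALSE)
  }
  group_stats <- grab("group_stats.csv", "stats")
  cbf_stats <- grab("cbf_group_stats.csv", "stats")
  cors <- grab("correlations.csv", "stats")
  clusters <- grab("clusters.csv", "stats")
  shape <- function(tbl, quantity) {
    if (is.null(tbl)) return(NULL)
    tbl |>
      dplyr::mutate(quantity = quantity) |>
      dplyr::select(dplyr::any_of(c("quantity", "region", "hemisphere",
                                    "mean_ctl", "sd_ctl", "mean_ad", "sd_ad",
                                    "t", "p", "significant")))
  }
  report <- list(
    seed = manifest$seed,
    regional = shape(group_stats, "SUVr"),
    cbf_regional = shape(cbf_stats, "CBF"),
    correlations = cors,
    clusters = clusters,
    gaps = as.list(gaps)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
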