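#' Specification of the synthetic PET/MRI phantom
#'
#' Defines the digital phantom geometry and ground-truth physiology used
#' to validate the pipeline end to end: a block parcellation with four
#' cortical lobes per hemisphere, cerebellar cortex (the SUVr reference),
#' central white matter and a bright intracranial-artery blob; regional
#' CBF seeds (mL/min/100 g) at the healthy-control operating points of
#' [reference_regional_values()]; regional SUVr seeds for the requested
#' group; one-tissue-compartment efflux rates; and the arterial
#' dispersion time constant.
#'
#' Tissue influx is tied to flow by `K1 = extraction * CBF / 100`
#' (min^-1, tissue density 1 g/mL), with a default extraction fraction
#' of 0.65.
#'
#' @param grid_shape Integer length-3 voxel grid (default 24 x 24 x 12).
#' @param voxel_size Isotropic voxel edge in mm (default 2).
#' @param group `"CTL"` or `"AD"`: which group's SUVr seeds to use.
#' @param region_cbf Named CBF vector (mL/min/100 g) over tissue regions;
#'   defaults to the CTL seeds (cerebellum hemisphere-averaged, white
#'   matter 22).
#' @param region_suvr Named SUVr vector; defaults to the group's lobar
#'   seeds with cerebellum 1 (reference) and white matter 1.6.
#' @param k2_per_region Named efflux-rate vector (min^-1); defaults
#'   0.10 (cortex), 0.12 (cerebellum), 0.06 (white matter).
#' @param dispersion_tau Arterial dispersion time constant (s, default 4).
#' @param extraction Extraction fraction linking K1 to CBF (default 0.65).
#' @param noise_scale Unitless noise multiplier (>= 0); frame noise SD is
#'   `noise_scale * sqrt(activity / frame_duration)`.
#' @param seed Integer random seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 12), voxel_size = 2,
                         group = c("CTL", "AD"),
                         region_cbf = NULL, region_suvr = NULL,
                         k2_per_region = NULL,
                         dispersion_tau = 4, extraction = 0.65,
                         noise_scale = 0.1, seed = 42) {
  group <- match.arg(group)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            voxel_size > 0, extraction > 0, extraction <= 1,
            noise_scale >= 0)
  ref <- reference_regional_values()
  lobes <- cortical_regions()
  if (is.null(region_cbf)) {
    ctl <- dplyr::filter(ref, .data$quantity == "CBF", .data$group == "CTL")
    cbf <- stats::setNames(
      ctl$mean[match(lobes, paste(ctl$region, ctl$hemisphere, sep = "_"))], lobes)
    cbf["cerebellum"] <- mean(ctl$mean[ctl$region == "cerebellum"])
    cbf["white_matter"] <- 22
    region_cbf <- cbf
  }
  if (is.null(region_suvr)) {
    sv <- dplyr::filter(ref, .data$quantity == "SUVr", .data$group == !!group)
    suvr <- stats::setNames(
      sv$mean[match(lobes, paste(sv$region, sv$hemisphere, sep = "_"))], lobes)
    suvr["cerebellum"] <- 1
    suvr["white_matter"] <- 1.6
    region_suvr <- suvr
  }
  if (is.null(k2_per_region)) {
    k2_per_region <- stats::setNames(rep(0.10, length(lobes)), lobes)
    k2_per_region["cerebellum"] <- 0.12
    k2_per_region["white_matter"] <- 0.06
  }
  tissue <- phantom_tissue_regions()
  for (nm in list(region_cbf, region_suvr, k2_per_region)) {
    miss <- setdiff(tissue, names(nm))
    if (length(miss) > 0L) {
      stop(sprintf("missing regions: %s", paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  if (any(region_cbf[tissue] <= 0)) stop("all CBF seeds must be positive", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 group = group,
                 region_cbf = region_cbf, region_suvr = region_suvr,
                 k2_per_region = k2_per_region,
                 dispersion_tau = dispersion_tau, extraction = extraction,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_tissue_regions <- function() {
  c(cortical_regions(), "cerebellum", "white_matter")
}

phantom_legend <- function() {
  stats::setNames(seq_len(11L),
                  c(phantom_tissue_regions(), "artery"))
}

#' Build the phantom's block parcellation
#'
#' Upper two-thirds of the slab: four anterior-posterior lobar bands split
#' into right/left hemispheres, with a central white-matter core. Lower
#' third: cerebellar cortex posteriorly and a small bright artery blob
#' anteriorly (disjoint from all tissue labels). Label 0 is background.
#'
#' @param spec A [phantom_spec()].
#' @return A [parcellation()].
#' @export
phantom_parcellation <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  lab <- array(0L, d)
  leg <- phantom_legend()
  zc <- floor(d[3] / 3)
  upper <- (zc + 1):d[3]
  band <- function(i) {
    lo <- floor((i - 1) * d[2] / 4) + 1
    hi <- floor(i * d[2] / 4)
    lo:hi
  }
  right <- 1:floor(d[1] / 2)
  left <- (floor(d[1] / 2) + 1):d[1]
  lobes4 <- c("frontal", "temporal", "parietal", "occipital")
  for (i in 1:4) {
    lab[right, band(i), upper] <- leg[[paste0(lobes4[i], "_right")]]
    lab[left, band(i), upper] <- leg[[paste0(lobes4[i], "_left")]]
  }
  cx <- round(d[1] / 2); cy <- round(d[2] / 2)
  wm_x <- max(1, cx - floor(d[1] / 6)):min(d[1], cx + floor(d[1] / 6))
  wm_y <- max(1, cy - floor(d[2] / 6)):min(d[2], cy + floor(d[2] / 6))
  lab[wm_x, wm_y, upper] <- leg[["white_matter"]]
  lower <- 1:zc
  lab[, (floor(d[2] / 2) + 1):d[2], lower] <- leg[["cerebellum"]]
  # artery blob spans the lower slab so the default grid holds >= 30 voxels
  ax <- cx + (-1:1); ay <- max(2, floor(d[2] / 4)) + (-1:1)
  lab[ax, ay, lower] <- leg[["artery"]]
  parcellation(lab, leg, default_affine(rep(spec$voxel_size, 3)))
}

#' Synthetic arterial bolus and its dispersed counterpart
#'
#' Generates a gamma-variate whole-blood bolus on a dense grid and the
#' same curve passed through the single-exponential dispersion kernel
#' `(1/tau) exp(-t/tau)`. A non-positive `tau` disables dispersion.
#'
#' @param peak_time Bolus peak time (s, > 0; default 25).
#' @param peak_value Bolus peak (kBq/mL, default 100).
#' @param tau Dispersion time constant (s, default 4).
#' @param dt Grid spacing (s, <= 1; default 1).
#' @param t_max End of grid (s, default 180).
#' @param plasma_fraction Plasma correction factor for both channels.
#' @return List with [input_function()] elements `undispersed` and
#'   `dispersed` on the same grid.
#' @export
make_input_function <- function(peak_time = 25, peak_value = 100, tau = 4,
                                dt = 1, t_max = 180, plasma_fraction = 0.95) {
  stopifnot(peak_time > 0, dt > 0, dt <= 1, t_max > peak_time)
  times <- seq(0, t_max, by = dt)
  wb <- gamma_variate(times, peak_time, peak_value)
  disp <- disperse_curve(wb, times, tau)
  list(undispersed = input_function(times, wb, plasma_fraction),
       dispersed = input_function(times, disp, plasma_fraction))
}

#' Generate a synthetic dynamic PET acquisition with ground truth
#'
#' Voxel time-activity curves follow the one-tissue compartment model
#' `C(t) = K1 * integral Cp(s) exp(-k2 (t - s)) ds`, frame-averaged over
#' the schedule, with region-specific `K1 = extraction * CBF / 100` and
#' `k2`. Artery voxels carry the dispersed whole-blood curve. Additive
#' Gaussian noise has SD `noise_scale * sqrt(C / frame_duration)`.
#' Activity is decay-corrected by construction.
#'
#' @param spec A [phantom_spec()].
#' @param schedule A [frame_schedule()] covering at least 0-180 s.
#' @param input Optional list as returned by [make_input_function()];
#'   defaults to the standard bolus extended over the full schedule.
#' @return List with elements `image` ([dynamic_image()]),
#'   `parcellation`, and `truth` (list: `true_input`, `dispersed_input`,
#'   `true_k1_map`, `true_cbf_map`, `region_tacs` tibble).
#' @export
make_dynamic_pet <- function(spec, schedule = default_schedule(), input = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  total <- schedule_total(schedule)
  if (total < 180) {
    stop("schedule must cover at least 0-180 s for the kinetic window", call. = FALSE)
  }
  if (is.null(input)) {
    input <- make_input_function(tau = spec$dispersion_tau, t_max = total)
  }
  parc <- phantom_parcellation(spec)
  leg <- parc$legend
  d <- spec$grid_shape
  nf <- nrow(schedule)
  E <- spec$extraction

  tissue <- phantom_tissue_regions()
  k1_reg <- E * spec$region_cbf[tissue] / 100
  tac_tbl <- purrr::map_dfr(tissue, function(nm) {
    tac <- model_tac(k1_reg[[nm]], spec$k2_per_region[[nm]],
                     input$undispersed, schedule, fit_window = c(0, total))
    tibble::tibble(region = nm, frame = schedule$frame, mid = schedule$mid,
                   k1 = k1_reg[[nm]], value = tac)
  })
  artery_tac <- frame_average(input$dispersed$time, input$dispersed$whole_blood,
                              schedule)

  data <- array(0, c(d, nf))
  labv <- as.vector(parc$labels)
  nvox <- prod(d)
  for (nm in tissue) {
    vox <- which(labv == leg[[nm]])
    tac <- tac_tbl$value[tac_tbl$region == nm]
    for (f in seq_len(nf)) data[vox + (f - 1L) * nvox] <- tac[f]
  }
  art <- which(labv == leg[["artery"]])
  for (f in seq_len(nf)) data[art + (f - 1L) * nvox] <- artery_tac[f]

  if (spec$noise_scale > 0) {
    set.seed(spec$seed)
    sdv <- spec$noise_scale *
      sqrt(pmax(data, 0) / rep(schedule$duration, each = nvox))
    data <- data + stats::rnorm(length(data), sd = as.vector(sdv))
  }

  k1_map <- array(0, d); cbf_map <- array(0, d)
  for (nm in tissue) {
    vox <- which(labv == leg[[nm]])
    k1_map[vox] <- k1_reg[[nm]]
    cbf_map[vox] <- spec$region_cbf[[nm]]
  }
  aff <- parc$affine
  list(
    image = dynamic_image(data, aff, schedule),
    parcellation = parc,
    truth = list(
      true_input = input$undispersed,
      dispersed_input = input$dispersed,
      true_k1_map = parametric_map(k1_map, aff, "K1"),
      true_cbf_map = parametric_map(cbf_map, aff, "CBF"),
      region_tacs = tac_tbl
    )
  )
}

#' Generate a synthetic late-frame static PET image
#'
#' Emulates the 50-70 min static acquisition: voxel activity equals the
#' regional SUVr seed times a reference-region SUV level, scaled by
#' injected dose per body weight, with reconstruction-style noise. The
#' cortical lobes are additionally multiplied by `suvr_scale` so
#' per-subject amyloid burden can be varied while the cerebellar
#' reference and white matter stay fixed.
#'
#' @param spec A [phantom_spec()].
#' @param dose_mbq Injected dose (MBq).
#' @param weight_kg Body weight (kg).
#' @param suvr_scale Cortical amyloid multiplier (default 1).
#' @param reference_suv SUV of the cerebellar reference region (default 1.2).
#' @param seed Random seed for the noise draw.
#' @return List with `image` (activity [parametric_map()]), `true_suv`
#'   map and the `parcellation`.
#' @export
make_static_pet <- function(spec, dose_mbq, weight_kg, suvr_scale = 1,
                            reference_suv = 1.2, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), dose_mbq > 0, weight_kg > 0)
  parc <- phantom_parcellation(spec)
  leg <- parc$legend
  suv <- array(0, spec$grid_shape)
  labv <- as.vector(parc$labels)
  for (nm in phantom_tissue_regions()) {
    scale <- if (nm %in% cortical_regions()) suvr_scale else 1
    suv[labv == leg[[nm]]] <- spec$region_suvr[[nm]] * reference_suv * scale
  }
  activity <- suv * (dose_mbq / weight_kg)
  if (spec$noise_scale > 0) {
    set.seed(seed)
    sdv <- spec$noise_scale * sqrt(pmax(activity, 0) / 1200)
    activity <- activity + stats::rnorm(length(activity), sd = as.vector(sdv))
  }
  aff <- parc$affine
  list(image = parametric_map(array(activity, spec$grid_shape), aff, "activity"),
       true_suv = parametric_map(suv, aff, "SUV"),
       parcellation = parc)
}

#' Generate a BOLD-like resting-state series with known fALFF target
#'
#' Each voxel's time course is a sum of sinusoids at fixed frequencies
#' inside the 0.01-0.08 Hz band (snapped to the series' DFT grid so the
#' emitted power sits exactly on in-band bins; random phase per voxel)
#' scaled by
#' `low_freq_amp`, plus white noise scaled by `broadband_amp`, plus an
#' optional linear trend. The recorded per-voxel target fALFF is the
#' expected amplitude-spectrum band fraction: exact for the two limiting
#' cases (pure in-band signal; pure white noise, where it equals the
#' band's share of spectral bins) and a first-order expectation when
#' both components are present.
#'
#' @param n_volumes Number of volumes (>= 20; default 201).
#' @param tr Repetition time (s, > 0; default 2.3).
#' @param low_freq_amp Amplitude of each in-band sinusoid (a.u.).
#' @param broadband_amp White-noise SD (a.u.).
#' @param seed Integer seed.
#' @param grid_shape Voxel grid (default 8 x 8 x 4).
#' @param trend_slope Linear trend slope (a.u. per volume, default 0).
#' @param frequencies In-band sinusoid frequencies (Hz).
#' @return List with `series` (4D array with attributes `tr`), `affine`,
#'   and `target_falff` (3D array).
#' @export
make_bold_series <- function(n_volumes = 201, tr = 2.3,
                             low_freq_amp = 1, broadband_amp = 0.25,
                             seed = 42, grid_shape = c(8, 8, 4),
                             trend_slope = 0,
                             frequencies = c(0.02, 0.035, 0.05, 0.065)) {
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  if (n_volumes < 20) stop("need at least 20 volumes", call. = FALSE)
  stopifnot(all(frequencies > 0.01 - 1e-12), all(frequencies < 0.08 + 1e-12))
  # snap to the series' DFT grid so the generated power sits exactly on
  # in-band bins (no spectral leakage in the emitted ground truth)
  frequencies <- pmax(round(frequencies * n_volumes * tr), 1) / (n_volumes * tr)
  set.seed(seed)
  nvox <- prod(grid_shape)
  t <- (seq_len(n_volumes) - 1) * tr
  series <- array(0, c(grid_shape, n_volumes))
  det_mat <- matrix(0, nvox, n_volumes)
  for (v in seq_len(nvox)) {
    sig <- numeric(n_volumes)
    if (low_freq_amp > 0) {
      for (f in frequencies) {
        sig <- sig + low_freq_amp * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      }
    }
    sig <- sig + trend_slope * seq_len(n_volumes)
    det_mat[v, ] <- sig
  }
  noise <- if (broadband_amp > 0) {
    matrix(stats::rnorm(nvox * n_volumes, sd = broadband_amp), nvox, n_volumes)
  } else matrix(0, nvox, n_volumes)
  for (f in seq_len(n_volumes)) {
    series[(seq_len(nvox)) + (f - 1L) * nvox] <- det_mat[, f] + noise[, f]
  }
  target <- bold_target_falff(det_mat, trend_slope, n_volumes, tr, broadband_amp)
  structure(list(series = structure(series, tr = tr),
                 affine = default_affine(c(3, 3, 4)),
                 target_falff = array(target, grid_shape)),
            class = "bold_phantom")
}

bold_target_falff <- function(det_mat, trend_slope, n, tr, broadband_amp) {
  half <- floor(n / 2)
  freqs <- (1:half) / (n * tr)
  inb <- freqs >= 0.01 & freqs <= 0.08
  # expected amplitude of a white-noise bin: sd * sqrt(pi * n) / 2
  c_noise <- broadband_amp * sqrt(pi * n) / 2
  apply(det_mat, 1, function(x) {
    # remove the deterministic trend the way preprocessing will
    if (trend_slope != 0) x <- stats::resid(stats::lm(x ~ seq_along(x)))
    a <- Mod(stats::fft(x))[2:(half + 1)]
    num <- sum(a[inb]) + sum(inb) * c_noise
    den <- sum(a) + half * c_noise
    if (den == 0) 0 else num / den
  })
}

#' Generate a synthetic subject cohort
#'
#' Draws AD and CTL subjects with injected dose (700-750 MBq), body
#' weight, a latent cortical amyloid multiplier (`suvr_scale`), MMSE
#' coupled negatively to amyloid burden (CTL about 29 +/- 1, AD about
#' 24 +/- 3), and a 4-level visual score derived from the implied
#' cortical SUVr (0 negative .. 3 severe).
#'
#' @param n_ad,n_ctl Group sizes (defaults 27 and 16).
#' @param seed Integer seed.
#' @return Subject tibble (see [read_subjects()]) plus `suvr_scale`.
#' @export
make_subjects <- function(n_ad = 27, n_ctl = 16, seed = 1) {
  set.seed(seed)
  n <- n_ad + n_ctl
  group <- c(rep("AD", n_ad), rep("CTL", n_ctl))
  cort_mean <- ifelse(group == "AD", 1.65, 1.01)
  scale_sd <- ifelse(group == "AD", 0.16, 0.15)
  suvr_scale <- pmax(stats::rnorm(n, 1, scale_sd), 0.5)
  cort <- cort_mean * suvr_scale
  mmse <- pmin(pmax(round(35 - 6 * cort + stats::rnorm(n, 0, 1.5)), 0), 30)
  visual <- findInterval(cort, c(1.2, 1.45, 1.7))
  tibble::tibble(
    id = sprintf("sub-%02d", seq_len(n)),
    group = group,
    dose_mbq = stats::runif(n, 700, 750),
    weight_kg = pmin(pmax(stats::rnorm(n, 60, 10), 40), 100),
    mmse = as.integer(mmse),
    visual_score = as.integer(visual),
    suvr_scale = suvr_scale
  )
}

#' Draw per-subject regional values from the reference group statistics
#'
#' For each subject, draws one value per region and hemisphere from the
#' subject's group-specific normal distribution in
#' [reference_regional_values()]. Used to emulate regional CBF or SUVr
#' tables at the study's printed group means and SDs.
#'
#' @param subjects Subject tibble with `id` and `group`.
#' @param quantity `"CBF"` or `"SUVr"`.
#' @param seed Integer seed.
#' @return A regional table tibble: `subject, region, hemisphere,
#'   quantity, value`.
#' @export
make_regional_cohort <- function(subjects, quantity = c("CBF", "SUVr"), seed = 1) {
  quantity <- match.arg(quantity)
  ref <- dplyr::filter(reference_regional_values(), .data$quantity == !!quantity)
  set.seed(seed)
  purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    g <- subjects$group[i]
    rg <- dplyr::filter(ref, .data$group == !!g)
    tibble::tibble(subject = subjects$id[i],
                   region = rg$region, hemisphere = rg$hemisphere,
                   quantity = quantity,
                   value = stats::rnorm(nrow(rg), rg$mean, rg$sd))
  })
}
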