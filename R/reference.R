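#' Reference regional CBF and SUVr values used to seed the phantom
#'
#' Regional early-phase PET-CBF (mL/min/100 g) and late-phase PiB SUVr
#' (unitless) group means and standard deviations for healthy controls
#' (CTL) and early Alzheimer's disease (AD) patients, by lobe and
#' hemisphere. These are the operating points the synthetic phantom
#' emulates and the cohort generator draws from.
#'
#' @return A tibble with columns `quantity` (`"CBF"` or `"SUVr"`),
#'   `region`, `hemisphere` (`"right"`/`"left"`), `group` (`"CTL"`/`"AD"`),
#'   `mean`, `sd`.
#' @examples
#' reference_regional_values() |>
#'   dplyr::filter(quantity == "CBF", group == "CTL")
#' @export
reference_regional_values <- function() {
  cbf <- tibble::tribble(
    ~region,      ~hemisphere, ~group, ~mean, ~sd,
    "frontal",    "right", "CTL", 41.6, 4.5,
    "frontal",    "left",  "CTL", 39.9, 4.0,
    "frontal",    "right", "AD",  38.7, 8.7,
    "frontal",    "left",  "AD",  37.7, 8.0,
    "temporal",   "right", "CTL", 39.9, 3.0,
    "temporal",   "left",  "CTL", 36.6, 3.1,
    "temporal",   "right", "AD",  34.5, 8.6,
    "temporal",   "left",  "AD",  32.2, 7.4,
    "parietal",   "right", "CTL", 44.3, 5.8,
    "parietal",   "left",  "CTL", 41.7, 4.7,
    "parietal",   "right", "AD",  37.8, 10.6,
    "parietal",   "left",  "AD",  36.3, 9.3,
    "occipital",  "right", "CTL", 44.0, 5.8,
    "occipital",  "left",  "CTL", 42.3, 4.7,
    "occipital",  "right", "AD",  39.7, 10.4,
    "occipital",  "left",  "AD",  38.4, 9.4,
    "cerebellum", "right", "CTL", 45.4, 5.9,
    "cerebellum", "left",  "CTL", 43.9, 5.9,
    "cerebellum", "right", "AD",  42.7, 9.4,
    "cerebellum", "left",  "AD",  41.6, 8.7
  )
  suvr <- tibble::tribble(
    ~region,     ~hemisphere, ~group, ~mean, ~sd,
    "frontal",   "right", "CTL", 1.02, 0.18,
    "frontal",   "left",  "CTL", 1.04, 0.19,
    "frontal",   "right", "AD",  1.74, 0.28,
    "frontal",   "left",  "AD",  1.77, 0.32,
    "temporal",  "right", "CTL", 1.00, 0.12,
    "temporal",  "left",  "CTL", 0.99, 0.12,
    "temporal",  "right", "AD",  1.54, 0.28,
    "temporal",  "left",  "AD",  1.54, 0.27,
    "parietal",  "right", "CTL", 1.01, 0.16,
    "parietal",  "left",  "CTL", 1.03, 0.19,
    "parietal",  "right", "AD",  1.79, 0.30,
    "parietal",  "left",  "AD",  1.81, 0.31,
    "occipital", "right", "CTL", 0.99, 0.12,
    "occipital", "left",  "CTL", 1.02, 0.12,
    "occipital", "right", "AD",  1.50, 0.24,
    "occipital", "left",  "AD",  1.51, 0.21
  )
  dplyr::bind_rows(
    dplyr::mutate(cbf, quantity = "CBF", .before = 1),
    dplyr::mutate(suvr, quantity = "SUVr", .before = 1)
  )
}

#' Cortical lobe region names used by the phantom parcellation
#' @return Character vector of the eight lobar region names.
#' @keywords internal
cortical_regions <- function() {
  as.vector(outer(c("frontal", "temporal", "parietal", "occipital"),
                  c("right", "left"), paste, sep = "_"))
}
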