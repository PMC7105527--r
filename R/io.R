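as_nifti_with_affine <- function(data, affine) {
  img <- RNifti::asNifti(data)
  xf <- structure(affine, code = 2L)
  RNifti::`sform<-`(img, xf)
}

#' Write a parametric map or raw array as NIfTI-1
#'
#' @param map A [parametric_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "parametric_map"))
  img <- as_nifti_with_affine(map$data, map$affine)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a 3D NIfTI volume as a parametric map
#'
#' @param path NIfTI file.
#' @param quantity Quantity tag (see [parametric_map()]).
#' @return A [parametric_map()].
#' @export
read_map <- function(path, quantity = "activity") {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D volume", call. = FALSE)
  parametric_map(array(as.numeric(img), dim = dim(img)),
                 RNifti::xform(img), quantity = quantity)
}

#' Write a dynamic image with its frame-schedule sidecar
#'
#' The schedule is written as a JSON sidecar holding `FrameTimesStart` and
#' `FrameDuration` arrays in seconds.
#'
#' @param dyn A [dynamic_image()].
#' @param path Output NIfTI path.
#' @param sidecar_path JSON sidecar path; default replaces the NIfTI
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_dynamic <- function(dyn, path, sidecar_path = NULL) {
  stopifnot(inherits(dyn, "dynamic_image"))
  sidecar_path <- sidecar_path %||% sidecar_for(path)
  img <- as_nifti_with_affine(dyn$data, dyn$affine)
  RNifti::writeNifti(img, path, datatype = "float")
  schedule_to_json(dyn$schedule, sidecar_path)
  invisible(path)
}

sidecar_for <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a dynamic image, validating against its frame schedule
#'
#' @param path 4D NIfTI file.
#' @param schedule Either a [frame_schedule()] or the path to a JSON
#'   sidecar with `FrameTimesStart`/`FrameDuration` (seconds). Defaults to
#'   the sidecar next to `path`.
#' @return A [dynamic_image()].
#' @export
read_dynamic <- function(path, schedule = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("expected a 4D volume", call. = FALSE)
  if (is.null(schedule)) schedule <- sidecar_for(path)
  if (is.character(schedule)) schedule <- schedule_from_json(schedule)
  if (dim(img)[4] != nrow(schedule)) {
    stop(sprintf("frame count mismatch: schedule has %d frames but image has %d",
                 nrow(schedule), dim(img)[4]), call. = FALSE)
  }
  dynamic_image(array(as.numeric(img), dim = dim(img)),
                RNifti::xform(img), schedule)
}

#' Write / read an integer parcellation
#'
#' The legend travels in a JSON sidecar mapping region names to labels.
#' @param parc A [parcellation()].
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  img <- as_nifti_with_affine(parc$labels, parc$affine)
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(as.list(parc$legend), sidecar_for(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  img <- RNifti::readNifti(path)
  legend <- unlist(jsonlite::read_json(sidecar_for(path), simplifyVector = TRUE))
  parcellation(array(as.integer(img), dim = dim(img)), legend, RNifti::xform(img))
}

#' Read / write the subject metadata table
#'
#' CSV with columns `id, group, dose_mbq, weight_kg, mmse, visual_score`.
#' `group` must be `AD` or `CTL`; `visual_score` is an integer 0-3 or
#' missing; MMSE an integer 0-30.
#'
#' @param path CSV file.
#' @return A tibble of subject records.
#' @export
read_subjects <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  validate_subjects(tbl)
}

#' @rdname read_subjects
#' @param subjects A subject tibble.
#' @export
write_subjects <- function(subjects, path) {
  validate_subjects(subjects)
  readr::write_csv(subjects, path)
  invisible(path)
}

validate_subjects <- function(tbl) {
  needed <- c("id", "group", "dose_mbq", "weight_kg", "mmse")
  miss <- setdiff(needed, names(tbl))
  if (length(miss) > 0L) {
    stop(sprintf("subject table missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (!"visual_score" %in% names(tbl)) tbl$visual_score <- NA_integer_
  if (!all(tbl$group %in% c("AD", "CTL"))) {
    stop("group must be 'AD' or 'CTL'", call. = FALSE)
  }
  if (any(tbl$dose_mbq <= 0) || any(tbl$weight_kg <= 0)) {
    stop("dose and weight must be positive", call. = FALSE)
  }
  if (any(!is.na(tbl$mmse) & (tbl$mmse < 0 | tbl$mmse > 30))) {
    stop("MMSE must lie in 0..30", call. = FALSE)
  }
  vs <- tbl$visual_score
  if (any(!is.na(vs) & !vs %in% 0:3)) {
    stop("visual_score must be 0, 1, 2, 3 or missing", call. = FALSE)
  }
  tibble::as_tibble(tbl)
}
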