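#' @importFrom rlang %||%
NULL

#' Diagonal voxel-to-world affine
#'
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @return A 4x4 affine matrix (RAS+, origin at voxel 0).
#' @export
default_affine <- function(voxel_size = c(2, 2, 2)) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  diag(c(voxel_size, 1))
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || any(!is.finite(affine))) {
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  }
  affine
}

#' Dynamic PET image
#'
#' Couples a 4D decay-corrected activity array (kBq/mL) with its voxel-to-
#' world affine and the frame schedule. The 4th dimension must match the
#' number of frames in the schedule.
#'
#' @param data 4D numeric array, kBq/mL.
#' @param affine 4x4 voxel-to-world matrix (mm, RAS+).
#' @param schedule A [frame_schedule()].
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, affine, schedule) {
  if (length(dim(data)) != 4L) stop("dynamic image data must be 4D", call. = FALSE)
  if (!inherits(schedule, "frame_schedule")) stop("`schedule` must be a frame_schedule", call. = FALSE)
  if (dim(data)[4] != nrow(schedule)) {
    stop(sprintf("frame count mismatch: image has %d frames but schedule has %d",
                 dim(data)[4], nrow(schedule)), call. = FALSE)
  }
  if (any(!is.finite(data))) stop("dynamic image contains non-finite values", call. = FALSE)
  structure(list(data = data, affine = check_affine(affine), schedule = schedule),
            class = "dynamic_image")
}

#' Parametric 3D map
#'
#' A 3D map on a voxel grid, tagged with the physical quantity it holds.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param quantity One of `"K1"` (1/min), `"CBF"` (mL/min/100 g), `"SUV"`,
#'   `"SUVr"`, `"fALFF"`, `"ALFF"`, `"z"`, `"t"`, `"activity"` (kBq/mL).
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(data, affine,
                           quantity = c("activity", "K1", "CBF", "SUV",
                                        "SUVr", "fALFF", "ALFF", "z", "t")) {
  quantity <- match.arg(quantity)
  if (length(dim(data)) != 3L) stop("parametric map data must be 3D", call. = FALSE)
  structure(list(data = data, affine = check_affine(affine), quantity = quantity),
            class = "parametric_map")
}

#' Integer-label parcellation
#'
#' @param labels 3D array of non-negative integers; 0 is background.
#' @param legend Named integer vector or named list mapping region name to
#'   label value, e.g. `c(frontal_r = 1, frontal_l = 2)`.
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, legend, affine) {
  if (length(dim(labels)) != 3L) stop("parcellation labels must be 3D", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative integers", call. = FALSE)
  legend <- unlist(legend)
  if (is.null(names(legend)) || any(names(legend) == "")) {
    stop("legend must be a named label map", call. = FALSE)
  }
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(as.integer(legend), present)
  if (length(missing) > 0L) {
    stop(sprintf("legend labels absent from volume: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(list(labels = labels, legend = legend, affine = check_affine(affine)),
            class = "parcellation")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image %dx%dx%d, %d frames, %.0f s>\n",
              d[1], d[2], d[3], d[4], schedule_total(x$schedule)))
  invisible(x)
}

#' @export
print.parametric_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<parametric_map [%s] %dx%dx%d, range %.4g..%.4g>\n",
              x$quantity, d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation %s, %d regions>\n",
              paste(dim(x$labels), collapse = "x"), length(x$legend)))
  invisible(x)
}

grid_of <- function(x) {
  if (inherits(x, "dynamic_image")) list(dim = dim(x$data)[1:3], affine = x$affine)
  else if (inherits(x, "parametric_map")) list(dim = dim(x$data), affine = x$affine)
  else if (inherits(x, "parcellation")) list(dim = dim(x$labels), affine = x$affine)
  else stop("unsupported object", call. = FALSE)
}

#' Assert that two images live on the same voxel grid
#'
#' Grids match when dimensions are equal and affines agree within 1e-4 mm.
#' @param a,b Images (dynamic_image, parametric_map or parcellation).
#' @return Invisibly `TRUE`; errors otherwise.
#' @keywords internal
check_same_grid <- function(a, b) {
  ga <- grid_of(a); gb <- grid_of(b)
  if (!all(ga$dim == gb$dim)) {
    stop(sprintf("grid dimension mismatch: %s vs %s",
                 paste(ga$dim, collapse = "x"), paste(gb$dim, collapse = "x")),
         call. = FALSE)
  }
  if (max(abs(ga$affine - gb$affine)) > 1e-4) {
    stop("affine mismatch beyond 1e-4 mm tolerance", call. = FALSE)
  }
  invisible(TRUE)
}
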