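make_box_dynamic <- function(values_by_frame, dims = c(6, 6, 4),
                             schedule = default_schedule()) {
  nf <- nrow(schedule)
  arr <- array(rep(values_by_frame, each = prod(dims)), c(dims, nf))
  dynamic_image(arr, default_affine(), schedule)
}

test_that("early average is a duration-weighted mean of the window frames", {
  sch <- default_schedule()
  # frames with mid-times in [10, 40): frames 3..8 (12.5 ... 37.5 s)
  expect_equal(pibflow:::frames_in_window(sch, c(10, 40)), 3:8)
  expect_equal(sch$mid[3:8], seq(12.5, 37.5, by = 5))
  vals <- numeric(nrow(sch)); vals[3:8] <- 1
  dyn <- make_box_dynamic(vals)
  expect_equal(unique(as.vector(early_average(dyn)$data)), 1)
  # constant image stays constant
  dyn2 <- make_box_dynamic(rep(3.5, nrow(sch)))
  expect_equal(unique(as.vector(early_average(dyn2)$data)), 3.5)
  # window (0, 5): exactly the first frame (mid 2.5 s)
  vals3 <- numeric(nrow(sch)); vals3[1] <- 2
  expect_equal(unique(as.vector(early_average(make_box_dynamic(vals3),
                                              c(0, 5))$data)), 2)
  expect_error(early_average(dyn, c(4200, 4300)), "no frame")
})

test_that("IDIF mask equals the brute-force top-n sort and breaks ties by index", {
  set.seed(42)
  vals <- array(runif(6 * 6 * 4), c(6, 6, 4))
  early <- parametric_map(vals, default_affine())
  search <- array(TRUE, c(6, 6, 4))
  got <- extract_idif_mask(early, search, n_voxels = 30)
  ord <- order(-as.vector(vals), seq_along(vals))
  expect_setequal(got, ord[1:30])
  # region of exactly n voxels is returned whole
  small <- array(FALSE, c(6, 6, 4)); small[1:30] <- TRUE
  expect_setequal(extract_idif_mask(early, small, 30), 1:30)
  expect_error(extract_idif_mask(early, small, 31), "fewer")
  # ties at the cutoff resolve to the lowest voxel indices
  tied <- parametric_map(array(1, c(6, 6, 4)), default_affine())
  expect_equal(extract_idif_mask(tied, search, 5), 1:5)
})

test_that("IDIF mask lands inside the artery when the artery is hottest", {
  ph <- make_dynamic_pet(tiny_spec())
  early <- early_average(ph$image)
  mask <- extract_idif_mask(early, ph$parcellation, n_voxels = 30,
                            search_label = "artery")
  artery <- which(as.vector(ph$parcellation$labels) ==
                    ph$parcellation$legend[["artery"]])
  expect_length(mask, 30L)
  expect_true(all(mask %in% artery))
})

test_that("idif_tac averages the mask and applies the plasma fraction", {
  sch <- default_schedule()
  dyn <- make_box_dynamic(rep(7, nrow(sch)))
  tac <- idif_tac(dyn, 1:10)
  expect_true(all(tac$whole_blood == 7))
  expect_true(all(tac$plasma == 0.95 * 7))
  expect_true(all(tac$time <= 180))
  expect_equal(tac$time, sch$mid[sch$mid <= 180])
  # single-voxel mask reproduces that voxel's series
  arr <- array(0, c(3, 3, 2, nrow(sch)))
  arr[2, 2, 1, ] <- seq_len(nrow(sch))
  dyn2 <- dynamic_image(arr, default_affine(), sch)
  vox <- 2 + (2 - 1) * 3
  tac2 <- idif_tac(dyn2, vox)
  expect_equal(tac2$whole_blood, sch$frame[sch$mid <= 180])
  expect_error(idif_tac(dyn, integer(0)), "empty")
})

test_that("phantom IDIF recovers the dispersed ground-truth input", {
  ph <- make_dynamic_pet(tiny_spec())
  early <- early_average(ph$image)
  mask <- extract_idif_mask(early, ph$parcellation, 30, search_label = "artery")
  tac <- idif_tac(ph$image, mask)
  truth <- ph$truth$dispersed_input
  want <- approx(truth$time, truth$whole_blood, xout = tac$time)$y
  expect_lt(max(abs(tac$whole_blood - want)) / max(want), 0.02)
})

test_that("dispersion correction inverts the forward operator", {
  times <- seq(0, 180, by = 1)
  bolus <- gamma_variate(times, 25, 100)
  disp <- disperse_curve(bolus, times, tau = 4)
  corrected <- correct_dispersion(input_function(times[-1], disp[-1]), tau = 4)
  err <- abs(corrected$whole_blood - bolus[-1]) / max(bolus)
  expect_lt(max(err), 0.01)
  # identity and constant cases
  f <- input_function(0:10, rep(2, 11))
  expect_identical(correct_dispersion(f, 0), f)
  const <- correct_dispersion(f, tau = 4)
  expect_equal(const$whole_blood, rep(2, 11))
  expect_error(correct_dispersion(f, tau = -1), "non-negative")
  expect_error(correct_dispersion(input_function(0:1, c(1, 2)), 4), "3 samples")
})

test_that("plasma channel is locked to the configured fraction", {
  f <- input_function(0:20, runif(21, 0, 50))
  expect_equal(f$plasma, 0.95 * f$whole_blood)
  g <- correct_dispersion(f, 4)
  expect_equal(g$plasma, 0.95 * g$whole_blood)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_input_function(f, csv)
  back <- read_input_function(csv)
  expect_equal(back$plasma, 0.95 * back$whole_blood, tolerance = 1e-9)
})
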