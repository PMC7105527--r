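test_that("dispersion operator behaves as a causal smoother", {
  times <- seq(0, 180, by = 1)
  bolus <- gamma_variate(times, 25, 100)
  expect_identical(disperse_curve(bolus, times, tau = 0), bolus)
  disp <- disperse_curve(bolus, times, tau = 4)
  expect_lt(max(disp), max(bolus))
  expect_gt(times[which.max(disp)], times[which.max(bolus)])
})

test_that("rectangular bolus matches the closed-form exponential convolution", {
  times <- seq(0, 60, by = 0.5)
  A <- 10; a <- 5; b <- 20; tau <- 4
  rect <- ifelse(times >= a & times < b, A, 0)
  disp <- disperse_curve(rect, times, tau, interp = "constant")
  oracle <- rect_dispersion_oracle(times, A, a, b, tau)
  expect_lt(max(abs(disp - oracle)), 1e-8)
})

test_that("noise-free phantom tissue curves match an independent ODE solution", {
  spec <- tiny_spec()
  sch <- default_schedule()
  ph <- make_dynamic_pet(spec, sch)
  cp <- ph$truth$true_input
  for (region in c("frontal_right", "white_matter")) {
    tac <- ph$truth$region_tacs
    got <- tac$value[tac$region == region & tac$mid < 180]
    k1 <- spec$extraction * spec$region_cbf[[region]] / 100
    k2 <- spec$k2_per_region[[region]]
    want <- ode_tac_oracle(k1, k2, cp$time, cp$plasma, sch)
    expect_lt(max(abs(got - want) / max(want)), 1e-3)
    # the voxel data hold the same curve
    parc <- ph$parcellation
    vox <- which(parc$labels == parc$legend[[region]])[1]
    ijk <- arrayInd(vox, dim(parc$labels))
    series <- ph$image$data[ijk[1], ijk[2], ijk[3], sch$mid < 180]
    expect_equal(series, got)
  }
})

test_that("ground-truth K1 honours K1 = E x CBF / 100 everywhere", {
  spec <- tiny_spec()
  ph <- make_dynamic_pet(spec)
  k1 <- as.vector(ph$truth$true_k1_map$data)
  cbf <- as.vector(ph$truth$true_cbf_map$data)
  tis <- cbf > 0
  expect_equal(k1[tis], 0.65 * cbf[tis] / 100, tolerance = 1e-12)
  # frontal seed 41.6 -> K1 0.2704 min^-1
  parc <- ph$parcellation
  fr <- parc$labels == parc$legend[["frontal_right"]]
  expect_equal(unique(ph$truth$true_k1_map$data[fr]), 0.2704)
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- make_dynamic_pet(tiny_spec(noise_scale = 0.3, seed = 11))
  b <- make_dynamic_pet(tiny_spec(noise_scale = 0.3, seed = 11))
  expect_identical(a$image$data, b$image$data)
  c <- make_dynamic_pet(tiny_spec(noise_scale = 0.3, seed = 12))
  expect_false(identical(a$image$data, c$image$data))
})

test_that("phantom rejects schedules shorter than the kinetic window", {
  expect_error(make_dynamic_pet(tiny_spec(), flat_schedule(100, 10)),
               "180")
})

test_that("BOLD generator records correct fALFF targets in the limit cases", {
  pure <- make_bold_series(n_volumes = 120, tr = 2.3, low_freq_amp = 1,
                           broadband_amp = 0, seed = 3,
                           grid_shape = c(3, 3, 2))
  expect_true(all(pure$target_falff > 0.9))
  noise <- make_bold_series(n_volumes = 120, tr = 2.3, low_freq_amp = 0,
                            broadband_amp = 1, seed = 3,
                            grid_shape = c(3, 3, 2))
  n <- 120; half <- floor(n / 2)
  freqs <- (1:half) / (n * 2.3)
  band_share <- sum(freqs >= 0.01 & freqs <= 0.08) / half
  expect_equal(unique(as.vector(noise$target_falff)), band_share)
  expect_equal(dim(make_bold_series(n_volumes = 201, tr = 2.3, seed = 1,
                                    grid_shape = c(2, 2, 2))$series)[4], 201L)
  expect_error(make_bold_series(tr = 0), "tr")
  expect_error(make_bold_series(n_volumes = 10), "20")
})

test_that("cohort generator hits the intended group structure", {
  subs <- make_subjects(27, 16, seed = 5)
  expect_equal(sum(subs$group == "AD"), 27L)
  expect_equal(sum(subs$group == "CTL"), 16L)
  expect_true(all(subs$dose_mbq >= 700 & subs$dose_mbq <= 750))
  expect_true(all(subs$visual_score %in% 0:3))
  expect_gt(mean(subs$mmse[subs$group == "CTL"]),
            mean(subs$mmse[subs$group == "AD"]))
  coh <- make_regional_cohort(subs, "CBF", seed = 5)
  expect_equal(nrow(coh), nrow(subs) * 10L)
  expect_true(all(c("subject", "region", "hemisphere", "value") %in% names(coh)))
})
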