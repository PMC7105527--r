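sinus_series <- function(f0, n = 191, tr = 2.3, dims = c(2, 2, 1),
                         amplitude = 1) {
  t <- (0:(n - 1)) * tr
  x <- amplitude * sin(2 * pi * f0 * t)
  array(rep(x, each = prod(dims)), c(dims, n))
}

test_that("preprocessing discards volumes and removes linear structure", {
  cfg <- falff_config(tr = 2.3)
  series <- array(rnorm(2 * 2 * 2 * 201), c(2, 2, 2, 201))
  out <- preprocess_bold(series, cfg)
  expect_equal(dim(out)[4], 191L)
  # a pure ramp voxel detrends to ~0
  ramp <- array(0, c(1, 1, 1, 50))
  ramp[1, 1, 1, ] <- 3 * (1:50) + 2
  expect_lt(max(abs(preprocess_bold(ramp, falff_config(discard_volumes = 0,
                                                       tr = 2)))), 1e-8)
  # residualizing against the voxel's own series zeroes it
  x <- rnorm(40)
  voxel <- array(x, c(1, 1, 1, 40))
  cfgr <- falff_config(discard_volumes = 0, tr = 2,
                       nuisance_regressors = matrix(x))
  expect_lt(max(abs(preprocess_bold(voxel, cfgr))), 1e-8)
  # rank-deficient regressors are rejected
  cfgbad <- falff_config(discard_volumes = 0, tr = 2,
                         nuisance_regressors = cbind(1:40, 2 * (1:40)))
  expect_error(preprocess_bold(voxel, cfgbad), "rank")
  expect_error(preprocess_bold(array(0, c(1, 1, 1, 5)),
                               falff_config(discard_volumes = 10, tr = 2)),
               "shorter")
})

test_that("fALFF of pure tones respects the band", {
  cfg <- falff_config(tr = 2.3)
  n <- 191
  on_bin <- round(0.05 * n * 2.3) / (n * 2.3)  # in-band, integer cycles
  res <- falff_map(sinus_series(on_bin), cfg)
  expect_true(all(res$falff$data >= 0.99))
  out_band <- falff_map(sinus_series(0.12), cfg)
  expect_true(all(out_band$falff$data < 0.3))
  # scaling the series leaves fALFF unchanged, scales ALFF linearly
  res5 <- falff_map(sinus_series(on_bin, amplitude = 5), cfg)
  expect_equal(res5$falff$data, res$falff$data, tolerance = 1e-12)
  expect_equal(res5$alff$data, 5 * res$alff$data, tolerance = 1e-9)
})

test_that("amplitude sums equal a direct per-voxel DFT", {
  cfg <- falff_config(tr = 2.3)
  set.seed(8)
  series <- array(rnorm(3 * 2 * 2 * 60), c(3, 2, 2, 60))
  res <- falff_map(series, cfg)
  n <- 60; half <- floor(n / 2)
  freqs <- (1:half) / (n * cfg$tr)
  inb <- freqs >= 0.01 & freqs <= 0.08
  for (v in seq_len(12)) {
    ijk <- arrayInd(v, c(3, 2, 2))
    x <- series[ijk[1], ijk[2], ijk[3], ]
    # direct DFT, no fft(): amplitude at bin k
    amp <- vapply(1:half, function(k) {
      Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))
    }, numeric(1))
    expect_equal(res$alff$data[ijk[1], ijk[2], ijk[3]], sum(amp[inb]),
                 tolerance = 1e-10)
    expect_equal(res$falff$data[ijk[1], ijk[2], ijk[3]],
                 sum(amp[inb]) / sum(amp), tolerance = 1e-10)
  }
})

test_that("fALFF is bounded and white noise approaches the band share", {
  cfg <- falff_config(tr = 2.3)
  set.seed(9)
  series <- array(rnorm(10 * 10 * 4 * 150), c(10, 10, 4, 150))
  res <- falff_map(series, cfg)
  expect_true(all(res$falff$data >= 0 & res$falff$data <= 1))
  n <- 150; half <- floor(n / 2)
  freqs <- (1:half) / (n * cfg$tr)
  share <- sum(freqs >= 0.01 & freqs <= 0.08) / half
  expect_equal(mean(res$falff$data), share, tolerance = 0.05)
  # flat voxel is flagged with fALFF 0
  series[1, 1, 1, ] <- 4
  series[1, 1, 1, ] <- mean(series[1, 1, 1, ])  # constant
  pre <- preprocess_bold(series, falff_config(discard_volumes = 0, tr = 2.3))
  res2 <- falff_map(pre, cfg)
  expect_true(res2$flag_map[1, 1, 1])
  expect_equal(res2$falff$data[1, 1, 1], 0)
})

test_that("z-score maps standardize within the mask and are affine-invariant", {
  set.seed(10)
  m <- parametric_map(array(runif(5 * 5 * 2), c(5, 5, 2)), default_affine(),
                      "fALFF")
  z <- zscore_map(m)
  expect_equal(mean(z$data), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(z$data)), 1, tolerance = 1e-12)
  shifted <- parametric_map(3 * m$data + 2, m$affine, "fALFF")
  expect_equal(zscore_map(shifted)$data, z$data, tolerance = 1e-12)
  # hand-computed toy: values 1..5
  toy <- parametric_map(array(c(1, 2, 3, 4, 5), c(5, 1, 1)), default_affine())
  zt <- zscore_map(toy)
  expect_equal(as.vector(zt$data),
               (c(1, 2, 3, 4, 5) - 3) / sd(1:5), tolerance = 1e-12)
  flat <- parametric_map(array(1, c(5, 1, 1)), default_affine())
  expect_error(zscore_map(flat), "variance")
  expect_error(zscore_map(toy, mask = array(c(TRUE, rep(FALSE, 4)),
                                            c(5, 1, 1))), "2 voxels")
})
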