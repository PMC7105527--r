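cp_test <- make_input_function()$undispersed
sch <- default_schedule()

test_that("model TAC limits: k1 = 0 vanishes, k2 = 0 integrates the input", {
  expect_true(all(model_tac(0, 0.1, cp_test, sch) == 0))
  got <- model_tac(0.3, 0, cp_test, sch)
  # oracle: frame-averaged running integral of Cp (fine trapezoid)
  tt <- seq(0, 180, by = 0.01)
  cpv <- approx(cp_test$time, cp_test$plasma, xout = tt, rule = 2)$y
  cum <- (0.3 / 60) * cumsum(c(0, diff(tt) * (cpv[-1] + cpv[-length(cpv)]) / 2))
  want <- vapply(1:21, function(i) {
    a <- sch$start[i]; b <- a + sch$duration[i]
    mean(cum[tt >= a & tt <= b])
  }, numeric(1))
  expect_lt(max(abs(got - want) / max(want)), 1e-3)
})

test_that("model TAC matches a stiff ODE solution within 0.1%", {
  for (p in list(c(0.27, 0.10), c(0.45, 0.25), c(0.08, 0.05))) {
    got <- model_tac(p[1], p[2], cp_test, sch)
    want <- ode_tac_oracle(p[1], p[2], cp_test$time, cp_test$plasma, sch)
    expect_lt(max(abs(got - want) / max(want)), 1e-3)
  }
})

test_that("weighted-integral fit recovers noise-free parameters", {
  cfg <- kinetic_config()
  lookup <- pibflow:::build_wi_lookup(cp_test, sch, cfg)
  tac <- model_tac(0.2704, 0.1, cp_test, sch)
  fit <- fit_weighted_integral(tac, cp_test, cfg, sch, lookup)
  expect_equal(fit$k1, 0.2704, tolerance = 0.01)
  expect_equal(fit$k2, 0.1, tolerance = 0.05)
  expect_false(fit$flag)
  zero <- fit_weighted_integral(rep(0, 21), cp_test, cfg, sch, lookup)
  expect_equal(zero$k1, 0)
  expect_false(zero$flag)
})

test_that("weighted-integral ratio is strictly monotone and scale-equivariant", {
  cfg <- kinetic_config()
  lookup <- pibflow:::build_wi_lookup(cp_test, sch, cfg)
  expect_true(all(diff(lookup$ratio) < 0))
  tac <- model_tac(0.3, 0.15, cp_test, sch)
  f1 <- fit_weighted_integral(tac, cp_test, cfg, sch, lookup)
  f2 <- fit_weighted_integral(5 * tac, input_function(cp_test$time,
                                                      5 * cp_test$whole_blood),
                              cfg, sch)
  expect_equal(f2$k1, f1$k1, tolerance = 1e-6)
  expect_equal(f2$k2, f1$k2, tolerance = 1e-6)
})

test_that("weighted-integral estimates agree with the NLLS reference", {
  cfg <- kinetic_config()
  lookup <- pibflow:::build_wi_lookup(cp_test, sch, cfg)
  set.seed(99)
  k1s <- runif(100, 0.1, 0.5)
  k2s <- runif(100, 0.05, 0.3)
  for (i in seq_len(100)) {
    tac <- model_tac(k1s[i], k2s[i], cp_test, sch)
    wi <- fit_weighted_integral(tac, cp_test, cfg, sch, lookup)
    expect_equal(wi$k1, k1s[i], tolerance = 0.01)
    expect_equal(wi$k2, k2s[i], tolerance = 0.05)
  }
  # spot-check the NLLS oracle itself on a subset
  for (i in 1:5) {
    nl <- fit_nlls(model_tac(k1s[i], k2s[i], cp_test, sch), cp_test, cfg, sch)
    expect_true(nl$converged)
    expect_equal(nl$k1, k1s[i], tolerance = 1e-4)
    expect_equal(nl$k2, k2s[i], tolerance = 1e-3)
  }
})

test_that("NLLS residual is minimized at the truth", {
  cfg <- kinetic_config()
  tac <- model_tac(0.3, 0.12, cp_test, sch)
  rss <- function(k1, k2) sum((tac - model_tac(k1, k2, cp_test, sch))^2)
  expect_gt(rss(0.33, 0.12), rss(0.3, 0.12))
  expect_gt(rss(0.3, 0.16), rss(0.3, 0.12))
  # matches a brute-force lattice minimum
  grid <- expand.grid(k1 = seq(0.2, 0.4, by = 0.02),
                      k2 = seq(0.06, 0.2, by = 0.02))
  grid$rss <- mapply(rss, grid$k1, grid$k2)
  best <- grid[which.min(grid$rss), ]
  nl <- fit_nlls(tac, cp_test, cfg, sch, init = c(0.25, 0.1))
  expect_equal(nl$k1, best$k1, tolerance = 0.02)
  expect_equal(nl$k2, best$k2, tolerance = 0.02)
})

test_that("K1 to CBF conversion is the exact algebraic inverse", {
  expect_equal(k1_to_cbf(0.2704), 41.6, tolerance = 1e-12)
  expect_equal(k1_to_cbf(0), 0)
  k1 <- c(0.1, 0.2704, 0.5)
  expect_equal(k1_to_cbf(k1) * 0.65 / 100, k1, tolerance = 1e-12)
  m <- parametric_map(array(0.2704, c(2, 2, 2)), default_affine(), "K1")
  cm <- k1_to_cbf(m)
  expect_equal(unique(as.vector(cm$data)), 41.6)
  expect_equal(cm$quantity, "CBF")
})

test_that("voxelwise CBF image recovers the phantom within tolerance", {
  ph <- make_dynamic_pet(tiny_spec())
  parc <- ph$parcellation
  tissue <- parc$labels > 0 & parc$labels != parc$legend[["artery"]]
  res <- cbf_image(ph$image, ph$truth$true_input, brain_mask = tissue)
  got <- regional_means(res$cbf_map, parc)
  want <- regional_means(ph$truth$true_cbf_map, parc)
  tis <- want$value > 0
  expect_lt(max(abs(got$value[tis] / want$value[tis] - 1)), 0.02)
  # artery excluded from the mask stays zero
  expect_true(all(res$cbf_map$data[parc$labels == parc$legend[["artery"]]] == 0))
  expect_true(all(res$cbf_map$data[!tissue] == 0))
})

test_that("regional CBF bias stays under 5% with frame noise", {
  ph <- make_dynamic_pet(tiny_spec(noise_scale = 0.5, seed = 21))
  parc <- ph$parcellation
  tissue <- parc$labels > 0 & parc$labels != parc$legend[["artery"]]
  res <- cbf_image(ph$image, ph$truth$true_input, brain_mask = tissue)
  got <- regional_means(res$cbf_map, parc)
  want <- regional_means(ph$truth$true_cbf_map, parc)
  tis <- want$value > 0 & got$n_voxels > 100
  expect_lt(max(abs(got$value[tis] / want$value[tis] - 1)), 0.05)
})

test_that("kinetic result tidiers summarise the fit", {
  ph <- make_dynamic_pet(tiny_spec())
  parc <- ph$parcellation
  tissue <- parc$labels > 0 & parc$labels != parc$legend[["artery"]]
  res <- cbf_image(ph$image, ph$truth$true_input, brain_mask = tissue)
  td <- tidy(res)
  expect_true(all(c("i", "j", "k", "k1", "k2", "cbf", "flag") %in% names(td)))
  expect_equal(nrow(td), sum(tissue))
  gl <- glance(res)
  expect_equal(gl$n_voxels, sum(tissue))
  expect_equal(gl$extraction, 0.65)
})
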