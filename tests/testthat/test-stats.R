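test_that("regional means equal a brute-force per-label loop and are linear", {
  set.seed(12)
  lab <- array(sample(0:3, 6 * 6 * 3, replace = TRUE), c(6, 6, 3))
  parc <- parcellation(lab, c(a = 1, b = 2, c = 3), default_affine())
  vals <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  m <- parametric_map(vals, default_affine())
  got <- regional_means(m, parc)
  for (i in 1:3) {
    expect_equal(got$value[got$label == i], mean(vals[lab == i]))
  }
  # constant map yields the constant everywhere
  cm <- regional_means(parametric_map(array(2.5, c(6, 6, 3)),
                                      default_affine()), parc)
  expect_true(all(cm$value == 2.5))
  # linearity in the map
  m2 <- parametric_map(2 * vals + 1, default_affine())
  got2 <- regional_means(m2, parc)
  expect_equal(got2$value, 2 * got$value + 1, tolerance = 1e-12)
  # empty label flagged as missing
  lab2 <- lab; lab2[lab2 == 3] <- 2L
  parc2 <- parcellation(lab2, c(a = 1, b = 2), default_affine())
  parc2$legend <- c(a = 1, b = 2, ghost = 9)
  got3 <- regional_means(m, parc2)
  expect_true(got3$flag[got3$region == "ghost"])
  expect_true(is.na(got3$value[got3$region == "ghost"]))
})

test_that("atrophy z-score follows the control-referenced sign convention", {
  expect_equal(vsrad_z(10, 10, 2), 0)
  expect_equal(vsrad_z(6, 10, 2), 2)
  expect_equal(vsrad_z(14, 10, 2), -2)
  expect_error(vsrad_z(1, 0, 0), "positive")
  # a group with reduced values scores higher z than controls
  set.seed(13)
  ctl <- rnorm(20, 10, 1)
  ad <- rnorm(20, 8, 1)
  expect_gt(mean(vsrad_z(ad, mean(ctl), sd(ctl))),
            mean(vsrad_z(ctl, mean(ctl), sd(ctl))))
})

test_that("group comparison matches the hand Welch formula", {
  tbl <- tibble::tibble(
    subject = rep(c("a1", "a2", "c1", "c2"), each = 1),
    region = "parietal", hemisphere = "right", quantity = "CBF",
    value = c(30, 34, 42, 46))
  groups <- c(a1 = "AD", a2 = "AD", c1 = "CTL", c2 = "CTL")
  out <- group_compare_regions(tbl, groups)
  a <- c(30, 34); c <- c(42, 46)
  t_hand <- (mean(a) - mean(c)) / sqrt(var(a) / 2 + var(c) / 2)
  expect_equal(out$regions$t, t_hand, tolerance = 1e-12)
  expect_equal(out$regions$mean_ad, 32)
  expect_equal(out$regions$sd_ctl, sd(c))
  # identical groups give t = 0, p = 1
  tbl2 <- tbl; tbl2$value <- c(30, 34, 30, 34)
  out2 <- group_compare_regions(tbl2, groups)
  expect_equal(out2$regions$t, 0)
  expect_equal(out2$regions$p, 1)
  expect_error(group_compare_regions(tbl[-1, ], groups[-1]), "2 subjects")
})

test_that("cohorts at the reference group statistics separate the parietal lobe", {
  hits <- 0L
  for (rep in 1:25) {
    subs <- make_subjects(27, 16, seed = 100 + rep)
    coh <- make_regional_cohort(subs, "CBF", seed = 200 + rep)
    out <- group_compare_regions(coh, subs)
    row <- dplyr::filter(out$regions, region == "parietal",
                         hemisphere == "right")
    hits <- hits + (row$p < 0.05 && row$mean_ad < row$mean_ctl)
  }
  expect_gt(hits, 12L)  # significant in most replicates
})

test_that("connected-component labelling agrees with a flood-fill oracle", {
  set.seed(14)
  for (i in 1:5) {
    mask <- array(runif(7 * 6 * 5) < 0.25, c(7, 6, 5))
    got <- label_components(mask)
    want <- flood_fill_oracle(mask)
    # same partition up to label permutation
    expect_equal(sort(tabulate(got)), sort(tabulate(want)))
    key <- paste(got[mask], want[mask])
    expect_equal(length(unique(key)), length(unique(got[mask])))
    expect_true(all((got > 0) == (mask != 0)))
  }
})

test_that("cluster extent filtering removes 49-voxel and keeps 50-voxel clusters", {
  d <- c(30, 30, 6)
  base <- array(0, d)
  # plant two flat clusters: 49 voxels (7x7x1) and 50 voxels (5x5x2)
  cl49 <- base; cl49[2:8, 2:8, 2] <- 1
  cl50 <- base; cl50[15:19, 15:19, 4:5] <- 1
  effect <- cl49 + cl50
  set.seed(15)
  maps_a <- lapply(1:6, function(i) 8 * effect + array(rnorm(prod(d), sd = 0.5), d))
  maps_b <- lapply(1:6, function(i) array(rnorm(prod(d), sd = 0.5), d))
  res <- voxelwise_ttest(maps_a, maps_b, mask = effect > 0,
                         height_p = 0.005, extent = 50)
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$size, 50L)
  expect_equal(nrow(res$removed), 1L)
  expect_equal(res$removed$size, 49L)
  expect_true(res$clusters$peak_i %in% 15:19)  # peak inside the 5x5x2 block
  # bookkeeping: suprathreshold voxels = kept + removed
  expect_equal(sum(res$suprathreshold),
               sum(res$clusters$size) + sum(res$removed$size))
  expect_true(all(res$suprathreshold[res$cluster_mask]))
  gl <- glance(res)
  expect_equal(gl$n_clusters, 1L)
  expect_equal(gl$n_removed, 1L)
})

test_that("null data give the nominal suprathreshold fraction", {
  set.seed(16)
  d <- c(25, 20, 10)  # 5000 voxels
  frac <- replicate(10, {
    maps_a <- lapply(1:16, function(i) array(rnorm(prod(d)), d))
    maps_b <- lapply(1:16, function(i) array(rnorm(prod(d)), d))
    res <- voxelwise_ttest(maps_a, maps_b, height_p = 0.005, extent = 50)
    mean(res$p_map < 0.005)
  })
  n_total <- 10 * prod(d)
  ci <- qbinom(c(0.0005, 0.9995), n_total, 0.005) / n_total
  expect_gt(mean(frac), ci[1])
  expect_lt(mean(frac), ci[2])
})

test_that("permutation cluster p-values flag a strong real effect", {
  d <- c(12, 12, 4)
  effect <- array(0, d); effect[3:8, 3:8, 2:3] <- 1
  set.seed(17)
  maps_a <- lapply(1:6, function(i) 5 * effect + array(rnorm(prod(d), sd = 0.5), d))
  maps_b <- lapply(1:6, function(i) array(rnorm(prod(d), sd = 0.5), d))
  res <- voxelwise_ttest(maps_a, maps_b, height_p = 0.005, extent = 20,
                         n_perm = 99, seed = 3)
  expect_true(all(res$clusters$p_cluster < 0.05))
})
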