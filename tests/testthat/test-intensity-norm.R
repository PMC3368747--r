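test_that("region statistics on simple constructed fields", {
  # uniform field: n, mean and zero sd are exact
  vol <- image_volume(array(7, c(12, 12, 12)), diag(4), "SPECT")
  rr <- reference_region(c(0, 0, 0), c(10, 10, 10), "world")
  rs <- region_stats(vol, rr)
  expect_identical(rs$n, 1000L)
  expect_equal(rs$mean, 7)
  expect_equal(rs$sd, 0)
  expect_equal(sum(rs$histogram$counts), rs$n)

  # 2x2x2 block of known values
  vox <- array(0, c(4, 4, 4))
  vox[1:2, 1:2, 1:2] <- 1:8
  vol2 <- image_volume(vox, diag(4), "SPECT")
  rs2 <- region_stats(vol2, reference_region(c(0, 0, 0), c(2, 2, 2),
                                             "world"))
  expect_identical(rs2$n, 8L)
  expect_equal(rs2$mean, 4.5)
  expect_equal(rs2$sd, sd(1:8))
  expect_equal(rs2$sd, 2.449, tolerance = 1e-3)

  expect_error(region_stats(vol, reference_region(c(100, 100, 100),
                                                  c(110, 110, 110),
                                                  "world")),
               "intersect")
  expect_error(region_stats(vol, reference_region(c(0, 0, 0), c(5, 5, 5),
                                                  "femoral")),
               "frame")
  expect_error(reference_region(c(0, 0, 0), c(0, 1, 1)), "min < max")
})

test_that("region statistics match a brute-force voxel loop", {
  set.seed(5)
  for (rep in 1:10) {
    d <- sample(4:12, 3, replace = TRUE)
    aff <- diag(4)
    aff[1:3, 1:3] <- diag(runif(3, 0.5, 2))
    aff[1:3, 4] <- runif(3, -5, 5)
    vol <- image_volume(array(rpois(prod(d), 50), dim = d), aff, "SPECT")
    lo <- runif(3, -4, 2)
    hi <- lo + runif(3, 3, 10)
    rr <- reference_region(lo, hi, "world")
    oracle <- brute_region_stats(vol, rr)
    if (oracle$n == 0) next
    rs <- region_stats(vol, rr)
    expect_identical(rs$n, as.integer(oracle$n))
    expect_equal(rs$mean, oracle$mean, tolerance = 1e-12)
    if (oracle$n >= 2) expect_equal(rs$sd, oracle$sd, tolerance = 1e-12)
    expect_equal(rs$min, oracle$min)
    expect_equal(rs$max, oracle$max)
  }
})

test_that("normalisation modes apply the reference statistics", {
  ref <- orthospect:::intensity_stats(c(rep(150, 10), rep(250, 10)))
  expect_equal(ref$mean, 200)
  scale <- normalization_model(ref, "scale_by_mean")
  offset <- normalization_model(ref, "offset_by_mean")
  zs <- normalization_model(ref, "zscore")
  expect_equal(normalize_intensity(910, scale), 4.55)
  expect_equal(normalize_intensity(200, scale), 1)
  expect_equal(normalize_intensity(200, offset), 0)
  expect_equal(normalize_intensity(200, zs), 0)
  expect_equal(normalize_intensity(200 + ref$sd, zs), 1)

  # volume normalisation: the normalised reference region has mean 1
  vox <- array(runif(1000, 50, 400), c(10, 10, 10))
  vol <- image_volume(vox, diag(4), "SPECT")
  rr <- reference_region(c(0, 0, 0), c(10, 10, 10), "world")
  model <- normalization_model(region_stats(vol, rr), "scale_by_mean")
  nvol <- normalize_intensity(vol, model)
  expect_equal(mean(nvol$voxels), 1, tolerance = 1e-12)

  bad <- orthospect:::intensity_stats(c(0, 0))
  expect_error(normalization_model(bad, "scale_by_mean"), "positive")
  expect_error(normalization_model(bad, "zscore"), "positive")
})

test_that("threshold rules produce the documented raw thresholds", {
  ref <- orthospect:::intensity_stats(c(rep(150, 50), rep(250, 50)))
  model <- normalization_model(ref, "scale_by_mean")
  expect_equal(threshold_from_model(model, list(k_times_mean = 3)), 600)
  expect_equal(threshold_from_model(model, list(k_times_mean = 4)), 800)
  ref2 <- orthospect:::intensity_stats(c(80, 120))   # mean 100
  ref2$sd <- 20
  model2 <- normalization_model(ref2, "scale_by_mean")
  expect_equal(threshold_from_model(model2, list(n_sd = 2)), 140)
  expect_equal(threshold_from_model(model2, list(n_sd = 0)), 100)
  # monotone in k and n
  ks <- sapply(c(1, 2, 3, 4, 6), function(k)
    threshold_from_model(model, list(k_times_mean = k)))
  expect_true(all(diff(ks) > 0))
  expect_error(threshold_from_model(model, list(k_times_mean = 0)), "k > 0")
  expect_error(threshold_from_model(model, list()), "rule")
})

test_that("Welch test matches the hand formula and stats::t.test", {
  hot <- orthospect:::intensity_stats(c(8, 10, 10, 12))   # n 4, mean 10, sd 2
  expect_equal(hot$sd, sqrt(8 / 3))
  hot$sd <- 2
  ref <- orthospect:::intensity_stats(rnorm(100))
  ref$n <- 100L; ref$mean <- 2; ref$sd <- 1
  res <- hotspot_vs_reference_test(hot, ref)
  expect_equal(res$t, (10 - 2) / sqrt(4 / 4 + 1 / 100), tolerance = 1e-12)
  expect_equal(res$t, 7.96, tolerance = 1e-2)

  # cross-check df and p against t.test on raw samples
  set.seed(9)
  x <- rnorm(30, 5, 2)
  y <- rnorm(200, 3, 1)
  mine <- hotspot_vs_reference_test(orthospect:::intensity_stats(x),
                                    orthospect:::intensity_stats(y))
  theirs <- t.test(x, y)
  expect_equal(mine$t, unname(theirs$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(theirs$parameter), tolerance = 1e-9)
  expect_equal(mine$p, theirs$p.value, tolerance = 1e-12)

  # identical constant samples: t = 0, p = 1
  same <- orthospect:::intensity_stats(rep(4, 5))
  null_res <- hotspot_vs_reference_test(same, same)
  expect_equal(null_res$t, 0)
  expect_equal(null_res$p, 1)
  one <- orthospect:::intensity_stats(3)
  expect_error(hotspot_vs_reference_test(one, same), "n >= 2")
})

test_that("histogram triplet shares bins and degenerates correctly", {
  set.seed(15)
  vox <- array(rpois(8000, 100), c(20, 20, 20))
  vol <- image_volume(vox, diag(4), "SPECT")
  rr <- reference_region(c(2, 2, 2), c(8, 8, 8), "world")
  whole <- reference_region(c(0, 0, 0), c(20, 20, 20), "world")
  # roi == reference region: saved and local identical
  h1 <- histogram_triplet(vol, rr, rr)
  expect_identical(h1$saved$counts, h1$local$counts)
  # roi covering the volume: local == global
  h2 <- histogram_triplet(vol, rr, whole)
  expect_identical(h2$local$counts, h2$global$counts)
  expect_identical(sum(h2$global$counts), length(vox))
  expect_equal(h2$breaks[1], 0)
  expect_equal(h2$breaks[length(h2$breaks)], max(vox))

  # a hotspot ROI carries more mass above 3x the reference mean
  vox2 <- array(100, c(20, 20, 20))
  vox2[10:14, 10:14, 10:14] <- 400
  vol2 <- image_volume(vox2, diag(4), "SPECT")
  roi <- reference_region(c(9, 9, 9), c(15, 15, 15), "world")
  h3 <- histogram_triplet(vol2, rr, roi)
  ref_mean <- region_stats(vol2, rr)$mean
  above <- h3$breaks[-length(h3$breaks)] >= 3 * ref_mean
  frac <- function(h) sum(h$counts[above]) / sum(h$counts)
  expect_gt(frac(h3$local), frac(h3$saved))
})
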