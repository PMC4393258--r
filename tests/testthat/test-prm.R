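# classify() operates on registered pairs; build one directly from arrays.
pair_from_arrays <- function(pre, post, spacing = c(1, 1, 1),
                             modality = "ADC") {
  b <- image_volume(pre, spacing = spacing, modality = modality)
  f <- image_volume(post, spacing = spacing, modality = modality)
  resample_to_baseline(b, f, NULL)
}

test_that("threshold calibration matches the 1.96*SD closed form on Gaussian noise", {
  set.seed(14)
  d <- c(50, 50, 40)                                   # 1e5 voxels
  test <- image_volume(array(1 + rnorm(prod(d), 0, 0.2 / sqrt(2)), dim = d))
  retest <- image_volume(array(1 + rnorm(prod(d), 0, 0.2 / sqrt(2)), dim = d))
  th <- calibrate_threshold(test, retest, full_mask(test))
  expect_equal(th$half_width, 0.392, tolerance = 0.005 / 0.392)
  expect_equal(th$method, "sd_1p96")
  expect_equal(th$n_voxels, prod(d))
})

test_that("degenerate and undersized calibrations are reported", {
  v <- tiny_volume(dims = c(10, 10, 5))
  expect_warning(th <- calibrate_threshold(v, v, full_mask(v)), "degenerate")
  expect_equal(th$half_width, 0)
  small <- voi_mask(array(c(rep(TRUE, 10), rep(FALSE, 490)), dim = c(10, 10, 5)))
  expect_error(calibrate_threshold(v, tiny_volume(seed = 2), small), "30")
})

test_that("percentile calibration follows the empirical 2.5/97.5 quantiles", {
  set.seed(15)
  d <- c(30, 30, 30)
  noise <- rexp(prod(d)) - 0.3                        # skewed differences
  test <- image_volume(array(0, dim = d))
  retest <- image_volume(array(noise, dim = d))
  th <- calibrate_threshold(test, retest, full_mask(test),
                            method = "percentile_2p5_97p5")
  q <- quantile(noise, c(0.025, 0.975), names = FALSE)
  expect_equal(th$half_width, max(abs(q[1]), q[2]), tolerance = 1e-12)
})

test_that("classification applies strict inequalities around the half width", {
  pre <- array(1.0, dim = c(4, 4, 4))
  hw <- 0.25                       # exactly representable: ties stay exact
  post <- pre
  post[1, 1, 1] <- 1.5                                 # delta 0.5 > hw -> +1
  post[2, 1, 1] <- 1.0 + hw                            # tie -> unchanged
  post[3, 1, 1] <- 1.0 - hw                            # tie -> unchanged
  post[4, 1, 1] <- 0.625                               # delta -0.375 -> -1
  res <- classify(pair_from_arrays(pre, post), full_mask(image_volume(pre)),
                  prm_threshold(hw, modality = "ADC"))
  expect_equal(res$labels[1, 1, 1], 1L)
  expect_equal(res$labels[2, 1, 1], 0L)
  expect_equal(res$labels[3, 1, 1], 0L)
  expect_equal(res$labels[4, 1, 1], -1L)
  expect_equal(res$n_valid, 64L)
  expect_equal(res$frac_plus + res$frac_minus + res$frac_zero, 100,
               tolerance = 1e-9)
})

test_that("identical pre and post yields 100% unchanged", {
  pre <- array(rnorm(125), dim = c(5, 5, 5))
  res <- classify(pair_from_arrays(pre, pre), full_mask(image_volume(pre)),
                  prm_threshold(0.1, modality = "ADC"))
  expect_equal(res$frac_zero, 100)
  expect_equal(res$frac_plus, 0)
  expect_equal(res$frac_minus, 0)
})

test_that("classify agrees exactly with the brute-force per-voxel oracle", {
  set.seed(20)
  d <- c(10, 10, 10)
  hw <- 0.25
  pre <- array(rnorm(prod(d), 1, 0.3), dim = d)
  delta <- array(rnorm(prod(d), 0, 0.4), dim = d)
  # plant exact ties and invalid voxels
  delta[1:5] <- hw
  delta[6:10] <- -hw
  post <- pre + delta
  pre[11:13] <- invalid_value()
  post[14:16] <- invalid_value()
  voi <- array(runif(prod(d)) < 0.8, dim = d)
  pair <- pair_from_arrays(pre, post)
  res <- classify(pair, voi_mask(voi), prm_threshold(hw, modality = "ADC"))
  oracle <- classify_bruteforce(pre, post, voi, pair$overlap_mask$data, hw)
  expect_identical(res$labels, oracle$labels)
  expect_equal(res$frac_plus, oracle$frac_plus)
  expect_equal(res$frac_minus, oracle$frac_minus)
  expect_equal(res$frac_zero, oracle$frac_zero)
  expect_equal(res$n_valid, oracle$n_valid)
  expect_equal(nrow(res$scatter), res$n_valid)
})

test_that("swapping pre and post exchanges the plus and minus fractions exactly", {
  set.seed(21)
  d <- c(8, 8, 8)
  pre <- array(rnorm(prod(d), 1, 0.3), dim = d)
  post <- pre + array(rnorm(prod(d), 0.1, 0.4), dim = d)
  voi <- full_mask(image_volume(pre))
  th <- prm_threshold(0.2, modality = "ADC")
  fwd <- classify(pair_from_arrays(pre, post), voi, th)
  rev <- classify(pair_from_arrays(post, pre), voi, th)
  expect_equal(fwd$frac_plus, rev$frac_minus)
  expect_equal(fwd$frac_minus, rev$frac_plus)
  expect_equal(fwd$frac_zero, rev$frac_zero)
})

test_that("the unchanged fraction is monotone in the half width and ~0 at zero", {
  set.seed(22)
  d <- c(12, 12, 10)
  pre <- array(rnorm(prod(d)), dim = d)
  post <- pre + array(rnorm(prod(d), 0, 0.5), dim = d)
  voi <- full_mask(image_volume(pre))
  pair <- pair_from_arrays(pre, post)
  fz <- vapply(c(0, 0.1, 0.3, 0.6, 1.2, 1e6), function(hw)
    classify(pair, voi, prm_threshold(hw, modality = "ADC"))$frac_zero, 0)
  expect_true(all(diff(fz) >= 0))
  expect_lt(fz[1], 1e-9)                 # continuous noise: no exact ties
  expect_equal(fz[6], 100)
})

test_that("a calibrated threshold covers ~95% of an independent null follow-up", {
  spec <- phantom_spec(grid_shape = c(50, 50, 40), noise_sd_adc = 0.15,
                       seed = 31)
  tr <- make_testretest(spec, "ADC")
  voi <- full_mask(tr$test)
  th <- calibrate_threshold(tr$test, tr$retest, voi)
  spec2 <- spec; spec2$seed <- 77L
  b <- make_baseline(spec2, "ADC")
  f <- make_followup(b, spec2, change_spec(mode = "null", seed = 78))
  res <- classify(resample_to_baseline(b$volume, f$volume, NULL), voi, th)
  expect_equal(res$frac_zero, 95, tolerance = 1 / 95)
})

test_that("time courses classify each day against the common baseline", {
  spec <- phantom_spec(grid_shape = c(24, 24, 16), noise_sd_adc = 0.1, seed = 41)
  b <- make_baseline(spec, "ADC")
  th <- prm_threshold(1.96 * sqrt(2) * spec$noise_sd_adc, modality = "ADC")
  # planted monotone densification: growing changed fraction by day
  fractions <- c(0.1, 0.3, 0.5)
  pairs <- lapply(seq_along(fractions), function(i) {
    f <- make_followup(b, spec, change_spec(mode = "response_adc_up",
                                            changed_fraction = fractions[i],
                                            effect_size = 4 * th$half_width,
                                            seed = 50 + i))
    resample_to_baseline(b$volume, f$volume, NULL)
  })
  tc <- prm_timecourse(pairs, days = c(7, 14, 21), voi = b$lesion_mask, th)
  expect_equal(tc$day, c(7, 14, 21))
  expect_true(all(diff(tc$frac_plus) > 0))
  expect_true(all(tc$frac_plus + tc$frac_minus + tc$frac_zero == 100))
  expect_equal(prm_timecourse(list(), numeric(0), b$lesion_mask, th),
               prm_timecourse(list(), numeric(0), b$lesion_mask, th))
  expect_equal(nrow(prm_timecourse(list(), numeric(0), b$lesion_mask, th)), 0L)
  expect_error(prm_timecourse(pairs[c(1, 1)], c(7, 7), b$lesion_mask, th),
               "duplicate")
})

test_that("overlay PNGs color exactly the labeled voxels", {
  d <- c(6, 5, 3)
  pre <- array(0.5, dim = d)
  post <- pre
  post[2, 3, 2] <- 2.0                                 # single increased voxel
  res <- classify(pair_from_arrays(pre, post), full_mask(image_volume(pre)),
                  prm_threshold(0.3, modality = "ADC"))
  tmp <- withr::local_tempdir()
  files <- export_overlay(res, image_volume(pre), slice_axis = 3, path = tmp)
  expect_length(files, d[3])
  img <- png::readPNG(files[2])
  red <- img[, , 1] > img[, , 2] & img[, , 1] > img[, , 3]
  expect_equal(sum(red), 1L)
  expect_true(red[3, 2])                               # (x=2, y=3) transposed
  img1 <- png::readPNG(files[1])                       # all-unchanged slice
  green <- img1[, , 2] > img1[, , 1] & img1[, , 2] > img1[, , 3]
  expect_equal(sum(green), prod(d[1:2]))
})

test_that("scatter and label exports round trip", {
  set.seed(51)
  d <- c(6, 6, 4)
  pre <- array(rnorm(prod(d), 1, 0.2), dim = d)
  post <- pre + array(rnorm(prod(d), 0, 0.3), dim = d)
  grid <- image_volume(pre)
  res <- classify(pair_from_arrays(pre, post), full_mask(grid),
                  prm_threshold(0.3, modality = "ADC"))
  tmp <- withr::local_tempdir()
  sc <- file.path(tmp, "scatter.csv")
  export_scatter(res, sc)
  back <- read.csv(sc)
  expect_equal(nrow(back), res$n_valid)
  expect_equal(back$pre, res$scatter$pre)
  lp <- file.path(tmp, "labels.nii.gz")
  write_labels(res, grid, lp)
  lab <- RNifti::readNifti(lp)
  expect_equal(array(as.integer(lab), dim = d), unname(res$labels))
})

test_that("fixed clinical and preclinical thresholds are exposed per modality", {
  expect_equal(default_threshold("ADC", "mouse")$half_width, 0.32)
  expect_equal(default_threshold("ADC", "human")$half_width, 0.55)
  expect_equal(default_threshold("HU", "mouse")$half_width, 391)
  expect_equal(default_threshold("HU", "human")$half_width, 100)
})
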