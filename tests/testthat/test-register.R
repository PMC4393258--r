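test_that("rigid transforms compose with their inverse to the identity", {
  set.seed(2)
  for (i in 1:5) {
    tf <- rigid_transform(runif(3, -0.3, 0.3), runif(3, -15, 15),
                          center = runif(3, -5, 5))
    inv <- invert_rigid(tf)
    pts <- matrix(runif(30, -40, 40), ncol = 3)
    expect_equal(transform_points(inv, transform_points(tf, pts)), pts,
                 tolerance = 1e-6)
    back <- invert_rigid(inv)
    expect_equal(back$rotation, tf$rotation, tolerance = 1e-6)
    expect_equal(back$translation, tf$translation, tolerance = 1e-6)
  }
})

test_that("resampling with the identity transform on a shared grid is exact", {
  base <- tiny_volume(dims = c(12, 10, 8), spacing = c(1, 1.5, 2))
  fup <- tiny_volume(dims = c(12, 10, 8), spacing = c(1, 1.5, 2), seed = 99)
  rp <- resample_to_baseline(base, fup, NULL)
  expect_identical(rp$followup_resampled$data, fup$data)
  expect_true(all(rp$overlap_mask$data))
})

test_that("integer-voxel translations resample without interpolation blur", {
  base <- tiny_volume(dims = c(12, 10, 8), spacing = c(1, 1.5, 2))
  fup <- tiny_volume(dims = c(12, 10, 8), spacing = c(1, 1.5, 2), seed = 99)
  # shift by exactly 3 voxels along x: transform adds +3*spacing_x in world
  tf <- rigid_transform(translation = c(3 * base$spacing[1], 0, 0))
  rp <- resample_to_baseline(base, fup, tf)
  got <- rp$followup_resampled$data
  expect_identical(got[1:9, , ], fup$data[4:12, , ])   # value pulled from x+3
  expect_true(all(is.na(got[10:12, , ])))
  expect_identical(rp$overlap_mask$data[10:12, , ],
                   array(FALSE, dim = c(3, 10, 8)))
  expect_true(all(rp$overlap_mask$data[1:9, , ]))
})

test_that("a transform pushing half the volume out of field yields a half overlap mask", {
  base <- tiny_volume(dims = c(10, 6, 6))
  tf <- rigid_transform(translation = c(5, 0, 0))   # half of 10 voxels at 1 mm
  rp <- resample_to_baseline(base, base, tf)
  expect_true(all(rp$overlap_mask$data[1:5, , ]))
  expect_false(any(rp$overlap_mask$data[6:10, , ]))
})

test_that("resampling through a planted transform and back recovers the volume", {
  spec <- reg_phantom_spec()
  fixed <- make_baseline(spec, "ADC")$volume
  tf <- rigid_transform(c(3, -2, 4) * pi / 180, c(4, -3, 2),
                        center = grid_center(fixed))
  moved <- resample_to_baseline(fixed, fixed, tf)$followup_resampled
  back <- resample_to_baseline(fixed, moved, invert_rigid(tf))$followup_resampled
  ok <- !is.na(back$data) & !is.na(fixed$data)
  rmse <- sqrt(mean((back$data[ok] - fixed$data[ok])^2))
  expect_lt(rmse, spec$noise_sd_adc)     # below the phantom noise floor
})

test_that("thin-plate splines interpolate landmarks exactly and degrade gracefully", {
  set.seed(8)
  src <- matrix(runif(24, 0, 50), ncol = 3)
  tgt <- src + matrix(rnorm(24, 0, 3), ncol = 3)
  warp <- fit_tps(src, tgt)
  expect_equal(transform_points(warp, src), tgt, tolerance = 1e-8)
  # identity correspondence: affine part identity, weights zero
  idw <- fit_tps(src, src)
  expect_equal(idw$weights, matrix(0, nrow(src), 3), tolerance = 1e-8)
  expect_equal(idw$affine, rbind(0, diag(3)), tolerance = 1e-8)
  # constant shift: every probe point moves by the shift (zero bending)
  shift <- c(2, -5, 1)
  shw <- fit_tps(src, sweep(src, 2, shift, "+"))
  probe <- matrix(runif(15, 0, 50), ncol = 3)
  expect_equal(transform_points(shw, probe), sweep(probe, 2, shift, "+"),
               tolerance = 1e-8)
  expect_error(fit_tps(src[1:3, ], tgt[1:3, ]), "at least 4")
  flat <- cbind(src[, 1:2], 0)
  expect_error(fit_tps(flat, tgt), "singular")
})

test_that("TPS landmark interpolation stays exact across random configurations", {
  set.seed(31)
  for (n in c(5, 8, 20)) {
    src <- matrix(runif(3 * n, -30, 30), ncol = 3)
    tgt <- src + matrix(rnorm(3 * n, 0, 5), ncol = 3)
    warp <- fit_tps(src, tgt)
    expect_lt(max(abs(transform_points(warp, src) - tgt)), 1e-8)
  }
})

test_that("self-registration returns the identity transform", {
  spec <- reg_phantom_spec()
  fixed <- make_baseline(spec, "ADC")$volume
  tf <- register_rigid_mi(fixed, fixed, seed = 1)
  expect_lt(max(abs(tf$rotation)) * 180 / pi, 0.1)
  expect_lt(max(abs(tf$translation)), 0.1)
  expect_gte(attr(tf, "mi"), attr(tf, "mi_identity"))
})

test_that("MI registration recovers a planted rigid transform on a textured phantom", {
  spec <- reg_phantom_spec()
  fixed <- make_baseline(spec, "ADC")$volume
  true_tf <- rigid_transform(c(-5, 7, -9) * pi / 180, c(-10, 4, 6),
                             center = grid_center(fixed))
  moving <- planted_moving(fixed, true_tf)
  tf <- register_rigid_mi(fixed, moving, seed = 1)
  expect_lt(max(abs(tf$rotation - true_tf$rotation)) * 180 / pi, 1)
  expect_lt(max(abs(tf$translation - true_tf$translation)),
            0.5 * min(fixed$spacing))
  expect_gte(attr(tf, "mi"), attr(tf, "mi_identity"))
})

test_that("registration rejects degenerate constant images", {
  flat <- image_volume(array(1, dim = c(8, 8, 8)))
  other <- tiny_volume(dims = c(8, 8, 8))
  expect_error(register_rigid_mi(flat, other), "constant")
  expect_error(register_rigid_mi(other, flat), "constant")
})

test_that("transforms serialize to text and back", {
  tmp <- withr::local_tempdir()
  tf <- rigid_transform(c(0.1, -0.2, 0.05), c(3.5, -2.25, 1), c(10, 12, 8))
  p <- file.path(tmp, "rigid.txt")
  write_transform(tf, p)
  back <- read_transform(p)
  expect_equal(back$rotation, tf$rotation)
  expect_equal(back$translation, tf$translation)
  expect_equal(back$center, tf$center)
  set.seed(4)
  src <- matrix(runif(18, 0, 40), ncol = 3)
  warp <- fit_tps(src, src + 2)
  p2 <- file.path(tmp, "tps.txt")
  write_transform(warp, p2)
  back2 <- read_transform(p2)
  probe <- matrix(runif(9, 0, 40), ncol = 3)
  expect_equal(transform_points(back2, probe), transform_points(warp, probe),
               tolerance = 1e-10)
})

test_that("landmark CSV files round trip through read_landmarks", {
  tmp <- withr::local_tempdir()
  set.seed(6)
  src <- matrix(runif(15, 0, 30), ncol = 3)
  tgt <- src + 1.5
  df <- data.frame(x_src = src[, 1], y_src = src[, 2], z_src = src[, 3],
                   x_tgt = tgt[, 1], y_tgt = tgt[, 2], z_tgt = tgt[, 3])
  p <- file.path(tmp, "lm.csv")
  write.csv(df, p, row.names = FALSE)
  lm <- read_landmarks(p)
  expect_equal(unname(lm$source), unname(src))
  expect_equal(unname(lm$target), unname(tgt))
  bad <- file.path(tmp, "bad.csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_landmarks(bad), "columns")
})
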