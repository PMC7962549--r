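test_that("HU normalization maps the clipping window to [0, 1]", {
  v <- volume(array(c(-1000, -120, 90, 300, 2000, 0), dim = c(6, 1, 1)))
  n <- normalize_hu(v)
  expect_equal(as.vector(n$values),
               c(0, 0, 0.5, 1, 1, 120 / 420), tolerance = 1e-12)
  expect_error(normalize_hu(v, hu_low = 10, hu_high = 10), "hu_low")
  # monotone non-decreasing in HU
  set.seed(2)
  hu <- sort(runif(50, -1500, 2000))
  out <- normalize_hu(volume(array(hu, dim = c(50, 1, 1))))
  expect_true(all(diff(as.vector(out$values)) >= 0))
})

test_that("isotropic resampling matches analytic linear interpolation on a ramp", {
  # ramp along x sampled at 1 mm, resampled to 2 mm
  n <- 21
  ramp <- array(rep(0:(n - 1), 4), dim = c(n, 2, 2))
  v <- volume(ramp, spacing = c(1, 1, 1))
  r <- resample_isotropic(v, 2)
  d <- dim(r$values)
  expect_equal(d[1], round(n / 2))
  # target voxel i (0-based) sits at source index 2 * i -> value 2 * i
  expect_equal(r$values[, 1, 1], 2 * (seq_len(d[1]) - 1), tolerance = 1e-9)
  # already at target spacing -> unchanged
  expect_identical(resample_isotropic(v, 1)$values, v$values)
  # constant volume -> constant output
  cv <- resample_isotropic(volume(array(0.7, dim = c(9, 9, 9)),
                                  spacing = c(3, 3, 3)), 2)
  expect_true(all(abs(cv$values - 0.7) < 1e-12))
  expect_error(resample_isotropic(v, 0), "positive")
})

test_that("centre crop/pad keeps the symmetric index range", {
  a <- array(seq_len(1000), dim = c(10, 10, 10))
  v <- volume(a, spacing = c(2, 2, 2))
  cr <- center_crop_pad(v, c(6, 6, 6))
  expect_equal(cr$values, a[3:8, 3:8, 3:8])
  pd <- center_crop_pad(volume(array(1, dim = c(4, 4, 4))), c(6, 6, 6),
                        pad_value = 0)
  expect_equal(dim(pd$values), c(6, 6, 6))
  expect_equal(pd$values[1, , ], matrix(0, 6, 6))
  expect_equal(pd$values[2:5, 2:5, 2:5], array(1, dim = c(4, 4, 4)))
  # crop(pad(v)) restores the original on the interior
  v0 <- volume(array(rnorm(64), dim = c(4, 4, 4)))
  back <- center_crop_pad(center_crop_pad(v0, c(8, 8, 8)), c(4, 4, 4))
  expect_equal(back$values, v0$values)
  # odd difference: extra voxel cropped from the high side
  cr5 <- center_crop_pad(volume(array(1:5, dim = c(5, 1, 1))), c(2, 1, 1))
  expect_equal(as.vector(cr5$values), c(2, 3))
})

test_that("full preprocessing pipeline is idempotent", {
  set.seed(3)
  raw <- volume(array(runif(20^3, -500, 800), dim = c(20, 20, 20)),
                spacing = c(1, 1, 2.5))
  cfg <- preprocess_config(target_spacing_mm = 2,
                           target_shape = c(16, 16, 16))
  once <- preprocess_volume(raw, cfg)
  expect_equal(dim(once$values), c(16, 16, 16))
  expect_true(all(once$values >= 0 & once$values <= 1))
  twice <- preprocess_volume(once, cfg, normalize = FALSE)
  expect_lt(max(abs(twice$values - once$values)), 1e-6)
})
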