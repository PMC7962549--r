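test_that("curriculum kernels follow the milestone schedule", {
  s <- curriculum_schedule()
  expect_equal(morphotrack:::kernel_at_epoch(0, s), 9L)
  expect_equal(morphotrack:::kernel_at_epoch(99, s), 9L)
  expect_equal(morphotrack:::kernel_at_epoch(100, s), 6L)
  expect_equal(morphotrack:::kernel_at_epoch(149, s), 6L)
  expect_equal(morphotrack:::kernel_at_epoch(150, s), 3L)
  expect_equal(morphotrack:::kernel_at_epoch(174, s), 3L)
  expect_equal(morphotrack:::kernel_at_epoch(175, s), 0L)
  expect_equal(morphotrack:::kernel_at_epoch(180, s), 0L)
  sc <- scale_schedule(s, 10)
  expect_equal(sc$milestones, c(10L, 15L, 17L))
  expect_equal(sc$kernels, s$kernels)
})

test_that("curriculum smoothing is a pure blur preserving the mean", {
  set.seed(12)
  v <- array(runif(20^3), dim = c(20, 20, 20))
  for (epoch in c(0, 160)) {   # kernels 9 and 3 (odd: exact preservation)
    sm <- curriculum_smooth(v, epoch)
    expect_equal(dim(sm), dim(v))
    expect_lt(abs(mean(sm) - mean(v)), 1e-6)
    expect_lt(stats::sd(sm), stats::sd(v))   # genuinely smoothing
  }
  # past the last milestone: identity
  expect_identical(curriculum_smooth(v, 175), v)
  # constant volume unchanged for any kernel
  cns <- array(0.3, dim = c(12, 12, 12))
  expect_lt(max(abs(curriculum_smooth(cns, 0) - 0.3)), 1e-12)
})

test_that("holdout split keeps ids that are multiples of 10", {
  sp <- split_by_id(1:20)
  expect_equal(sp$holdout_ids, c(10L, 20L))
  expect_equal(sort(c(sp$train_ids, sp$holdout_ids)), 1:20)
  # a 1010-patient corpus holds out exactly 10%
  sp2 <- split_by_id(1:1010)
  expect_length(sp2$holdout_ids, 101)
  expect_equal(length(sp2$holdout_ids) / 1010, 0.1)
  sp0 <- split_by_id(integer(0))
  expect_length(sp0$train_ids, 0)
  expect_length(sp0$holdout_ids, 0)
})

test_that("training on self-pairs reduces the loss, deterministically", {
  set.seed(13)
  d <- c(16, 16, 16)
  spec <- test_phantom_spec()
  coh <- simulate_cohort(3, spec, seed = 41L)
  mk <- function(i) {
    v <- generate_phantom(spec, coh$patients[[i]], 1L)$volume$values
    # downsample 32^3 -> 16^3 to keep this unit test fast
    v[seq(1, 32, 2), seq(1, 32, 2), seq(1, 32, 2)]
  }
  # identity-initialised network scores 0 on exact self-pairs, so pair each
  # scan with a deformed copy of itself: loss reduction is then meaningful
  pairs <- lapply(1:3, function(i) {
    f <- mk(i)
    spec16 <- test_phantom_spec()
    spec16$grid_shape <- c(16L, 16L, 16L)
    spec16$spacing_mm <- c(8, 8, 8)
    def <- apply_synthetic_deformation(volume(f, c(8, 8, 8)), spec16,
                                       seed = 60L + i)
    list(fixed = f, moving = def$warped$values)
  })
  cfgn <- regnet_config(channels = c(4, 4, 8, 8), latent_channels = 8,
                        affine_channels = c(4, 4, 8, 8, 8), fc_hidden = 8)
  sched <- curriculum_schedule(c(2L, 3L, 4L), c(9L, 6L, 3L))
  W1 <- train_registration(pairs, cfgn,
                           train_config(lr = 1e-3, epochs = 5L, seed = 3L),
                           loss_config(), sched)
  log1 <- attr(W1, "log")
  # the logged loss is only comparable within one curriculum stage
  expect_lt(log1$correlation[2], log1$correlation[1])
  # unsmoothed pre/post comparison on the training pairs
  pre <- sapply(pairs, function(p)
    as.numeric(correlation_loss(p$fixed, p$moving)))
  post <- sapply(pairs, function(p) {
    r <- forward_register(p$fixed, p$moving, W1)
    as.numeric(correlation_loss(p$fixed, r$warped_moving))
  })
  expect_lt(mean(post), mean(pre))
  # same seed -> identical trajectory
  W2 <- train_registration(pairs, cfgn,
                           train_config(lr = 1e-3, epochs = 5L, seed = 3L),
                           loss_config(), sched)
  expect_equal(attr(W2, "log")$total, log1$total, tolerance = 1e-6)
  expect_lt(max(abs(W2$out_w - W1$out_w)), 1e-12)
})
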