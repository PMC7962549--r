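test_that("warp operators are identities for identity transforms", {
  set.seed(4)
  v <- array(runif(16^3), dim = c(16, 16, 16))
  expect_lt(max(abs(affine_warp(v, cbind(diag(3), c(0, 0, 0))) - v)), 1e-6)
  zf <- array(0, dim = c(16, 16, 16, 3))
  expect_lt(max(abs(dense_warp(v, zf) - v)), 1e-12)
  expect_error(affine_warp(v, cbind(diag(3), c(NA, 0, 0))), "finite")
  expect_error(dense_warp(v, array(0, dim = c(8, 8, 8, 3))), "shape")
})

test_that("affine translation matches the array-shift oracle", {
  set.seed(5)
  v <- array(rnorm(16^3), dim = c(16, 16, 16))
  A <- cbind(diag(3), c(0, 0, 3))   # sample at z + 3
  w <- affine_warp(v, A)
  expect_equal(w[, , 1:13], v[, , 4:16], tolerance = 1e-12)
})

test_that("scaling by 2 then 0.5 composes to the identity on the interior", {
  # smooth input: product of sinusoids
  n <- 32
  ax <- sin(seq(0, pi / 4, length.out = n))
  v <- outer(outer(ax, ax), ax)
  ctr <- (n - 1) / 2
  mk_scale <- function(s) cbind(diag(s, 3), rep(ctr * (1 - s), 3))
  w <- affine_warp(affine_warp(v, mk_scale(2)), mk_scale(0.5))
  interior <- 9:24
  expect_lt(max(abs(w[interior, interior, interior] -
                    v[interior, interior, interior])), 1e-3)
})

test_that("warp operators are linear in the image argument", {
  set.seed(6)
  v <- array(rnorm(16^3), dim = c(16, 16, 16))
  w2 <- array(rnorm(16^3), dim = c(16, 16, 16))
  field <- array(rnorm(16^3 * 3, 0, 0.5), dim = c(16, 16, 16, 3))
  lhs <- dense_warp(2 * v + 3 * w2, field)
  rhs <- 2 * dense_warp(v, field) + 3 * dense_warp(w2, field)
  expect_lt(max(abs(lhs - rhs)), 1e-5)
})

test_that("untrained network performs the identity registration", {
  W <- small_weights()
  pr <- small_pair()
  res <- forward_register(pr$prior, pr$subsequent, W)
  expect_equal(res$affine, cbind(diag(3), c(0, 0, 0)), tolerance = 1e-12)
  expect_lt(max(abs(res$field)), 1e-12)
  expect_lt(max(abs(res$warped_moving - pr$subsequent$values)), 1e-6)
})

test_that("affine head regresses exactly 12 parameters and the default latent has 96 maps", {
  W <- regnet_init(regnet_config(), seed = 2L)
  set.seed(7)
  d <- c(32, 32, 32)
  f <- array(runif(prod(d)), dim = d)
  m <- array(runif(prod(d)), dim = d)
  res <- forward_register(f, m, W)
  expect_length(res$affine, 12)
  expect_equal(dim(res$latent_maps), c(2, 2, 2, 96))
})

test_that("latent grid is input shape / 16 and field shape matches input", {
  W <- small_weights()
  set.seed(8)
  d <- c(32, 32, 48)
  f <- array(runif(prod(d)), dim = d)
  m <- array(runif(prod(d)), dim = d)
  res <- forward_register(f, m, W)
  expect_equal(dim(res$latent_maps)[1:3], d / 16)
  expect_equal(dim(res$field), c(d, 3))
  expect_error(forward_register(array(0, dim = c(20, 20, 20)),
                                array(0, dim = c(20, 20, 20)), W),
               "divisible by 16")
})

test_that("transform_points composes displacement and affine consistently", {
  W <- small_weights()
  pr <- small_pair()
  res <- forward_register(pr$prior, pr$subsequent, W)
  pts <- matrix(c(5, 6, 7, 10, 11, 12), 2, 3, byrow = TRUE)
  # identity result: points unchanged
  expect_equal(unname(transform_points(pts, res)[, 1:3]), pts,
               tolerance = 1e-9, ignore_attr = TRUE)
  # pure translation: p + t
  res_t <- res
  res_t$affine <- cbind(diag(3), c(1, -2, 3))
  out <- transform_points(pts, res_t)
  expect_equal(unname(out), sweep(pts, 2, c(1, -2, 3), `+`),
               ignore_attr = TRUE)
  # out-of-grid points are clamped with a warning
  expect_warning(transform_points(matrix(c(-5, 0, 0), 1, 3), res), "clamped")
})

test_that("transform_points matches peak tracking under dense_warp", {
  # a displacement field moves a delta peak; transform_points must map the
  # peak's new location back onto the original
  n <- 16
  v <- array(0, dim = c(n, n, n))
  v[9, 9, 9] <- 1
  field <- array(0, dim = c(n, n, n, 3))
  field[, , , 1] <- 2  # warped(x) = v(x + 2): peak appears at x = 7 (1-based)
  w <- dense_warp(v, field)
  expect_equal(which(w == max(w), arr.ind = TRUE)[1, ], c(7, 9, 9),
               ignore_attr = TRUE)
  res <- structure(list(affine = cbind(diag(3), c(0, 0, 0)), field = field,
                        dim = c(n, n, n)), class = "mt_registration")
  # 0-based peak location 6 maps to 8 = 0-based original peak
  out <- transform_points(matrix(c(6, 8, 8), 1, 3), res)
  expect_equal(unname(out), matrix(c(8, 8, 8), 1, 3), ignore_attr = TRUE)
})
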