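test_that("rank-based AUC handles perfect, chance and tied scores", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.9, 0.2, 0.3, 0.8), c(1, 1, 0, 0)), 0.5)
  expect_equal(auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  # complement symmetry
  set.seed(20)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  expect_equal(auc(1 - s, y), 1 - auc(s, y), tolerance = 1e-12)
})

test_that("AUC equals U/(n1 n0) and the test agrees with wilcox.test", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
    p <- mann_whitney_p(s, y)
    expect_equal(attr(p, "auc"), auc(s, y), tolerance = 1e-15)
    ref <- suppressWarnings(wilcox.test(s[y == 1], s[y == 0],
                                        exact = FALSE, correct = FALSE))
    expect_equal(attr(p, "U"), unname(ref$statistic), tolerance = 1e-9)
    expect_equal(as.numeric(p), ref$p.value, tolerance = 1e-9)
  }
})

test_that("bootstrap CI is deterministic, covers the estimate, hits 1 when separable", {
  set.seed(22)
  s <- c(rnorm(30, 1), rnorm(30))
  y <- rep(1:0, each = 30)
  ci <- bootstrap_ci(s, y, n_boot = 300, seed = 5L)
  est <- auc(s, y)
  expect_lte(ci[1], est)
  expect_gte(ci[2], est)
  ci2 <- bootstrap_ci(s, y, n_boot = 300, seed = 5L)
  expect_identical(ci, ci2)
  # perfectly separated data: upper limit 1
  sep <- c(rep(1, 10), rep(0, 10))
  cis <- bootstrap_ci(sep, sep, n_boot = 100, seed = 6L)
  expect_equal(cis[2], 1)
})

test_that("round-trip error vanishes for identity and inverse translations", {
  d <- c(32, 32, 32)
  mk <- function(affine) structure(
    list(affine = affine, field = array(0, dim = c(d, 3)), dim = d),
    class = "mt_registration")
  idr <- mk(cbind(diag(3), c(0, 0, 0)))
  r0 <- round_trip_error(idr, idr, n_points = 100, seed = 1L)
  expect_equal(r0$mean_cm, 0, tolerance = 1e-12)
  expect_length(r0$distances_cm, 100)
  t <- c(2.5, -1.5, 3)
  rt <- round_trip_error(mk(cbind(diag(3), t)), mk(cbind(diag(3), -t)),
                         n_points = 100, seed = 2L)
  expect_lte(rt$mean_cm, 0.05)
  # seed-invariance within sampling noise
  ra <- round_trip_error(idr, idr, seed = 3L)
  rb <- round_trip_error(idr, idr, seed = 4L)
  expect_lt(abs(ra$mean_cm - rb$mean_cm), 1e-9)
  not_reg <- unclass(idr)
  expect_error(round_trip_error(idr, not_reg), "mt_registration")
})

test_that("round trip through a known field and its numeric inverse is small", {
  spec <- test_phantom_spec()
  coh <- simulate_cohort(1, spec, seed = 31L)
  vol <- generate_phantom(spec, coh$patients[[1]], 1L)$volume
  def <- apply_synthetic_deformation(vol, spec, seed = 7L)
  d <- dim(vol$values)
  # fixed-point inversion of the displacement field
  inv <- array(0, dim = c(d, 3))
  P <- morphotrack:::grid_coords(d)
  for (it in 1:30) {
    q <- P + matrix(inv, ncol = 3)
    u_at_q <- vapply(1:3, function(c)
      morphotrack:::sample3d_fw(def$field[, , , c], q), numeric(nrow(P)))
    inv <- array(-u_at_q, dim = c(d, 3))
  }
  mk <- function(field) structure(
    list(affine = cbind(diag(3), c(0, 0, 0)), field = field, dim = d),
    class = "mt_registration")
  rt <- round_trip_error(mk(def$field), mk(inv), n_points = 100, seed = 8L,
                         spacing_mm = spec$spacing_mm)
  # inversion residual bound for the composed round trip
  q <- P + matrix(inv, ncol = 3)
  u_at_q <- vapply(1:3, function(c)
    morphotrack:::sample3d_fw(def$field[, , , c], q), numeric(nrow(P)))
  resid <- sqrt(rowSums((matrix(inv, ncol = 3) + u_at_q)^2))
  bound <- max(resid) * max(spec$spacing_mm) / 10
  expect_lte(rt$mean_cm, bound + 1e-9)
  expect_lt(rt$mean_cm, 0.1)
})

test_that("KM without censoring equals the empirical survivor function", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  set.seed(23)
  t <- sample(1:50, 30, replace = TRUE)
  km2 <- km_estimate(t, rep(1, 30))
  emp <- sapply(km2$time, function(x) mean(t > x))
  expect_equal(km2$surv, emp, tolerance = 1e-12)
})

test_that("log-rank and Cox behave on constructed cohorts", {
  set.seed(24)
  t <- rexp(60, 0.01)
  g <- rep(c("a", "b"), 30)
  # identical groups: p near 1
  expect_gt(logrank_p(c(t, t), rep(1, 120), rep(c("a", "b"), each = 60)), 0.95)
  # binary covariate doubling the hazard: HR ~ 2 within 10%
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.005 * 2^x)
  cx <- cox_fit(data.frame(x = x), tt, rep(1, n))
  expect_lt(abs(cx$hr[1] - 2) / 2, 0.1)
  expect_lt(cx$p[1], 1e-10)
})
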