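test_that("correlation loss hits its analytic extremes", {
  set.seed(9)
  a <- array(rnorm(6^3), dim = c(6, 6, 6))
  expect_equal(as.numeric(correlation_loss(a, a)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(correlation_loss(a, 2 * a + 1)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(correlation_loss(a, -a)), 2, tolerance = 1e-12)
  # invariant to positive affine rescaling of either argument
  b <- array(rnorm(6^3), dim = c(6, 6, 6))
  expect_equal(as.numeric(correlation_loss(a, b)),
               as.numeric(correlation_loss(3 * a + 2, 0.5 * b - 1)),
               tolerance = 1e-12)
  # degenerate: both constant -> 1, flagged
  cns <- array(0.5, dim = c(6, 6, 6))
  l <- correlation_loss(cns, cns)
  expect_equal(as.numeric(l), 1)
  expect_true(attr(l, "degenerate"))
})

test_that("smoothness penalty: ramp on an 8^3 grid gives 1/3", {
  d <- c(8, 8, 8)
  f <- array(0, dim = c(d, 3))
  expect_equal(smoothness_penalty(f), 0)
  # spatially constant field
  f[, , , 2] <- 4
  expect_equal(smoothness_penalty(f), 0)
  # u_x(x) = x: one of the nine component-gradients is 1
  f <- array(0, dim = c(d, 3))
  f[, , , 1] <- array(rep(0:7, 64), dim = d)
  expect_equal(smoothness_penalty(f), 1 / 3, tolerance = 1e-12)
})

test_that("folding penalty detects orientation reversal", {
  d <- c(8, 8, 8)
  f <- array(0, dim = c(d, 3))
  expect_equal(folding_penalty(f), 0)
  f[, , , 1] <- 5; f[, , , 3] <- -2          # pure translation
  expect_equal(folding_penalty(f), 0)
  # u_x(x) = -2x folds space: det J = -1 everywhere on the interior
  f <- array(0, dim = c(d, 3))
  f[, , , 1] <- array(rep(-2 * (0:7), 64), dim = d)
  expect_equal(folding_penalty(f), 1, tolerance = 1e-12)
})

test_that("magnitude penalty is the mean squared displacement norm", {
  d <- c(8, 8, 8)
  f <- array(0, dim = c(d, 3))
  expect_equal(magnitude_penalty(f), 0)
  f[, , , 1] <- 1
  expect_equal(magnitude_penalty(f), 1)
  f[, , , 1] <- 3; f[, , , 2] <- 4
  expect_equal(magnitude_penalty(f), 25)
})

test_that("total loss adds the weighted parts", {
  set.seed(10)
  d <- c(8, 8, 8)
  a <- array(runif(prod(d)), dim = d)
  zf <- array(0, dim = c(d, 3))
  expect_equal(as.numeric(total_loss(a, a, zf)), 0, tolerance = 1e-12)
  # zero weights: equals the correlation loss alone
  b <- array(runif(prod(d)), dim = d)
  f <- array(rnorm(prod(d) * 3, 0, 0.5), dim = c(d, 3))
  expect_equal(as.numeric(total_loss(a, b, f, loss_config(0, 0, 0))),
               as.numeric(correlation_loss(a, b)), tolerance = 1e-12)
  # hand-assembled weighted sum, each penalty weighted 1/10 by default
  lt <- total_loss(a, b, f)
  terms <- attr(lt, "terms")
  expect_equal(as.numeric(lt),
               terms["correlation"] + 0.1 * terms["smoothness"] +
                 0.1 * terms["folding"] + 0.1 * terms["magnitude"],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(terms),
               c(as.numeric(correlation_loss(a, b)), smoothness_penalty(f),
                 folding_penalty(f), magnitude_penalty(f)), tolerance = 1e-12)
})

test_that("fused C++ penalties agree with the reference implementations", {
  set.seed(11)
  f <- array(rnorm(10 * 10 * 10 * 3, 0, 0.6), dim = c(10, 10, 10, 3))
  fp <- morphotrack:::field_penalties(f, 0.1, 0.1, 0.1)
  expect_equal(fp$smoothness, smoothness_penalty(f), tolerance = 1e-12)
  expect_equal(fp$folding, folding_penalty(f), tolerance = 1e-12)
  expect_equal(fp$magnitude, magnitude_penalty(f), tolerance = 1e-12)
  gref <- 0.1 * (morphotrack:::smoothness_penalty_grad(f)$grad +
                 morphotrack:::folding_penalty_grad(f)$grad +
                 morphotrack:::magnitude_penalty_grad(f)$grad)
  expect_lt(max(abs(fp$grad - gref)), 1e-12)
})
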