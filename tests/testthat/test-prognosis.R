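test_that("1-year labels from the later scan handle death, survival and censoring", {
  pairs <- data.frame(patient_id = c(1, 2, 3, 4),
                      subsequent_day = c(68, 68, 68, 68))
  surv <- data.frame(patient_id = 1:4,
                     os_days = c(268, 468, 368, 500),   # anchors + 200/400/300/432
                     event = c(1, 1, 0, 0))
  lab <- make_labels(pairs, surv)
  # death 200 d after anchor -> 0; alive at anchor+400 -> 1;
  # censored alive at anchor+300 -> excluded; censored at anchor+432 -> 1
  expect_equal(lab$label[lab$patient_id == 1], 0L)
  expect_equal(lab$label[lab$patient_id == 2], 1L)
  expect_false(3 %in% lab$patient_id)
  expect_equal(lab$label[lab$patient_id == 4], 1L)
  expect_equal(attr(lab, "n_excluded"), 1L)
  # scan after recorded death is a data-integrity error
  expect_error(make_labels(data.frame(patient_id = 1, subsequent_day = 300),
                           surv), "integrity")
  # label monotonicity in the horizon: 1 -> 0 or exclusion, never 0 -> 1
  lab2 <- make_labels(pairs, surv, horizon_days = 500)
  common <- intersect(lab$patient_id, lab2$patient_id)
  l1 <- lab$label[match(common, lab$patient_id)]
  l2 <- lab2$label[match(common, lab2$patient_id)]
  expect_true(all(l2 <= l1))
})

test_that("wrapper selection finds a planted signal feature", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 200
    y <- rep(0:1, each = n / 2)
    x <- matrix(rnorm(n * 6), n, 6)
    x[, 4] <- y + rnorm(n, 0, 0.05)   # feature 4 encodes the label
    sel <- wrapper_select(x, y, seed = s)
    if (sel[1] == 4L) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("wrapper selection terminates on pure noise near AUC 0.5", {
  # n large enough that the winner's-curse bias of maximising OOB AUC over
  # the candidates stays inside the 0.5 +/- 0.1 band
  set.seed(201)
  n <- 400
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 8), n, 8)
  sel <- wrapper_select(x, y, seed = 1L)
  expect_lte(length(sel), 3L)
  tr <- attr(sel, "oob_auc")
  expect_lt(abs(tr[length(tr)] - 0.5), 0.1)
  expect_error(wrapper_select(x, rep(1, n), seed = 1L), "both classes")
})

test_that("a duplicated feature adds no OOB improvement", {
  set.seed(124)
  n <- 150
  y <- rep(0:1, each = n / 2)
  x <- cbind(y + rnorm(n, 0, 0.2), rnorm(n))
  x <- cbind(x, x[, 1])   # column 3 duplicates column 1
  sel <- wrapper_select(x, y, seed = 2L)
  expect_true(1L %in% sel || 3L %in% sel)
  expect_false(all(c(1L, 3L) %in% sel))
})

test_that("score model separates a separable construction and is deterministic", {
  set.seed(125)
  n <- 120
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4)
  x[, 2] <- y * 2 + rnorm(n, 0, 0.3)
  colnames(x) <- paste0("f_", 1:4, "_mean")
  m <- fit_score_model(x, y, seed = 7L)
  sc <- predict_survival_score(m, x)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(auc(sc, y), 0.9)
  m2 <- fit_score_model(x, y, seed = 7L)
  expect_identical(predict_survival_score(m2, x), sc)
})

test_that("median split sends ties and the median element high", {
  g <- median_split(c(0.1, 0.2, 0.8, 0.9))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g3 <- median_split(c(0.1, 0.5, 0.9))
  expect_equal(as.character(g3)[2], "high")   # odd n: median goes high
  ga <- median_split(rep(0.4, 5))
  expect_true(all(ga == "high"))
  expect_true(attr(ga, "degenerate"))
  # discovery threshold applied to test scores
  gt <- median_split(c(0.2, 0.6), threshold = 0.5)
  expect_equal(as.character(gt), c("low", "high"))
})

test_that("PCA combination of two time-point scores behaves geometrically", {
  s <- rnorm(20)
  cmb <- combine_timepoints(s, 2 * s + 1)      # perfectly correlated
  expect_equal(attr(cmb, "explained_variance"), 1, tolerance = 1e-12)
  # two points at z-scored (1,1) and (-1,-1): +/- sqrt(2), positive first
  cmb2 <- combine_timepoints(c(2, 1, 0), c(4, 2, 0))
  expect_gt(cor(cmb2, c(2, 1, 0)), 0.99)
  set.seed(126)
  a <- rnorm(4000); b <- rnorm(4000)
  ev <- attr(combine_timepoints(a, b), "explained_variance")
  expect_lt(abs(ev - 0.5), 0.05)
  expect_error(combine_timepoints(1:2, 1:2), "3 patients")
})

test_that("quadrant assignment uses independent median splits", {
  q <- quadrant_assign(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(as.character(q), c("hi-hi", "hi-lo", "lo-hi", "lo-lo"))
  expect_equal(sum(attr(q, "counts")), 4)
  set.seed(127)
  s1 <- rnorm(21); s2 <- rnorm(21)
  q2 <- quadrant_assign(s1, s2)
  perm <- sample(21)
  expect_equal(as.character(quadrant_assign(s1[perm], s2[perm])),
               as.character(q2)[perm])
})

test_that("pseudo-diameter inverts the sphere volume formula", {
  expect_equal(pseudo_diameter(pi / 6), 1, tolerance = 1e-12)
  expect_equal(pseudo_diameter(4 / 3 * pi * 5^3), 10, tolerance = 1e-12)
  expect_equal(pseudo_diameter(1000), (6000 / pi)^(1 / 3), tolerance = 1e-12)
  # strictly increasing, exact inverse
  set.seed(128)
  d <- sort(runif(20, 1, 60))
  v <- pi / 6 * d^3
  expect_true(all(diff(pseudo_diameter(v)) > 0))
  expect_lt(max(abs(pseudo_diameter(v) - d) / d), 1e-9)
  expect_error(pseudo_diameter(-1), "non-negative")
})

test_that("durable clinical benefit is PFS of at least 180 days", {
  expect_equal(dcb_label(c(179, 180, 400, NA)), c(0L, 1L, 1L, NA))
})
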