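#' Rank-based AUC
#'
#' Area under the ROC curve computed from midranks (equivalent to the
#' Mann-Whitney statistic: `AUC = U / (n1 * n0)`); tied scores contribute
#' 1/2.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  U <- sum(r[y == 1]) - n1 * (n1 + 1) / 2
  U / (n1 * n0)
}

#' Two-sided Mann-Whitney U test
#'
#' Normal approximation with tie correction; the U statistic divided by
#' `n1 * n0` equals [auc()] exactly.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector.
#' @return two-sided p-value, with attributes `U` and `auc`.
#' @export
mann_whitney_p <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores, ties.method = "average")
  U <- sum(r[y == 1]) - n1 * (n1 + 1) / 2
  N <- n1 + n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n0 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(structure(1, U = U, auc = U / (n1 * n0)))
  z <- (U - n1 * n0 / 2) / sqrt(sigma2)
  structure(min(1, 2 * pnorm(-abs(z))), U = U, auc = U / (n1 * n0))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples (score, label) rows with replacement `n_boot` times and takes
#' the 2.5/97.5 percentiles of the statistic; resamples containing a single
#' class are skipped and redrawn (the skip count is reported).
#'
#' @param scores,labels data vectors.
#' @param statistic function of (scores, labels), default [auc()].
#' @param n_boot number of valid resamples (default 10000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return `c(lower, upper)` with attributes `n_skipped` and `estimate`.
#' @export
bootstrap_ci <- function(scores, labels, statistic = auc, n_boot = 10000,
                         seed = 1L, conf = 0.95) {
  n <- length(scores)
  stopifnot(length(labels) == n)
  est <- statistic(scores, labels)
  with_seed(mix_seed(seed, 53), {
    vals <- numeric(n_boot)
    got <- 0L
    skipped <- 0L
    guard <- 0L
    while (got < n_boot) {
      guard <- guard + 1L
      if (guard > 50L * n_boot) stop("bootstrap failed: too many degenerate resamples")
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) < 2) {
        skipped <- skipped + 1L
        next
      }
      got <- got + 1L
      vals[got] <- statistic(scores[idx], labels[idx])
    }
    a <- (1 - conf) / 2
    structure(as.numeric(quantile(vals, c(a, 1 - a), names = FALSE)),
              n_skipped = skipped, estimate = est)
  })
}

#' Permutation null distribution of the AUC
#'
#' Shuffles the labels `n_perm` times and recomputes the AUC, giving the
#' null band against which an observed AUC is judged.
#'
#' @param scores,labels data vectors.
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed.
#' @return numeric vector of null AUCs.
#' @export
perm_null_auc <- function(scores, labels, n_perm = 200, seed = 1L) {
  with_seed(mix_seed(seed, 59),
            vapply(seq_len(n_perm),
                   function(i) auc(scores, sample(labels)), 0))
}

#' Round-trip landmark error of a registration pair
#'
#' Samples points uniformly inside the central 80% of the grid, maps them
#' prior-to-subsequent and back with the two registration results, and
#' reports the mean Euclidean distance between each point and its round-trip
#' image, converted to cm via the voxel spacing.  An inverse-consistency
#' proxy for registration quality.
#'
#' @param result_ab,result_ba [forward_register()] results on the same grid
#'   (A to B, and B to A).
#' @param n_points number of sampled points (default 100).
#' @param seed integer seed.
#' @param spacing_mm voxel spacing (default 2 mm isotropic).
#' @return list of class `mt_roundtrip`: `mean_cm`, `distances_cm`,
#'   `n_points`, `seed`.
#' @export
round_trip_error <- function(result_ab, result_ba, n_points = 100, seed = 1L,
                             spacing_mm = c(2, 2, 2)) {
  stopifnot(inherits(result_ab, "mt_registration"),
            inherits(result_ba, "mt_registration"))
  d <- result_ab$dim
  if (!all(result_ba$dim == d)) stop("registration grids do not match")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  pts <- with_seed(mix_seed(seed, 61), {
    sapply(1:3, function(k) runif(n_points, 0.1 * (d[k] - 1), 0.9 * (d[k] - 1)))
  })
  fwd <- suppressWarnings(transform_points(pts, result_ab))
  back <- suppressWarnings(transform_points(fwd, result_ba))
  diff_mm <- sweep(back - pts, 2, spacing_mm, `*`)
  dist_cm <- sqrt(rowSums(diff_mm^2)) / 10
  structure(list(mean_cm = mean(dist_cm), distances_cm = dist_cm,
                 n_points = n_points, seed = seed),
            class = "mt_roundtrip")
}

#' Kaplan-Meier estimate
#'
#' Thin wrapper around [survival::survfit()]; with no censoring the curve
#' equals the empirical survivor function.
#'
#' @param times survival times.
#' @param events 1 = event observed, 0 = censored.
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`; the fitted
#'   `survfit` object is attached as attribute `fit`.
#' @export
km_estimate <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv),
            fit = fit)
}

#' Log-rank test
#'
#' @param times survival times.
#' @param events event indicators.
#' @param groups group factor.
#' @return p-value (chi-squared approximation, df = groups - 1).
#' @export
logrank_p <- function(times, events, groups) {
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  as.numeric(1 - stats::pchisq(sd$chisq, length(sd$n) - 1))
}

#' Cox proportional-hazards fit
#'
#' @param covariates data.frame of covariates.
#' @param times survival times.
#' @param events event indicators.
#' @return data.frame per covariate: `hr`, `lower`, `upper` (95% CI), `p`.
#' @export
cox_fit <- function(covariates, times, events) {
  df <- cbind(data.frame(.time = times, .event = events),
              as.data.frame(covariates))
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df)
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             hr = s$conf.int[, "exp(coef)"],
             lower = s$conf.int[, "lower .95"],
             upper = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL)
}
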