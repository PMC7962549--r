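#' Label scan pairs for 1-year survival from the later scan
#'
#' Each scan pair is labelled by whether the patient survived
#' `horizon_days` (default 365) from the date of the later scan of the pair:
#' death before the horizon gives label 0, follow-up (death or censoring) at
#' or past the horizon with the patient alive gives label 1, and patients
#' censored alive before the horizon are indeterminate and excluded (the
#' exclusion count is reported via the `n_excluded` attribute).
#'
#' @param pairs data.frame with columns `patient_id` and `subsequent_day`
#'   (the anchor day), e.g. from [cohort_features()].
#' @param survival data.frame with columns `patient_id`, `os_days`, `event`.
#' @param horizon_days prediction horizon (default 365).
#' @return `pairs` with a `label` column (0/1), indeterminate rows removed;
#'   attributes `n_excluded` and `anchor_day`.
#' @export
make_labels <- function(pairs, survival, horizon_days = 365) {
  stopifnot(all(c("patient_id", "subsequent_day") %in% names(pairs)),
            all(c("patient_id", "os_days", "event") %in% names(survival)))
  idx <- match(pairs$patient_id, survival$patient_id)
  if (anyNA(idx)) stop("missing survival record for patient(s): ",
                       paste(unique(pairs$patient_id[is.na(idx)]), collapse = ", "))
  os <- survival$os_days[idx]
  ev <- survival$event[idx]
  anchor <- pairs$subsequent_day
  if (any(anchor > os))
    stop("data-integrity error: scan after recorded death/censoring for patient(s) ",
         paste(unique(pairs$patient_id[anchor > os]), collapse = ", "))
  label <- rep(NA_integer_, nrow(pairs))
  label[ev == 1 & os < anchor + horizon_days] <- 0L
  label[os >= anchor + horizon_days] <- 1L
  keep <- !is.na(label)
  out <- pairs[keep, , drop = FALSE]
  out$label <- label[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

feature_columns <- function(df) {
  grep("^f_[0-9]+_|^dt_days$|^t_sot_days$", names(df), value = TRUE)
}

# out-of-bag AUC of a default-parameter forest on a feature subset
oob_auc <- function(x, y, seed) {
  with_seed(seed, {
    rf <- randomForest::randomForest(x = as.data.frame(x), y = factor(y, levels = c(0, 1)))
    auc(rf$votes[, "1"], y)
  })
}

#' Greedy forward wrapper feature selection
#'
#' Adds one feature at a time, evaluating each candidate by the out-of-bag
#' AUC of a default-parameter random forest on the discovery data, and stops
#' when no candidate improves the OOB AUC by more than `tol`.  Deterministic
#' given the seed.
#'
#' @param features matrix or data.frame of candidate features.
#' @param labels 0/1 vector (both classes must be present).
#' @param seed integer seed.
#' @param tol minimum OOB AUC improvement to accept a feature (default 1e-4).
#' @param max_features optional cap on the number of selected features.
#' @return integer vector of selected column indices (in selection order),
#'   with attribute `oob_auc` (the OOB AUC trajectory).
#' @export
wrapper_select <- function(features, labels, seed = 1L, tol = 1e-4,
                           max_features = Inf) {
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  if (length(y) < 10) stop("need at least 10 labelled samples")
  selected <- integer(0)
  best_auc <- -Inf
  trajectory <- numeric(0)
  repeat {
    if (length(selected) >= min(max_features, ncol(x))) break
    cand <- setdiff(seq_len(ncol(x)), selected)
    scores <- vapply(cand, function(j)
      oob_auc(x[, c(selected, j), drop = FALSE], y,
              mix_seed(seed, length(selected), j)), 0)
    j_best <- cand[which.max(scores)]
    if (max(scores) > best_auc + tol) {
      selected <- c(selected, j_best)
      best_auc <- max(scores)
      trajectory <- c(trajectory, best_auc)
    } else break
  }
  structure(selected, oob_auc = trajectory)
}

#' Fit the survival-score random forest
#'
#' A default-parameter random forest on the wrapper-selected features of the
#' discovery set; no hyperparameter tuning or cross-validation is performed.
#'
#' @param features matrix or data.frame (discovery set).
#' @param labels 0/1 vector.
#' @param seed integer seed.
#' @param selected optional pre-computed selection (column indices); if
#'   `NULL`, [wrapper_select()] is run.
#' @return list of class `mt_score_model`: `forest`, `selected`,
#'   `feature_names`, `seed`.
#' @export
fit_score_model <- function(features, labels, seed = 1L, selected = NULL) {
  x <- as.matrix(features)
  y <- factor(as.integer(labels), levels = c(0, 1))
  if (is.null(selected)) selected <- wrapper_select(x, labels, seed = seed)
  forest <- with_seed(mix_seed(seed, 131),
    randomForest::randomForest(x = as.data.frame(x[, selected, drop = FALSE]),
                               y = y))
  structure(list(forest = forest, selected = selected,
                 feature_names = colnames(x)[selected], seed = seed),
            class = "mt_score_model")
}

#' Predict the survival score
#'
#' @param model an [fit_score_model()] result.
#' @param features matrix/data.frame with the same columns used at fit time.
#' @return numeric vector of predicted 1-year survival probabilities.
#' @export
predict_survival_score <- function(model, features) {
  stopifnot(inherits(model, "mt_score_model"))
  x <- as.matrix(features)
  nd <- as.data.frame(x[, model$selected, drop = FALSE])
  # selection is positional; align names with the training frame
  if (!is.null(model$feature_names) && !anyNA(model$feature_names))
    colnames(nd) <- model$feature_names
  as.numeric(predict(model$forest, newdata = nd, type = "prob")[, "1"])
}

#' Median split into high/low survival groups
#'
#' Scores at or above the median go to the high-survival group (ties at the
#' median go high).  If all scores are equal the split is degenerate: every
#' sample is assigned high, and the result is flagged.
#'
#' @param scores numeric vector.
#' @param threshold optional externally supplied median (e.g. the discovery
#'   median applied to test scores).
#' @return factor with levels `low`, `high`; attributes `threshold`,
#'   `degenerate`.
#' @export
median_split <- function(scores, threshold = NULL) {
  if (is.null(threshold)) threshold <- median(scores)
  grp <- factor(ifelse(scores >= threshold, "high", "low"),
                levels = c("low", "high"))
  structure(grp, threshold = threshold,
            degenerate = length(unique(scores)) == 1L)
}

#' Combine two time-point scores by PCA
#'
#' Standardizes both score columns and projects onto the first principal
#' component, with the sign oriented so the combined score correlates
#' positively with the mean of the two inputs.  Used to reduce the
#' pre-baseline/baseline and baseline/first-follow-up scores to a single
#' prognostic score (mitigating collinearity in multivariate models).
#'
#' @param score1,score2 numeric vectors of per-patient scores (same order).
#' @return numeric vector of combined scores, with attribute
#'   `explained_variance` (fraction of variance captured by PC1).
#' @export
combine_timepoints <- function(score1, score2) {
  stopifnot(length(score1) == length(score2))
  if (length(score1) < 3) stop("need at least 3 patients")
  Z <- scale(cbind(score1, score2))
  Z[is.nan(Z)] <- 0   # constant column
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  combined <- pc$x[, 1]
  m <- rowMeans(Z)
  if (sum(combined * m) < 0) combined <- -combined
  structure(as.numeric(combined),
            explained_variance = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Quadrant assignment from two score sets
#'
#' Independent median splits of both scores; patients are assigned to
#' `hi-hi`, `hi-lo`, `lo-hi` or `lo-lo` (first position = first score).
#'
#' @param scores1,scores2 numeric vectors (same order).
#' @return factor of quadrant labels with a `counts` attribute.
#' @export
quadrant_assign <- function(scores1, scores2) {
  stopifnot(length(scores1) == length(scores2))
  g1 <- ifelse(scores1 >= median(scores1), "hi", "lo")
  g2 <- ifelse(scores2 >= median(scores2), "hi", "lo")
  q <- factor(paste(g1, g2, sep = "-"),
              levels = c("hi-hi", "hi-lo", "lo-hi", "lo-lo"))
  structure(q, counts = table(q))
}

#' Pseudo-diameter of a tumour burden
#'
#' Diameter of the sphere equi-volumetric to the total tumour burden,
#' `d = (6 V / pi)^(1/3)`, making volumetric burden comparable to 2D
#' diameter measurements.
#'
#' @param total_volume_mm3 non-negative volume in cubic mm.
#' @return diameter in mm.
#' @export
pseudo_diameter <- function(total_volume_mm3) {
  if (any(total_volume_mm3 < 0)) stop("volume must be non-negative")
  (6 * total_volume_mm3 / pi)^(1 / 3)
}

#' Durable-clinical-benefit label
#'
#' Alternative target: progression-free survival of at least `threshold_days`
#' (default 180, i.e. 6 months) from treatment start.
#'
#' @param pfs_days numeric vector of PFS days.
#' @param threshold_days DCB threshold (default 180).
#' @return 0/1 integer vector (NA where PFS is missing).
#' @export
dcb_label <- function(pfs_days, threshold_days = 180) {
  ifelse(is.na(pfs_days), NA_integer_, as.integer(pfs_days >= threshold_days))
}
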