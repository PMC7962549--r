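#' Build registration training pairs from a phantom cohort
#'
#' The unsupervised registration corpus, a mix of three pair types:
#' self-pairs (a scan paired with a synthetically deformed copy of itself,
#' known ground-truth deformation), follow-up pairs (two scans of the same
#' patient at different days, the later one jittered — the distribution the
#' monitoring stage consumes), and inter-patient pairs (scans of two
#' different patients), emulating the variability of a public chest-CT
#' corpus.
#'
#' @param cohort an `mt_cohort`.
#' @param n_pairs number of pairs to build.
#' @param seed integer seed.
#' @param proportions length-3 numeric, mixing weights for
#'   `c(self, followup, inter)` (default equal thirds).
#' @param patient_ids optional subset of patient ids to draw from (e.g. the
#'   training side of [split_by_id()]).
#' @return list of pairs, each `list(fixed, moving, meta)`; self-pairs carry
#'   the true deformation field in `meta$field`.
#' @export
make_training_pairs <- function(cohort, n_pairs, seed = 1L,
                                proportions = c(1, 1, 1) / 3,
                                patient_ids = NULL) {
  pats <- cohort$patients
  if (!is.null(patient_ids))
    pats <- Filter(function(p) p$patient_id %in% patient_ids, pats)
  stopifnot(length(pats) >= 2, length(proportions) == 3,
            all(proportions >= 0), sum(proportions) > 0)
  draws <- with_seed(mix_seed(seed, 71), {
    lapply(seq_len(n_pairs), function(i)
      list(type = sample(c("self", "followup", "inter"), 1,
                         prob = proportions),
           a = sample(length(pats), 1), b = sample(length(pats), 1),
           sa = runif(1), sb = runif(1), ds = sample.int(1e6, 1)))
  })
  lapply(seq_along(draws), function(i) {
    dr <- draws[[i]]
    pa <- pats[[dr$a]]
    na <- length(pa$scan_days)
    ia <- 1L + floor(dr$sa * na)
    type <- dr$type
    if (type == "followup" && na < 2) type <- "self"
    fixed <- generate_phantom(cohort$spec, pa, ia)$volume
    if (type == "self") {
      def <- apply_synthetic_deformation(fixed, cohort$spec, seed = dr$ds)
      list(fixed = fixed$values, moving = def$warped$values,
           meta = list(type = "self", patient = pa$patient_id,
                       field = def$field))
    } else if (type == "followup") {
      ib <- 1L + floor(dr$sb * (na - 1L))
      if (ib >= ia) ib <- ib + 1L
      mv <- generate_phantom(cohort$spec, pa, ib)$volume
      def <- apply_synthetic_deformation(mv, cohort$spec, seed = dr$ds)
      list(fixed = fixed$values, moving = def$warped$values,
           meta = list(type = "followup", patient = pa$patient_id))
    } else {
      pb <- pats[[if (dr$b == dr$a) (dr$a %% length(pats)) + 1L else dr$b]]
      ib <- 1L + floor(dr$sb * length(pb$scan_days))
      mv <- generate_phantom(cohort$spec, pb, ib)$volume
      def <- apply_synthetic_deformation(mv, cohort$spec, seed = dr$ds)
      list(fixed = fixed$values, moving = def$warped$values,
           meta = list(type = "inter", patient = pa$patient_id,
                       patient_b = pb$patient_id))
    }
  })
}

#' Experiment configuration
#'
#' One configuration fully determines all outputs of [run_experiment()].
#'
#' @param n_patients monitored cohort size (default 60).
#' @param phantom list of [phantom_spec()] overrides for the monitored
#'   cohort.
#' @param train_phantom optional [phantom_spec()] overrides for the
#'   registration-training corpus; defaults to `phantom`. The network is
#'   fully convolutional, so it can be trained on a coarser grid (e.g.
#'   32^3 at 4 mm) and applied to a finer one covering the same anatomy.
#' @param survival_params survival coupling, see [simulate_cohort()].
#' @param net list of [regnet_config()] overrides.
#' @param train list of [train_config()] overrides.
#' @param schedule_scale divisor applied to the curriculum milestones (and
#'   implicitly the epoch count), see [scale_schedule()].
#' @param reg_corpus list with `n_patients` and `n_pairs` for the
#'   registration training corpus.
#' @param n_boot bootstrap resamples for CIs.
#' @param n_perm label permutations for the null band.
#' @param seed global seed.
#' @return list of class `mt_experiment_config`.
#' @export
experiment_config <- function(n_patients = 60L,
                              phantom = list(),
                              train_phantom = NULL,
                              survival_params = list(baseline_hazard_per_day = 1 / 400,
                                                     beta_growth = 15),
                              net = list(),
                              train = list(),
                              schedule_scale = 1,
                              reg_corpus = list(n_patients = 40L, n_pairs = 200L),
                              n_boot = 1000L,
                              n_perm = 200L,
                              seed = 1L) {
  structure(list(n_patients = as.integer(n_patients), phantom = phantom,
                 train_phantom = train_phantom,
                 survival_params = survival_params, net = net, train = train,
                 schedule_scale = schedule_scale, reg_corpus = reg_corpus,
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "mt_experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose keys mirror [experiment_config()] arguments.
#' @return an `mt_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

#' Run the full experiment
#'
#' Simulate, train, featurize, label, fit, score and evaluate, end to end:
#' (1) simulate a registration corpus and train the registration network on
#' it (holding out patients with ids divisible by 10); (2) simulate a
#' monitored cohort whose survival is coupled to lesion growth; (3) compute
#' order-invariant monitoring features for every consecutive scan pair;
#' (4) label pairs by 1-year survival from the later scan; (5) fit the
#' wrapper-selected random forest on the discovery half (even patient ids)
#' and score the test half (odd ids); (6) report AUC with bootstrap CI,
#' Mann-Whitney p, a label-permutation null band, and a median-split
#' log-rank test.  Deterministic given the configuration.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory for artifacts (features and
#'   scores CSV, metrics JSON, weights RDS, the resolved config YAML).
#' @param weights optional pre-trained weights (skips stage 1).
#' @param verbose print stage progress.
#' @return list of class `mt_experiment`: `weights`, `features`, `labels`,
#'   `model`, `scores`, `metrics`, `cohort`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           weights = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "mt_experiment_config"))
  say <- function(...) if (verbose) message(...)
  spec <- do.call(phantom_spec, c(config$phantom, list(seed = config$seed)))
  net_cfg <- do.call(regnet_config, config$net)
  sched <- scale_schedule(curriculum_schedule(), config$schedule_scale)
  tr_cfg <- do.call(train_config, c(config$train, list(seed = config$seed)))

  if (is.null(weights)) {
    say("stage 1/6: training registration network")
    train_spec <- if (is.null(config$train_phantom)) spec else
      do.call(phantom_spec, c(config$train_phantom, list(seed = config$seed)))
    reg_cohort <- simulate_cohort(config$reg_corpus$n_patients, train_spec,
                                  config$survival_params,
                                  seed = mix_seed(config$seed, 1))
    ids <- vapply(reg_cohort$patients, `[[`, 0L, "patient_id")
    split <- split_by_id(ids)
    pairs <- make_training_pairs(reg_cohort, config$reg_corpus$n_pairs,
                                 seed = mix_seed(config$seed, 2),
                                 patient_ids = split$train_ids)
    weights <- train_registration(pairs, net_cfg, tr_cfg, loss_config(),
                                  sched, verbose = verbose)
  }

  say("stage 2/6: simulating monitored cohort")
  cohort <- simulate_cohort(config$n_patients, spec, config$survival_params,
                            seed = mix_seed(config$seed, 3))
  say("stage 3/6: computing monitoring features")
  features <- cohort_features(cohort, weights)
  say("stage 4/6: labelling pairs (1-year survival from later scan)")
  surv <- cohort_survival(cohort)
  labels <- make_labels(features, surv)

  say("stage 5/6: fitting survival-score model")
  fcols <- feature_columns(labels)
  disc <- labels[labels$patient_id %% 2L == 0L, , drop = FALSE]
  test <- labels[labels$patient_id %% 2L == 1L, , drop = FALSE]
  if (length(unique(disc$label)) < 2 || length(unique(test$label)) < 2)
    stop("degenerate cohort: a split contains a single class")
  model <- fit_score_model(disc[, fcols], disc$label,
                           seed = mix_seed(config$seed, 4))
  disc$score <- predict_survival_score(model, disc[, fcols])
  test$score <- predict_survival_score(model, test[, fcols])

  say("stage 6/6: evaluation")
  test_auc <- auc(test$score, test$label)
  ci <- bootstrap_ci(test$score, test$label, n_boot = config$n_boot,
                     seed = mix_seed(config$seed, 5))
  p_mw <- mann_whitney_p(test$score, test$label)
  null_auc <- perm_null_auc(test$score, test$label, n_perm = config$n_perm,
                            seed = mix_seed(config$seed, 6))
  disc_split <- median_split(disc$score)
  thr <- attr(disc_split, "threshold")
  disc$risk_group <- disc_split
  test$risk_group <- median_split(test$score, threshold = thr)
  # survival by risk group, one row per patient (first scored pair)
  first <- test[!duplicated(test$patient_id), ]
  sv <- surv[match(first$patient_id, surv$patient_id), ]
  lr_p <- if (length(unique(first$risk_group)) == 2)
    logrank_p(sv$os_days, sv$event, first$risk_group) else NA_real_

  bins <- c(-Inf, 0, 90, 180, 365, Inf)
  bin_lab <- c("<0", "0-90", "90-180", "180-365", ">365")
  by_bin <- lapply(seq_along(bin_lab), function(b) {
    sel <- test$subsequent_day > bins[b] & test$subsequent_day <= bins[b + 1]
    if (sum(sel) >= 4 && length(unique(test$label[sel])) == 2)
      data.frame(bin = bin_lab[b], n = sum(sel),
                 auc = auc(test$score[sel], test$label[sel]))
    else data.frame(bin = bin_lab[b], n = sum(sel), auc = NA_real_)
  })
  by_pair <- lapply(sort(unique(test$pair_index)), function(k) {
    sel <- test$pair_index == k
    if (sum(sel) >= 4 && length(unique(test$label[sel])) == 2)
      data.frame(pair_index = k, n = sum(sel),
                 auc = auc(test$score[sel], test$label[sel]))
    else data.frame(pair_index = k, n = sum(sel), auc = NA_real_)
  })

  metrics <- list(
    n_pairs_labelled = nrow(labels),
    n_excluded = attr(labels, "n_excluded"),
    n_test = nrow(test), n_discovery = nrow(disc),
    test_auc = test_auc, ci_lower = ci[1], ci_upper = ci[2],
    mann_whitney_p = as.numeric(p_mw),
    null_auc_p95 = as.numeric(quantile(null_auc, 0.95)),
    null_auc_p05 = as.numeric(quantile(null_auc, 0.05)),
    logrank_p = lr_p,
    by_time_bin = do.call(rbind, by_bin),
    by_pair_type = do.call(rbind, by_pair))

  result <- structure(list(weights = weights, features = features,
                           labels = labels, model = model,
                           scores = rbind(cbind(disc, set = "discovery"),
                                          cbind(test, set = "test")),
                           metrics = metrics, cohort = cohort,
                           config = config),
                      class = "mt_experiment")
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(result$config), cfg_path)
  stamp <- list(seed = result$config$seed,
                config_md5 = unname(tools::md5sum(cfg_path)))
  write.csv(result$features, file.path(out_dir, "features.csv"),
            row.names = FALSE)
  sc <- result$scores
  sc$risk_group <- as.character(sc$risk_group)
  write.csv(sc[, c("patient_id", "pair_index", "prior_day", "subsequent_day",
                   "label", "score", if ("risk_group" %in% names(sc)) "risk_group",
                   "set")],
            file.path(out_dir, "scores.csv"), row.names = FALSE)
  m <- result$metrics
  m$by_time_bin <- NULL
  m$by_pair_type <- NULL
  jsonlite::write_json(c(m, stamp), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(result$metrics$by_time_bin,
            file.path(out_dir, "auc_by_time_bin.csv"), row.names = FALSE)
  write.csv(result$metrics$by_pair_type,
            file.path(out_dir, "auc_by_pair_type.csv"), row.names = FALSE)
  saveRDS(result$weights, file.path(out_dir, "weights.rds"))
  invisible(out_dir)
}

#' @export
print.mt_experiment <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<mt_experiment: %d labelled pairs (%d test), ",
                     "test AUC %.3f (CI %.3f-%.3f), null p95 %.3f>\n"),
              m$n_pairs_labelled, m$n_test, m$test_auc, m$ci_lower,
              m$ci_upper, m$null_auc_p95))
  invisible(x)
}
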