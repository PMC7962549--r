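# Shared fixtures.  Heavy objects (the trained registration network, the
# end-to-end experiment) are built once per test run and cached, so several
# test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small-scale study conditions: 32^3 grid at 4 mm spacing (the same 128 mm
# physical anatomy as the 64^3 / 2 mm default), reduced channel widths
test_phantom_spec <- function(seed = 11L, ...) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), spacing_mm = c(4, 4, 4),
               seed = seed, ...)
}

test_net_config <- function() {
  regnet_config(channels = c(4L, 8L, 16L, 24L), latent_channels = 24L,
                affine_channels = c(8L, 8L, 16L, 16L, 16L), fc_hidden = 32L)
}

# untrained network for structural / order-invariance checks
small_weights <- function() {
  cached("small_weights", function() regnet_init(test_net_config(), seed = 5L))
}

# one 32^3 phantom volume pair (prior scan + deformed later scan)
small_pair <- function() {
  cached("small_pair", function() {
    spec <- test_phantom_spec()
    coh <- simulate_cohort(2, spec, seed = 21L)
    p <- coh$patients[[1]]
    prior <- generate_phantom(spec, p, 1L)$volume
    subs <- generate_phantom(spec, p, 2L)$volume
    def <- apply_synthetic_deformation(subs, spec, seed = 22L)
    list(prior = prior, subsequent = def$warped, patient = p,
         prior_day = p$scan_days[1], subsequent_day = p$scan_days[2])
  })
}

# registration network trained under the scaled protocol: 200 pairs at 32^3,
# curriculum milestones divided by 10, 20 epochs
trained_registration <- function() {
  cached("trained_registration", function() {
    spec <- test_phantom_spec()
    coh <- simulate_cohort(40, spec, seed = 11L)
    ids <- vapply(coh$patients, `[[`, 0L, "patient_id")
    sp <- split_by_id(ids)
    pairs <- make_training_pairs(coh, 200, seed = 12L,
                                 patient_ids = sp$train_ids)
    hold <- make_training_pairs(coh, 30, seed = 13L,
                                patient_ids = sp$holdout_ids)
    W <- train_registration(pairs, test_net_config(),
                            train_config(lr = 1e-3, epochs = 20L, seed = 1L,
                                         affine_warmup_epochs = 4L),
                            loss_config(),
                            scale_schedule(curriculum_schedule(), 10))
    list(weights = W, holdout_pairs = hold, spec = spec)
  })
}

# end-to-end experiment on a 60-patient cohort with survival coupled to
# lesion growth; the monitoring cohort runs at 64^3 / 2 mm (the fully
# convolutional network transfers across resolutions, and the finer latent
# grid stabilises the pooled statistics)
test_e2e_config <- function(seed = 31L, beta_growth = 15) {
  experiment_config(
    n_patients = 60L,
    phantom = list(grid_shape = c(64L, 64L, 64L), spacing_mm = c(2, 2, 2)),
    survival_params = list(baseline_hazard_per_day = 1 / 400,
                           beta_growth = beta_growth),
    net = list(channels = c(4L, 8L, 16L, 24L), latent_channels = 24L,
               affine_channels = c(8L, 8L, 16L, 16L, 16L), fc_hidden = 32L),
    n_boot = 200L, seed = seed)
}

signal_experiment <- function() {
  cached("signal_experiment", function()
    run_experiment(test_e2e_config(), weights = trained_registration()$weights))
}

# the same cohort conditions with the survival coupling removed
null_experiment <- function() {
  cached("null_experiment", function()
    run_experiment(test_e2e_config(beta_growth = 0),
                   weights = trained_registration()$weights))
}

# occlusion-heatmap localization on single-lesion pairs: fit a survival
# forest on a single-lesion cohort, then check whether the strongest
# occlusion patch of each eligible test pair intersects the true lesion
heatmap_localization <- function(weights, n_pairs = 8L, seed = 71L) {
  cached("heatmap_localization", function() {
    spec1 <- phantom_spec(grid_shape = c(64L, 64L, 64L),
                          spacing_mm = c(2, 2, 2),
                          lesion_count_range = c(1L, 1L), seed = seed)
    coh1 <- simulate_cohort(40, spec1, seed = seed)
    feats <- cohort_features(coh1, weights)
    labs <- make_labels(feats, cohort_survival(coh1))
    fcols <- feature_columns_of(labs)
    disc <- labs[labs$patient_id %% 2L == 0L, ]
    test <- labs[labs$patient_id %% 2L == 1L, ]
    model <- fit_score_model(disc[, fcols], disc$label, seed = seed)
    occ <- occlusion_config(patch_size = 32L, stride = 16L)
    hits <- 0L
    tried <- 0L
    for (r in seq_len(nrow(test))) {
      if (tried >= n_pairs) break
      pid <- test$patient_id[r]
      pat <- coh1$patients[[pid]]
      if (abs(pat$growth_rate) < 0.01) next  # needs a real change
      i <- test$pair_index[r]
      a <- generate_phantom(spec1, pat, i)
      b <- generate_phantom(spec1, pat, i + 1L)
      om <- occlusion_map(a$volume, b$volume, pat$scan_days[i],
                          pat$scan_days[i + 1L], model, weights, occ)
      pv <- om$patch_values
      best <- pv[which.max(abs(pv$delta)), ]
      mask <- a$ground_truth$lesion_mask | b$ground_truth$lesion_mask
      sel <- list(best$x + 0:31, best$y + 0:31, best$z + 0:31)
      hits <- hits + as.integer(any(mask[sel[[1]], sel[[2]], sel[[3]]]))
      tried <- tried + 1L
    }
    list(hits = hits, tried = tried)
  })
}

feature_columns_of <- function(df) {
  grep("^f_[0-9]+_|^dt_days$|^t_sot_days$", names(df), value = TRUE)
}
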