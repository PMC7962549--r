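#' Order-invariant latent feature maps of a scan pair
#'
#' Runs the registration network in both directions and multiplies the
#' latent feature maps element-wise:
#' `M = latent(fixed = subsequent, moving = prior) * latent(fixed = prior,
#' moving = subsequent)`.  Multiplication commutes, so swapping the scans
#' leaves the result bit-identical; only changes detected in both directions
#' survive.  Negative products are preserved (no clipping).
#'
#' @param prior,subsequent preprocessed [volume()]s (or arrays).
#' @param weights trained [regnet_init()] weights.
#' @return array `c(dim/16, latent_channels)` of per-channel products.
#' @export
order_invariant_maps <- function(prior, subsequent, weights) {
  r1 <- forward_register(subsequent, prior, weights)
  r2 <- forward_register(prior, subsequent, weights)
  if (!all(dim(r1$latent_maps) == dim(r2$latent_maps)))
    stop("internal error: latent shapes differ between directions")
  r1$latent_maps * r2$latent_maps
}

#' Pooled statistics of latent feature maps
#'
#' Global average pooling plus the higher moments that a large latent grid
#' warrants: per map, the mean, population standard deviation, Fisher
#' skewness (`m3 / m2^1.5`) and excess kurtosis (`m4 / m2^2 - 3`).  For a
#' constant map (`m2 = 0`) skewness and kurtosis are defined as 0, avoiding
#' NaNs on degenerate maps.
#'
#' @param maps array `c(lx, ly, lz, C)` (or a matrix with maps in columns).
#' @return C x 4 matrix with columns mean, sd, skewness, kurtosis.
#' @export
pool_stats <- function(maps) {
  d <- dim(maps)
  if (length(d) == 4L) maps <- matrix(maps, prod(d[1:3]), d[4])
  else if (is.null(d) || length(d) != 2L) stop("maps must be a 4D array or matrix")
  if (nrow(maps) < 2L) stop("each map needs at least 2 voxels")
  out <- t(apply(maps, 2, function(v) {
    mu <- mean(v)
    cv <- v - mu
    m2 <- mean(cv^2)
    if (m2 <= 0) return(c(mu, 0, 0, 0))
    c(mu, sqrt(m2), mean(cv^3) / m2^1.5, mean(cv^4) / m2^2 - 3)
  }))
  colnames(out) <- c("mean", "sd", "skewness", "kurtosis")
  out
}

#' Monitoring feature vector of a scan pair
#'
#' The classifier input: the four pooled statistics of every order-invariant
#' latent map (in fixed map order: map 1 mean, sd, skewness, kurtosis, map 2
#' ..., etc.), followed by the days elapsed between the two scans and the
#' days from treatment start to the later scan (the prediction origin).
#' With the default 96-channel latent space the vector has
#' `96 * 4 + 2 = 386` entries.  A pure function of (pair, weights): swapping
#' the input order (with the day stamps attached to the scans) yields an
#' identical vector.
#'
#' @param prior,subsequent preprocessed [volume()]s.
#' @param prior_day,subsequent_day acquisition days relative to treatment
#'   start; `subsequent_day` must be strictly later.
#' @param weights trained [regnet_init()] weights.
#' @return named numeric vector of length `4 * latent_channels + 2`
#'   (`f_000_mean, ..., dt_days, t_sot_days`).
#' @export
build_feature_vector <- function(prior, subsequent, prior_day, subsequent_day,
                                 weights) {
  if (!is.finite(prior_day) || !is.finite(subsequent_day))
    stop("scan days must be finite")
  if (subsequent_day <= prior_day)
    stop("chronology error: subsequent_day must be after prior_day")
  maps <- order_invariant_maps(prior, subsequent, weights)
  st <- pool_stats(maps)
  v <- as.vector(t(st))
  names(v) <- as.vector(t(outer(sprintf("f_%03d", seq_len(nrow(st)) - 1),
                                colnames(st), paste, sep = "_")))
  c(v, dt_days = subsequent_day - prior_day, t_sot_days = subsequent_day)
}

#' Feature table for a phantom cohort
#'
#' Generates each patient's scans, forms all consecutive scan pairs, and
#' computes the monitoring feature vector for each pair.
#'
#' @param cohort an `mt_cohort` from [simulate_cohort()].
#' @param weights trained [regnet_init()] weights.
#' @param deform_spec optional [phantom_spec()] whose settings are used to
#'   deform the later scan of each pair. The default is the cohort spec
#'   with the elastic amplitude set to 0 — i.e. rigid repositioning jitter
#'   only: between-visit morphological change in the phantom design is
#'   carried by the lesions themselves, while smooth random elastic fields
#'   are the ground-truth oracle for registration training and evaluation.
#'   Pass the full cohort spec to add elastic change between visits.
#' @param verbose print progress.
#' @return data.frame: patient_id, pair_index, prior_day, subsequent_day,
#'   then the feature columns.
#' @export
cohort_features <- function(cohort, weights, deform_spec = NULL,
                            verbose = FALSE) {
  spec <- cohort$spec
  if (is.null(deform_spec)) {
    deform_spec <- spec
    deform_spec$field_amplitude_mm <- 0
  }
  rows <- list()
  for (p in cohort$patients) {
    n <- length(p$scan_days)
    if (n < 2) next
    scans <- lapply(seq_len(n), function(i) generate_phantom(spec, p, i))
    for (i in seq_len(n - 1)) {
      prior <- scans[[i]]$volume
      subs <- scans[[i + 1]]$volume
      # repositioning jitter on the later scan, reproducible per pair
      def <- apply_synthetic_deformation(subs, deform_spec,
                                         seed = mix_seed(cohort$seed,
                                                         p$patient_id, 7, i))
      fv <- build_feature_vector(prior, def$warped,
                                 p$scan_days[i], p$scan_days[i + 1], weights)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(patient_id = p$patient_id, pair_index = i,
                         prior_day = p$scan_days[i],
                         subsequent_day = p$scan_days[i + 1]),
              as.data.frame(t(fv)))
    }
    if (verbose) message("featurized patient ", p$patient_id)
  }
  do.call(rbind, rows)
}
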