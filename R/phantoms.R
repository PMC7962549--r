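# Synthetic longitudinal phantom cohorts: chest-like volumes whose lesion
# growth rates drive simulated survival, with known ground-truth geometry and
# deformations.  The anatomy is deliberately schematic (body ellipsoid, two
# lung ellipsoids, spine cylinder, spherical lesions): every downstream stage
# consumes normalized intensities only, so realistic CT texture is not needed.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers do not perturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# deterministic integer seed derived from several components, < 2^31
mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  s <- 0
  for (p in parts) s <- (s * 1000003 + (p %% 2147483647)) %% 2147483629
  as.integer(s)
}

#' Phantom cohort specification
#'
#' Geometry, noise and deformation parameters for the synthetic longitudinal
#' chest phantoms.  The seed fully determines every generated volume.
#'
#' @param grid_shape integer length-3 voxel grid (default `c(64, 64, 64)`).
#' @param spacing_mm voxel spacing in mm (default 2 mm isotropic).
#' @param lesion_count_range integer interval, lesions per patient.
#' @param lesion_radius_range_mm interval of baseline lesion radii (mm).
#' @param lesion_radius_cap_mm saturation radius (mm): compound growth is
#'   capped here, emulating the bounded size a lung lesion can reach.
#' @param noise_sd additive Gaussian intensity noise, in `[0, 1]` units.
#' @param elastic_smoothness_mm correlation length of the random elastic
#'   deformation (Gaussian smoothing sigma, mm).
#' @param field_amplitude_mm RMS magnitude of the elastic displacement (mm).
#' @param affine_jitter list with `max_rot_deg` and `max_trans_mm`: bounds of
#'   the random rigid patient-repositioning component.
#' @param seed integer master seed.
#' @return A list of class `mt_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing_mm = c(2, 2, 2),
                         lesion_count_range = c(1L, 3L),
                         lesion_radius_range_mm = c(7, 12),
                         lesion_radius_cap_mm = 13,
                         noise_sd = 0.02,
                         elastic_smoothness_mm = 12,
                         field_amplitude_mm = 4,
                         affine_jitter = list(max_rot_deg = 3, max_trans_mm = 4),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            all(spacing_mm > 0),
            lesion_count_range[1] <= lesion_count_range[2],
            lesion_count_range[1] >= 0,
            lesion_radius_range_mm[1] <= lesion_radius_range_mm[2],
            lesion_radius_range_mm[1] > 0,
            lesion_radius_cap_mm >= lesion_radius_range_mm[2],
            noise_sd >= 0, noise_sd <= 1,
            elastic_smoothness_mm > 0, field_amplitude_mm >= 0)
  extent <- grid_shape * spacing_mm
  if (min(extent) / 2 <= max(lesion_radius_range_mm))
    stop("grid too small for the largest lesion radius")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range_mm = lesion_radius_range_mm,
                 lesion_radius_cap_mm = lesion_radius_cap_mm,
                 noise_sd = noise_sd,
                 elastic_smoothness_mm = elastic_smoothness_mm,
                 field_amplitude_mm = field_amplitude_mm,
                 affine_jitter = affine_jitter,
                 seed = as.integer(seed)),
            class = "mt_phantom_spec")
}

#' Simulated patient record
#'
#' @param patient_id integer identifier (also used for discovery/test and
#'   training-holdout splits).
#' @param growth_rate fractional lesion-radius change per 30 days (may be
#'   negative: shrinking lesions).
#' @param scan_days strictly increasing days relative to treatment start.
#' @param os_days overall survival in days from treatment start.
#' @param event 1 if death observed, 0 if administratively censored.
#' @param pfs_days optional progression-free survival days.
#' @return A list of class `mt_sim_patient`.
#' @export
sim_patient <- function(patient_id, growth_rate, scan_days, os_days, event,
                        pfs_days = NA_real_) {
  stopifnot(length(scan_days) >= 1, !is.unsorted(scan_days, strictly = TRUE),
            os_days > 0, event %in% c(0, 1),
            is.na(pfs_days) || pfs_days <= os_days)
  structure(list(patient_id = as.integer(patient_id),
                 growth_rate = growth_rate,
                 scan_days = as.numeric(scan_days),
                 os_days = as.numeric(os_days), event = as.integer(event),
                 pfs_days = as.numeric(pfs_days)),
            class = "mt_sim_patient")
}

# intensity palette of the schematic phantom (normalized units)
PHANTOM_INTENSITY <- list(air = 0, body = 0.55, lung = 0.12,
                          spine = 0.85, lesion = 0.9)

# mm coordinates of voxel centres relative to the grid centre, per axis
phantom_axes_mm <- function(spec) {
  lapply(1:3, function(k) {
    n <- spec$grid_shape[k]
    (seq_len(n) - (n + 1) / 2) * spec$spacing_mm[k]
  })
}

# geometry of the static anatomy, all in mm relative to grid centre
phantom_anatomy <- function(spec) {
  ext <- spec$grid_shape * spec$spacing_mm
  list(
    body_semi  = c(0.42, 0.38, 0.46) * ext,
    lung_semi  = c(0.16, 0.24, 0.34) * ext,
    lung_off   = rbind(c(-0.18, -0.02, 0) * ext, c(0.18, -0.02, 0) * ext),
    spine_r    = 0.06 * min(ext[1:2]),
    spine_off  = c(0, 0.26 * ext[2]),
    spine_half = 0.42 * ext[3]
  )
}

ellipsoid_mask <- function(axes, centre, semi) {
  dx2 <- ((axes[[1]] - centre[1]) / semi[1])^2
  dy2 <- ((axes[[2]] - centre[2]) / semi[2])^2
  dz2 <- ((axes[[3]] - centre[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Lesion radius after compound growth
#'
#' Radii compound per 30-day period: `r(t) = r0 * (1 + g)^(t / 30)` with `t`
#' in days from treatment start, so a 0.10/30d growth rate turns a 5 mm
#' lesion into `5 * 1.1^3 = 6.655` mm by day 90.
#'
#' @param r0_mm baseline radius at day 0 (mm).
#' @param growth_rate fractional change per 30 days.
#' @param day days from treatment start (may be negative).
#' @param cap_mm saturation radius; compound growth never exceeds it.
#' @return Radius in mm.
#' @export
lesion_radius_at <- function(r0_mm, growth_rate, day, cap_mm = Inf) {
  pmin(r0_mm * (1 + growth_rate)^(day / 30), cap_mm)
}

# patient-level lesion geometry: centres (mm, relative to grid centre) and
# baseline radii, drawn once per patient and reused across all scans
phantom_lesion_geometry <- function(spec, patient) {
  anat <- phantom_anatomy(spec)
  n_lesions <- with_seed(mix_seed(spec$seed, patient$patient_id, 1), {
    if (spec$lesion_count_range[1] == spec$lesion_count_range[2])
      spec$lesion_count_range[1]
    else sample(spec$lesion_count_range[1]:spec$lesion_count_range[2], 1)
  })
  if (n_lesions == 0)
    return(list(centres = matrix(numeric(0), 0, 3), r0_mm = numeric(0)))
  with_seed(mix_seed(spec$seed, patient$patient_id, 2), {
    centres <- matrix(NA_real_, n_lesions, 3)
    r0 <- numeric(n_lesions)
    for (i in seq_len(n_lesions)) {
      placed <- FALSE
      for (attempt in 1:500) {
        r0[i] <- runif(1, spec$lesion_radius_range_mm[1],
                       spec$lesion_radius_range_mm[2])
        r_needed <- max(lesion_radius_at(r0[i], patient$growth_rate,
                                         patient$scan_days,
                                         spec$lesion_radius_cap_mm))
        r_needed <- max(r_needed, r0[i])
        side <- sample(1:2, 1)
        u <- runif(3, -1, 1)
        cand <- anat$lung_off[side, ] + u * anat$lung_semi
        # lesion sphere (at its largest) must stay inside the lung ellipsoid
        margin <- 1 - sqrt(sum(((cand - anat$lung_off[side, ]) / anat$lung_semi)^2))
        if (margin * min(anat$lung_semi) >= r_needed) {
          centres[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("degenerate phantom spec: could not place lesion ", i,
             " after bounded retries (lesions too large for the lungs)")
    }
    list(centres = centres, r0_mm = r0)
  })
}

#' Generate one phantom scan
#'
#' Builds the schematic chest volume for one scan of a simulated patient:
#' mid-intensity body ellipsoid, two low-intensity lungs, high-intensity
#' spine cylinder, and high-intensity spherical lesions whose radii follow
#' the patient's growth rate, plus additive Gaussian noise clipped to
#' `[0, 1]`.  Bit-identical for identical inputs.
#'
#' @param spec a [phantom_spec()].
#' @param patient a [sim_patient()].
#' @param scan_index index into `patient$scan_days`.
#' @return A list with `volume` (a [volume()]) and `ground_truth` (lesion
#'   centres in mm relative to the grid centre, current radii in mm, lesion
#'   voxel mask).
#' @export
generate_phantom <- function(spec, patient, scan_index) {
  stopifnot(inherits(spec, "mt_phantom_spec"), inherits(patient, "mt_sim_patient"))
  if (scan_index < 1 || scan_index > length(patient$scan_days))
    stop("scan_index out of range")
  day <- patient$scan_days[scan_index]
  axes <- phantom_axes_mm(spec)
  anat <- phantom_anatomy(spec)

  vals <- array(PHANTOM_INTENSITY$air, dim = spec$grid_shape)
  body <- ellipsoid_mask(axes, c(0, 0, 0), anat$body_semi)
  vals[body] <- PHANTOM_INTENSITY$body
  for (side in 1:2) {
    lung <- ellipsoid_mask(axes, anat$lung_off[side, ], anat$lung_semi)
    vals[lung] <- PHANTOM_INTENSITY$lung
  }
  sp_d2 <- outer((axes[[1]] - anat$spine_off[1])^2,
                 (axes[[2]] - anat$spine_off[2])^2, `+`)
  spine2d <- sp_d2 <= anat$spine_r^2
  zin <- abs(axes[[3]]) <= anat$spine_half
  spine <- outer(spine2d, zin, `&`)
  vals[spine] <- PHANTOM_INTENSITY$spine

  geom <- phantom_lesion_geometry(spec, patient)
  radii <- lesion_radius_at(geom$r0_mm, patient$growth_rate, day,
                            spec$lesion_radius_cap_mm)
  lesion_mask <- array(FALSE, dim = spec$grid_shape)
  for (i in seq_along(radii)) {
    m <- ellipsoid_mask(axes, geom$centres[i, ], rep(radii[i], 3))
    lesion_mask <- lesion_mask | m
  }
  vals[lesion_mask] <- PHANTOM_INTENSITY$lesion

  if (spec$noise_sd > 0) {
    noise <- with_seed(mix_seed(spec$seed, patient$patient_id, 3, scan_index),
                       array(rnorm(length(vals), 0, spec$noise_sd),
                             dim = spec$grid_shape))
    vals <- vals + noise
  }
  vals <- pmin(pmax(vals, 0), 1)

  list(volume = volume(vals, spacing = spec$spacing_mm,
                       origin = -(spec$grid_shape - 1) / 2 * spec$spacing_mm),
       ground_truth = list(centres_mm = geom$centres, radii_mm = radii,
                           r0_mm = geom$r0_mm, day = day,
                           lesion_mask = lesion_mask))
}

# default longitudinal scan schedule: pre-baseline, baseline, then follow-ups
# at the cohort's typical intervals (PBL -102 d, BL -26 d, FU1 +68 d, then
# every 77 d), each jittered by +/- 10 days
default_scan_schedule <- function(n_scans = 3) {
  base <- c(-102, -26, 68)
  if (n_scans > 3) base <- c(base, 68 + 77 * seq_len(n_scans - 3))
  base[seq_len(n_scans)]
}

#' Simulate a longitudinal phantom cohort
#'
#' Draws per-patient lesion growth rates and couples survival to them:
#' `growth_rate ~ Normal(0.03, 0.05)` per 30 days (truncated at -0.05) and
#' `OS ~ Exponential(rate = baseline_hazard_per_day * exp(beta_growth *
#' growth_rate))`, administratively censored at `censor_horizon_days`.
#' Pre-treatment scans (PBL, BL) are always acquired; follow-up scans only
#' while the patient is alive, so every patient retains at least two scans.
#'
#' @param n_patients number of patients (ids `1..n_patients`).
#' @param spec a [phantom_spec()].
#' @param survival_params list with `baseline_hazard_per_day` (default 1/400)
#'   and `beta_growth` (default 15, log-hazard units per unit growth rate).
#' @param seed integer seed (fully determines the cohort).
#' @param n_scans scheduled scans per patient (default 6: PBL, BL, FU1-FU4,
#'   matching the roughly six scans per patient of a two-year follow-up
#'   routine with visits every 11 weeks).
#' @param censor_horizon_days administrative censoring horizon (default 900).
#' @return A list of class `mt_cohort`: `patients` (list of [sim_patient()]),
#'   `spec`, `seed`, and the survival parameters.
#' @export
simulate_cohort <- function(n_patients, spec = phantom_spec(),
                            survival_params = list(baseline_hazard_per_day = 1 / 400,
                                                   beta_growth = 15),
                            seed = 1L, n_scans = 6L,
                            censor_horizon_days = 900) {
  stopifnot(n_patients >= 1)
  h0 <- survival_params$baseline_hazard_per_day
  beta <- survival_params$beta_growth
  if (!is.finite(h0) || h0 <= 0) stop("baseline_hazard_per_day must be positive")
  patients <- with_seed(mix_seed(seed, 17), {
    lapply(seq_len(n_patients), function(pid) {
      g <- rnorm(1, 0.03, 0.05)
      while (g < -0.05) g <- rnorm(1, 0.03, 0.05)
      sched <- default_scan_schedule(n_scans) + runif(n_scans, -10, 10)
      sched <- sort(sched)
      os <- rexp(1, rate = h0 * exp(beta * g))
      event <- 1L
      if (os > censor_horizon_days) {
        os <- censor_horizon_days
        event <- 0L
      }
      keep <- sched < 0 | sched < os   # follow-ups only while alive
      days <- round(sched[keep], 1)
      os <- max(0.1, round(os, 1))
      pfs <- min(os, max(1, round(os * runif(1, 0.4, 0.95))))
      sim_patient(pid, g, days, os, event, pfs)
    })
  })
  structure(list(patients = patients, spec = spec, seed = as.integer(seed),
                 survival_params = list(baseline_hazard_per_day = h0,
                                        beta_growth = beta),
                 censor_horizon_days = censor_horizon_days),
            class = "mt_cohort")
}

#' Survival records of a cohort as a data frame
#'
#' @param cohort an `mt_cohort`.
#' @return data.frame with patient_id, growth_rate, os_days, event, pfs_days.
#' @export
cohort_survival <- function(cohort) {
  do.call(rbind, lapply(cohort$patients, function(p)
    data.frame(patient_id = p$patient_id, growth_rate = p$growth_rate,
               os_days = p$os_days, event = p$event, pfs_days = p$pfs_days)))
}

#' Apply a smooth random deformation with known ground truth
#'
#' Composes a small rigid jitter (rotation + translation, emulating patient
#' repositioning) with Gaussian-smoothed random elastic displacement, and
#' warps the volume under the combined field.  The exact displacement field
#' is returned, so `dense_warp(volume, field)` reproduces the warped volume
#' bit-identically.
#'
#' @param vol a [volume()].
#' @param spec a [phantom_spec()] (supplies smoothness, amplitude, jitter).
#' @param seed integer seed.
#' @param amplitude_mm optional override of the elastic RMS amplitude.
#' @return list with `warped` (a [volume()]) and `field` (array
#'   `c(dim, 3)` of voxel-unit displacements on the fixed grid).
#' @export
apply_synthetic_deformation <- function(vol, spec, seed, amplitude_mm = NULL) {
  stopifnot(is_volume(vol))
  d <- dim(vol$values)
  amp <- if (is.null(amplitude_mm)) spec$field_amplitude_mm else amplitude_mm
  field <- with_seed(mix_seed(seed, 23), {
    u <- array(0, dim = c(d, 3))
    if (amp > 0) {
      sigma_vox <- spec$elastic_smoothness_mm / mean(spec$spacing_mm)
      for (c in 1:3) {
        w <- array(rnorm(prod(d)), dim = d)
        u[, , , c] <- smooth_gaussian3d(w, sigma_vox)
      }
      rms <- sqrt(mean(u^2) * 3)            # RMS of the magnitude
      amp_vox <- amp / mean(spec$spacing_mm)
      u <- u * (amp_vox / max(rms, 1e-12))
    }
    # rigid jitter: rotation about a random axis through the grid centre
    jit <- spec$affine_jitter
    theta <- runif(1, -jit$max_rot_deg, jit$max_rot_deg) * pi / 180
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
    trans_vox <- runif(3, -jit$max_trans_mm, jit$max_trans_mm) / spec$spacing_mm
    ctr <- (d - 1) / 2
    P <- grid_coords(d)                      # N x 3, 0-based
    aff <- sweep(P, 2, ctr) %*% t(R)
    aff <- sweep(aff, 2, ctr + trans_vox, `+`) - P
    u + array(aff, dim = c(d, 3))
  })
  warped <- dense_warp(vol, field)
  list(warped = warped, field = field)
}

# 0-based voxel coordinates of every grid point, as an N x 3 matrix
# (memoized: the same grids recur thousands of times during training)
grid_coords_cache <- new.env(parent = emptyenv())
grid_coords <- function(d) {
  key <- paste(d, collapse = "x")
  P <- grid_coords_cache[[key]]
  if (is.null(P)) {
    P <- unname(as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1),
                                      0:(d[3] - 1))))
    grid_coords_cache[[key]] <- P
  }
  P
}

# separable Gaussian smoothing with symmetric boundary handling
smooth_gaussian3d <- function(arr, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  for (axis in 0:2) arr <- sepconv3d_axis(arr, k, axis, FALSE)
  arr
}
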