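#' Occlusion configuration
#'
#' @param patch_size cubic occlusion patch edge in voxels (default 32;
#'   small-volume runs typically use 8-16).
#' @param stride scroll step in voxels (default `patch_size / 2`,
#'   overlapping patches).
#' @param fill_value normalized intensity used to fill the occluded region
#'   (default 0, i.e. sub-fat density).
#' @return list of class `mt_occlusion_config`.
#' @export
occlusion_config <- function(patch_size = 32L, stride = NULL, fill_value = 0) {
  patch_size <- as.integer(patch_size)
  if (is.null(stride)) stride <- max(1L, patch_size %/% 2L)
  stride <- as.integer(stride)
  stopifnot(patch_size >= 1, stride >= 1, stride <= patch_size,
            fill_value >= 0, fill_value <= 1)
  structure(list(patch_size = patch_size, stride = stride,
                 fill_value = fill_value), class = "mt_occlusion_config")
}

#' Deformation-magnitude map
#'
#' Per-voxel Euclidean norm of the displacement, converted to mm; hotspots
#' correspond to regions of gross morphological change.
#'
#' @param field displacement array `c(nx, ny, nz, 3)` in voxel units.
#' @param spacing_mm voxel spacing.
#' @return 3D array of displacement magnitudes in mm.
#' @export
deformation_magnitude <- function(field, spacing_mm = c(2, 2, 2)) {
  field <- field_as_array(field)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  d <- dim(field)[1:3]
  mm2 <- array(0, dim = d)
  for (c in 1:3) mm2 <- mm2 + (field[, , , c] * spacing_mm[c])^2
  sqrt(mm2)
}

# patch start positions (1-based) scrolling an axis, always covering the end
patch_starts <- function(n, patch, stride) {
  s <- seq(1L, max(1L, n - patch + 1L), by = stride)
  if (s[length(s)] + patch - 1L < n) s <- c(s, n - patch + 1L)
  s
}

#' Occlusion-sensitivity prognostic map
#'
#' Scrolls a cubic patch through the scan pair; at each position the patch
#' is occluded with `fill_value` in BOTH the prior and the subsequent scan
#' (a morphological change needs two time points), the monitoring feature
#' vector is rebuilt, and the survival score recomputed.  The patch value is
#' `original_score - occluded_score` (positive = the region supports the
#' predicted survival); voxel values average over all covering patches, and
#' are 0 where no patch covered.
#'
#' @param prior,subsequent preprocessed [volume()]s.
#' @param prior_day,subsequent_day scan days relative to treatment start.
#' @param model an [fit_score_model()] survival-score model.
#' @param weights trained [regnet_init()] weights.
#' @param config an [occlusion_config()].
#' @return list of class `mt_prognostic_map`: `map` (3D array),
#'   `original_score`, `patch_values` (data.frame of patch positions and
#'   score deltas), `config`.
#' @export
occlusion_map <- function(prior, subsequent, prior_day, subsequent_day,
                          model, weights, config = occlusion_config()) {
  stopifnot(inherits(model, "mt_score_model"),
            inherits(config, "mt_occlusion_config"))
  pv <- vol_values(prior)
  sv <- vol_values(subsequent)
  d <- dim(pv)
  if (any(config$patch_size > d)) stop("occlusion patch larger than the volume")
  fv0 <- build_feature_vector(pv, sv, prior_day, subsequent_day, weights)
  s0 <- predict_survival_score(model, t(fv0))
  starts <- expand.grid(x = patch_starts(d[1], config$patch_size, config$stride),
                        y = patch_starts(d[2], config$patch_size, config$stride),
                        z = patch_starts(d[3], config$patch_size, config$stride))
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  deltas <- numeric(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    ix <- starts$x[i] + seq_len(config$patch_size) - 1L
    iy <- starts$y[i] + seq_len(config$patch_size) - 1L
    iz <- starts$z[i] + seq_len(config$patch_size) - 1L
    po <- pv; so <- sv
    po[ix, iy, iz] <- config$fill_value
    so[ix, iy, iz] <- config$fill_value
    fv <- build_feature_vector(po, so, prior_day, subsequent_day, weights)
    si <- predict_survival_score(model, t(fv))
    deltas[i] <- s0 - si
    acc[ix, iy, iz] <- acc[ix, iy, iz] + deltas[i]
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  map <- acc
  map[cnt > 0] <- map[cnt > 0] / cnt[cnt > 0]
  structure(list(map = map, original_score = s0,
                 patch_values = cbind(starts, delta = deltas),
                 config = config),
            class = "mt_prognostic_map")
}

#' Fuse prognostic and deformation maps
#'
#' Element-wise product of the min-max-normalized absolute prognostic map
#' and the min-max-normalized deformation magnitude: high only where a
#' region is both prognostically sensitive and morphologically changing.
#' Degenerate (constant) inputs normalize to 1 if non-zero and 0 otherwise.
#'
#' @param prognostic an [occlusion_map()] result or 3D array.
#' @param magnitude deformation-magnitude array (same shape).
#' @return fused 3D array in `[0, 1]`.
#' @export
fuse_maps <- function(prognostic, magnitude) {
  p <- if (inherits(prognostic, "mt_prognostic_map")) prognostic$map else prognostic
  minmax <- function(x) {
    x <- abs(x)
    rng <- range(x)
    if (rng[2] == rng[1]) {
      if (rng[2] == 0) return(x * 0)
      return(x / rng[2])
    }
    (x - rng[1]) / (rng[2] - rng[1])
  }
  minmax(p) * minmax(magnitude)
}
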