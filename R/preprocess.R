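#' Preprocessing configuration
#'
#' Settings that map heterogeneous CT volumes onto the fixed-intensity,
#' fixed-spacing, fixed-shape tensors the registration network consumes.
#' Hounsfield units are clipped between fat (-120 HU) and cancellous bone
#' (300 HU) and rescaled to `[0, 1]`; volumes are linearly resampled to
#' isotropic spacing and centre-cropped/padded to a regular shape.
#'
#' @param hu_low,hu_high HU clipping window (defaults -120 and 300).
#' @param target_spacing_mm isotropic target voxel size in mm (default 2).
#' @param target_shape integer length-3 output shape (default
#'   `c(192, 192, 160)`; small-scale runs typically use `c(64, 64, 64)`).
#' @param axial_crop_fractions fractions of the axial (z) extent to discard
#'   from the top and bottom before cropping, default `c(0, 0)`.  This is a
#'   configurable stand-in for anatomical body-part cropping, which requires
#'   a separately trained model and is out of scope.
#' @return A list of class `mt_preprocess_config`.
#' @export
preprocess_config <- function(hu_low = -120, hu_high = 300,
                              target_spacing_mm = 2,
                              target_shape = c(192L, 192L, 160L),
                              axial_crop_fractions = c(0, 0)) {
  if (hu_low >= hu_high) stop("hu_low must be < hu_high")
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape <= 0L))
    stop("target_shape must be 3 positive integers")
  if (any(axial_crop_fractions < 0) || sum(axial_crop_fractions) >= 1)
    stop("axial_crop_fractions must be non-negative and sum to < 1")
  structure(list(hu_low = hu_low, hu_high = hu_high,
                 target_spacing_mm = target_spacing_mm,
                 target_shape = target_shape,
                 axial_crop_fractions = axial_crop_fractions),
            class = "mt_preprocess_config")
}

#' Clip and rescale Hounsfield units
#'
#' `v' = (clamp(v, hu_low, hu_high) - hu_low) / (hu_high - hu_low)`, so the
#' default window maps -120 HU (fat) to 0 and 300 HU (cancellous bone) to 1.
#' Monotone non-decreasing in HU.
#'
#' @param vol a [volume()] in raw HU.
#' @param hu_low,hu_high clipping window, `hu_low < hu_high`.
#' @return A [volume()] with values in `[0, 1]`.
#' @export
normalize_hu <- function(vol, hu_low = -120, hu_high = 300) {
  stopifnot(is_volume(vol))
  if (hu_low >= hu_high) stop("hu_low must be < hu_high")
  v <- pmin(pmax(vol$values, hu_low), hu_high)
  vol$values <- (v - hu_low) / (hu_high - hu_low)
  vol
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation onto a grid with `target_spacing_mm` isotropic
#' voxels.  The new shape is `round(old_shape * old_spacing / target)`; the
#' world position of voxel centres is preserved (both grids share the origin).
#'
#' @param vol a [volume()].
#' @param target_spacing_mm positive scalar, mm.
#' @return The resampled [volume()].
#' @export
resample_isotropic <- function(vol, target_spacing_mm = 2) {
  stopifnot(is_volume(vol))
  if (!is.finite(target_spacing_mm) || target_spacing_mm <= 0)
    stop("target_spacing_mm must be positive")
  d <- dim(vol$values)
  new_d <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing_mm)))
  if (all(new_d == d) && all(abs(vol$spacing - target_spacing_mm) < 1e-12))
    return(vol)
  # target voxel i (0-based) sits at world offset i * target; source index
  # (0-based) = world / source_spacing
  ax <- lapply(1:3, function(k) (seq_len(new_d[k]) - 1) * target_spacing_mm / vol$spacing[k])
  coords <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  # clamp to the grid so border voxels replicate rather than fade to 0
  for (k in 1:3) coords[, k] <- pmin(pmax(coords[, k], 0), d[k] - 1)
  out <- sample3d_fw(vol$values, coords)
  volume(array(out, dim = new_d), spacing = rep(target_spacing_mm, 3),
         origin = vol$origin)
}

#' Symmetric centre crop / pad to a target shape
#'
#' Crops and/or pads each axis symmetrically to `target_shape`; when the
#' difference is odd the extra voxel is cropped/padded on the high-index
#' side.  Padding uses `pad_value` (default 0, i.e. normalized air).
#'
#' @param vol a [volume()].
#' @param target_shape integer length-3.
#' @param pad_value fill value for padded voxels.
#' @return A [volume()] of shape `target_shape`.
#' @export
center_crop_pad <- function(vol, target_shape, pad_value = 0) {
  stopifnot(is_volume(vol))
  target_shape <- as.integer(target_shape)
  d <- dim(vol$values)
  out <- array(pad_value, dim = target_shape)
  src_start <- dst_start <- integer(3)
  len <- integer(3)
  for (k in 1:3) {
    if (d[k] >= target_shape[k]) {        # crop
      src_start[k] <- (d[k] - target_shape[k]) %/% 2L
      dst_start[k] <- 0L
      len[k] <- target_shape[k]
    } else {                               # pad
      src_start[k] <- 0L
      dst_start[k] <- (target_shape[k] - d[k]) %/% 2L
      len[k] <- d[k]
    }
  }
  out[dst_start[1] + seq_len(len[1]), dst_start[2] + seq_len(len[2]),
      dst_start[3] + seq_len(len[3])] <-
    vol$values[src_start[1] + seq_len(len[1]), src_start[2] + seq_len(len[2]),
               src_start[3] + seq_len(len[3])]
  new_origin <- vol$origin + (src_start - dst_start) * vol$spacing
  volume(out, spacing = vol$spacing, origin = new_origin)
}

#' Full preprocessing pipeline
#'
#' Optional axial crop, HU normalization, isotropic resampling, and centre
#' crop/pad, in that order.  Idempotent on already-processed volumes (a
#' second pass changes nothing beyond interpolation round-off).
#'
#' @param vol a [volume()] in raw HU (or already normalized; values already
#'   inside `[0, 1]` pass through the HU window unchanged only if the window
#'   is the default and the data were normalized with it).
#' @param config a [preprocess_config()].
#' @param normalize apply the HU window (set `FALSE` for volumes already in
#'   `[0, 1]`, e.g. synthetic phantoms).
#' @return A preprocessed [volume()].
#' @export
preprocess_volume <- function(vol, config = preprocess_config(), normalize = TRUE) {
  stopifnot(is_volume(vol), inherits(config, "mt_preprocess_config"))
  f <- config$axial_crop_fractions
  if (any(f > 0)) {
    nz <- dim(vol$values)[3]
    keep <- seq.int(1L + floor(f[1] * nz), nz - floor(f[2] * nz))
    vol <- volume(vol$values[, , keep, drop = FALSE], vol$spacing,
                  vol$origin + c(0, 0, (keep[1] - 1) * vol$spacing[3]))
  }
  if (normalize) vol <- normalize_hu(vol, config$hu_low, config$hu_high)
  vol <- resample_isotropic(vol, config$target_spacing_mm)
  center_crop_pad(vol, config$target_shape, pad_value = 0)
}
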