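#' 3D image volume
#'
#' A `Volume` is the unit of all imaging in the package: a 3D scalar grid with
#' voxel spacing and origin in millimetres.  The array is indexed `(x, y, z)`
#' in the same order as the NIfTI on-disk layout; world coordinates are
#' `origin + (index - 1) * spacing` with identity direction cosines (any
#' upstream DICOM conversion is assumed to have resolved orientation).
#'
#' @param values 3D numeric array of intensities (raw HU before
#'   normalization, `[0, 1]` after).
#' @param spacing numeric length-3, voxel spacing in mm (all positive).
#' @param origin numeric length-3, world position of the first voxel in mm.
#' @return An object of class `mt_volume`.
#' @export
volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("volume values must be a 3D array, got ", length(dim(values)), "D")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "mt_volume")
}

#' @export
print.mt_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mt_volume %dx%dx%d, spacing %s mm, range [%.3g, %.3g]>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.mt_volume <- function(x) dim(x$values)

is_volume <- function(x) inherits(x, "mt_volume")

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), "D: ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  # origin = world coordinate of voxel (1,1,1)
  orig <- as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
  volume(arr, spacing = sp, origin = orig)
}

#' Write a volume as NIfTI
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  xf <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
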