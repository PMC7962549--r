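#' Registration network configuration
#'
#' Two-stage registration architecture: a VGG-like affine stage (five
#' stride-2 convolutional blocks followed by two fully-connected layers
#' regressing the 12 affine parameters) and a U-Net deformable stage (four
#' stride-2 encoder blocks, a stride-1 convolutional latent block, and four
#' x2-upsampling decoder blocks with encoder-decoder skip connections).
#' Group normalization is used throughout, so the small training batch does
#' not destabilise the statistics.
#'
#' @param channels encoder channel widths of the deformable stage, length 4.
#' @param latent_channels channels of the stride-1 latent block (default 96);
#'   the pooled latent maps are the monitoring features.
#' @param affine_channels channel widths of the five affine-stage blocks.
#' @param fc_hidden width of the first fully-connected affine layer.
#' @param groups requested group count for group normalization (capped at
#'   the channel count of each layer).
#' @param leaky_slope negative slope of the leaky-ReLU activations.
#' @return A list of class `mt_regnet_config`.
#' @export
regnet_config <- function(channels = c(16L, 32L, 64L, 96L),
                          latent_channels = 96L,
                          affine_channels = c(16L, 32L, 64L, 96L, 96L),
                          fc_hidden = 64L,
                          groups = 8L,
                          leaky_slope = 0.1) {
  stopifnot(length(channels) == 4, all(channels > 0),
            latent_channels > 0, length(affine_channels) == 5,
            fc_hidden > 0, groups >= 1)
  structure(list(channels = as.integer(channels),
                 latent_channels = as.integer(latent_channels),
                 affine_channels = as.integer(affine_channels),
                 fc_hidden = as.integer(fc_hidden),
                 groups = as.integer(groups),
                 leaky_slope = leaky_slope),
            class = "mt_regnet_config")
}

# identity affine as a 3 x 4 matrix (3x3 linear | translation)
identity_affine <- function() cbind(diag(3), c(0, 0, 0))

#' Initialise registration-network weights
#'
#' The affine head is initialised to output exactly the identity transform
#' (zero final-layer weights, identity bias) and the dense-field output
#' layer is zero-initialised, so an untrained network performs the identity
#' warp.  This makes early training stable: the network starts from "no
#' deformation" and learns corrections.
#'
#' @param config a [regnet_config()].
#' @param seed integer seed; fully determines the weights.
#' @return Named list of weight arrays, with the config stored as an
#'   attribute; class `mt_regnet_weights`.
#' @export
regnet_init <- function(config = regnet_config(), seed = 1L) {
  W <- with_seed(mix_seed(seed, 41), {
    W <- list()
    add_block <- function(W, prefix, cin, cout) {
      W[[paste0(prefix, "_w")]] <- init_conv_w(cin, cout)
      W[[paste0(prefix, "_b")]] <- numeric(cout)
      W[[paste0(prefix, "_g")]] <- rep(1, cout)
      W[[paste0(prefix, "_bb")]] <- numeric(cout)
      W
    }
    ac <- config$affine_channels
    cin <- 2L
    for (i in 1:5) {
      W <- add_block(W, paste0("aff", i), cin, ac[i])
      cin <- ac[i]
    }
    W$aff_fc1_W <- init_fc_w(ac[5], config$fc_hidden)
    W$aff_fc1_b <- numeric(config$fc_hidden)
    W$aff_fc2_W <- matrix(0, 12, config$fc_hidden)   # identity-initialised head
    W$aff_fc2_b <- as.vector(identity_affine())
    ch <- config$channels
    cin <- 2L
    for (i in 1:4) {
      W <- add_block(W, paste0("enc", i), cin, ch[i])
      cin <- ch[i]
    }
    W <- add_block(W, "lat", ch[4], config$latent_channels)
    up_in <- config$latent_channels
    for (i in 3:1) {
      pre <- paste0("up", i)
      W[[paste0(pre, "_w")]] <- init_tconv_w(up_in, ch[i])
      W[[paste0(pre, "_b")]] <- numeric(ch[i])
      W[[paste0(pre, "_g")]] <- rep(1, ch[i])
      W[[paste0(pre, "_bb")]] <- numeric(ch[i])
      W <- add_block(W, paste0("mrg", i), 2L * ch[i], ch[i])
      up_in <- ch[i]
    }
    W$up0_w <- init_tconv_w(ch[1], ch[1])
    W$up0_b <- numeric(ch[1])
    W$up0_g <- rep(1, ch[1])
    W$up0_bb <- numeric(ch[1])
    W$out_w <- array(0, dim = c(3, 3, 3, ch[1], 3))   # identity-initialised field
    W$out_b <- numeric(3)
    W
  })
  structure(W, config = config, class = "mt_regnet_weights")
}

vol_values <- function(x) if (is_volume(x)) x$values else x

affine_forward <- function(W, x2, cfg, with_cache = FALSE) {
  caches <- vector("list", 5)
  h <- x2
  for (i in 1:5) {
    bl <- block_fw(h, W, paste0("aff", i), 2L, cfg$groups, cfg$leaky_slope)
    h <- bl$y
    caches[[i]] <- bl$cache
  }
  d <- dim(h)
  hm <- matrix(h, prod(d[1:3]), d[4])
  gap <- colMeans(hm)
  z1 <- fc_fw(gap, W$aff_fc1_W, W$aff_fc1_b)
  a1 <- lrelu_fw(z1, cfg$leaky_slope)
  a12 <- fc_fw(a1$y, W$aff_fc2_W, W$aff_fc2_b)
  A <- matrix(a12, 3, 4)
  cache <- if (with_cache)
    list(blocks = caches, conv_out_dim = d, gap = gap, a1 = a1$y,
         act1 = a1$cache) else NULL
  list(A = A, cache = cache)
}

affine_backward <- function(W, cache, gA, cfg) {
  g12 <- as.vector(gA)
  fc2 <- fc_bw(cache$a1, W$aff_fc2_W, g12)
  g1 <- lrelu_bw(cache$act1, fc2$gx, cfg$leaky_slope)
  fc1 <- fc_bw(cache$gap, W$aff_fc1_W, g1)
  grads <- list(aff_fc2_W = fc2$gW, aff_fc2_b = fc2$gb,
                aff_fc1_W = fc1$gW, aff_fc1_b = fc1$gb)
  d <- cache$conv_out_dim
  nvox <- prod(d[1:3])
  gh <- matrix(rep(fc1$gx / nvox, each = nvox), nvox, d[4])
  dim(gh) <- d
  for (i in 5:1) {
    bb <- block_bw(cache$blocks[[i]], W, paste0("aff", i), gh,
                   cfg$leaky_slope, need_gx = (i > 1))
    grads <- c(grads, bb$grads)
    gh <- bb$gx
  }
  grads
}

deform_forward <- function(W, x2, cfg, with_cache = FALSE) {
  enc <- vector("list", 4)
  caches <- list()
  h <- x2
  for (i in 1:4) {
    bl <- block_fw(h, W, paste0("enc", i), 2L, cfg$groups, cfg$leaky_slope)
    h <- bl$y
    enc[[i]] <- h
    caches[[paste0("enc", i)]] <- bl$cache
  }
  lat <- block_fw(h, W, "lat", 1L, cfg$groups, cfg$leaky_slope)
  caches$lat <- lat$cache
  latent <- lat$y
  h <- latent
  for (i in 3:1) {
    up <- upblock_fw(h, W, paste0("up", i), cfg$groups, cfg$leaky_slope)
    caches[[paste0("up", i)]] <- up$cache
    cat2 <- abind4(up$y, enc[[i]])
    mg <- block_fw(cat2, W, paste0("mrg", i), 1L, cfg$groups, cfg$leaky_slope)
    caches[[paste0("mrg", i)]] <- mg$cache
    h <- mg$y
  }
  up0 <- upblock_fw(h, W, "up0", cfg$groups, cfg$leaky_slope)
  caches$up0 <- up0$cache
  out <- conv_fw(up0$y, W$out_w, W$out_b, 1L)
  caches$out <- out$cache
  field <- out$y
  list(field = field, latent = latent,
       cache = if (with_cache) caches else NULL)
}

# split a 4D array along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

deform_backward <- function(W, cache, gfield, cfg, need_gx = TRUE) {
  cfgch <- attr(W, "config")$channels
  ob <- conv_bw(cache$out, W$out_w, gfield, TRUE)
  grads <- list(out_w = ob$gw, out_b = ob$gb)
  u0 <- upblock_bw(cache$up0, W, "up0", ob$gx, cfg$leaky_slope)
  grads <- c(grads, u0$grads)
  gh <- u0$gx
  genc <- vector("list", 4)
  for (i in 1:3) {
    mb <- block_bw(cache[[paste0("mrg", i)]], W, paste0("mrg", i), gh,
                   cfg$leaky_slope)
    grads <- c(grads, mb$grads)
    ci <- cfgch[i]
    g_up <- mb$gx[, , , seq_len(ci), drop = FALSE]
    genc[[i]] <- mb$gx[, , , ci + seq_len(ci), drop = FALSE]
    ub <- upblock_bw(cache[[paste0("up", i)]], W, paste0("up", i), g_up,
                     cfg$leaky_slope)
    grads <- c(grads, ub$grads)
    gh <- ub$gx
  }
  # gh now flows into the latent block output
  lb <- block_bw(cache$lat, W, "lat", gh, cfg$leaky_slope)
  grads <- c(grads, lb$grads)
  gh <- lb$gx
  for (i in 4:1) {
    if (i < 4 && !is.null(genc[[i]])) gh <- gh + genc[[i]]
    eb <- block_bw(cache[[paste0("enc", i)]], W, paste0("enc", i), gh,
                   cfg$leaky_slope, need_gx = (i > 1 || need_gx))
    grads <- c(grads, eb$grads)
    gh <- eb$gx
  }
  list(grads = grads, gx = gh)
}

#' Warp a volume under an affine transform
#'
#' Backward warping: the output at fixed-grid voxel `p` (0-based) samples the
#' input trilinearly at `A %*% c(p, 1)`; samples outside the domain are 0.
#'
#' @param vol a [volume()] or 3D array (the moving image).
#' @param affine 3 x 4 matrix (3x3 linear part | translation), in voxel
#'   coordinates of the fixed grid.
#' @return Warped image, same type as the input.
#' @export
affine_warp <- function(vol, affine) {
  v <- vol_values(vol)
  if (any(!is.finite(affine))) stop("non-finite affine parameters")
  d <- dim(v)
  P <- grid_coords(d)
  coords <- P %*% t(affine[, 1:3]) + matrix(affine[, 4], nrow(P), 3, byrow = TRUE)
  out <- array(sample3d_fw(v, coords), dim = d)
  if (is_volume(vol)) volume(out, vol$spacing, vol$origin) else out
}

#' Warp a volume under a dense displacement field
#'
#' The output at fixed-grid voxel `x` samples the input at `x + u(x)`
#' (trilinear, zero fill outside the domain); displacements are in voxel
#' units.
#'
#' @param vol a [volume()] or 3D array.
#' @param field displacement array `c(dim(vol), 3)`.
#' @return Warped image, same type as the input.
#' @export
dense_warp <- function(vol, field) {
  v <- vol_values(vol)
  d <- dim(v)
  if (!all(dim(field) == c(d, 3))) stop("field shape does not match volume")
  P <- grid_coords(d)
  coords <- P + matrix(field, ncol = 3)
  out <- array(sample3d_fw(v, coords), dim = d)
  if (is_volume(vol)) volume(out, vol$spacing, vol$origin) else out
}

#' Register a pair of preprocessed volumes
#'
#' Runs the two-stage network: the affine stage sees `(fixed, moving)` as two
#' channels and regresses a 3x4 affine; the deformable stage sees
#' `(fixed, affine-warped moving)` and outputs a dense displacement field
#' plus the latent feature maps of its stride-1 latent block.  The returned
#' warped moving image is `dense_warp(affine_warp(moving, affine), field)`.
#'
#' @param fixed,moving preprocessed [volume()]s (or 3D arrays) of identical
#'   shape, divisible by 16 along every axis.
#' @param weights a [regnet_init()] weight set.
#' @param with_cache keep the forward caches (used internally by training).
#' @return A list of class `mt_registration`: `affine` (3x4), `field`
#'   (`c(dim, 3)` voxel displacements), `warped_moving`, `latent_maps`
#'   (`c(dim/16, latent_channels)`), and optionally `cache`.
#' @export
forward_register <- function(fixed, moving, weights, with_cache = FALSE) {
  stopifnot(inherits(weights, "mt_regnet_weights"))
  cfg <- attr(weights, "config")
  f <- vol_values(fixed)
  m <- vol_values(moving)
  d <- dim(f)
  if (!all(dim(m) == d)) stop("fixed and moving shapes differ")
  if (any(d %% 16L != 0L))
    stop("input shape must be divisible by 16, got ", paste(d, collapse = "x"))
  x_aff <- abind4(array(f, c(d, 1L)), array(m, c(d, 1L)))
  af <- affine_forward(weights, x_aff, cfg, with_cache)
  P <- grid_coords(d)
  coords_aff <- P %*% t(af$A[, 1:3]) +
    matrix(af$A[, 4], nrow(P), 3, byrow = TRUE)
  m_aff <- array(sample3d_fw(m, coords_aff), dim = d)
  x_def <- abind4(array(f, c(d, 1L)), array(m_aff, c(d, 1L)))
  df <- deform_forward(weights, x_def, cfg, with_cache)
  coords_dense <- P + matrix(df$field, ncol = 3)
  warped <- array(sample3d_fw(m_aff, coords_dense), dim = d)
  res <- list(affine = af$A, field = df$field, warped_moving = warped,
              latent_maps = df$latent, dim = d)
  if (with_cache)
    res$cache <- list(affine = af$cache, deform = df$cache, P = P,
                      coords_aff = coords_aff, coords_dense = coords_dense,
                      m_aff = m_aff, moving = m, fixed = f)
  class(res) <- "mt_registration"
  res
}

#' @export
print.mt_registration <- function(x, ...) {
  cat(sprintf("<mt_registration %s, %d latent maps, mean |u| = %.3f vox>\n",
              paste(x$dim, collapse = "x"), dim(x$latent_maps)[4],
              mean(sqrt(rowSums(matrix(x$field, ncol = 3)^2)))))
  invisible(x)
}

#' Map fixed-grid points through a registration
#'
#' Points are mapped as `p -> A (p + u(p))` with the displacement `u`
#' trilinearly interpolated at `p`, consistent with the warping convention
#' (warped image at `x` samples the moving image at `A (x + u(x))`).  Points
#' outside the grid are clamped to it and flagged.
#'
#' @param points n x 3 matrix of 0-based fixed-grid voxel coordinates.
#' @param result an [forward_register()] result.
#' @return n x 3 matrix of moving-grid coordinates, with attribute
#'   `clamped` (logical vector marking out-of-grid inputs).
#' @export
transform_points <- function(points, result) {
  stopifnot(inherits(result, "mt_registration"))
  points <- matrix(as.numeric(points), ncol = 3)
  d <- result$dim
  clamped <- rep(FALSE, nrow(points))
  for (k in 1:3) {
    bad <- points[, k] < 0 | points[, k] > d[k] - 1
    clamped <- clamped | bad
    points[, k] <- pmin(pmax(points[, k], 0), d[k] - 1)
  }
  if (any(clamped)) warning(sum(clamped), " point(s) outside the grid were clamped")
  u <- vapply(1:3, function(c) sample3d_fw(result$field[, , , c], points),
              numeric(nrow(points)))
  q <- points + u
  out <- q %*% t(result$affine[, 1:3]) +
    matrix(result$affine[, 4], nrow(q), 3, byrow = TRUE)
  attr(out, "clamped") <- clamped
  out
}
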