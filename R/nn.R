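# Minimal layer primitives with explicit forward caches and hand-derived
# backward passes.  All feature tensors are arrays dim c(nx, ny, nz, C);
# convolutions are 3x3x3 with "same" padding (stride 1 keeps the shape,
# stride 2 halves it), expressed as im2col + BLAS GEMM.

as_4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

conv_fw <- function(x, w, b, stride) {
  x <- as_4d(x)
  y <- conv3d_direct_fw(x, w, b, stride)
  list(y = y, cache = list(x = x, in_dim = dim(x), stride = stride,
                           cout = dim(w)[5]))
}

conv_bw <- function(cache, w, gy, need_gx = TRUE) {
  wb <- conv3d_direct_bww(cache$x, gy, cache$stride, cache$cout)
  gx <- if (need_gx)
    conv3d_direct_bwx(cache$in_dim, w, gy, cache$stride) else NULL
  list(gx = gx, gw = wb$gw, gb = wb$gb)
}

# largest divisor of C not exceeding the requested group count
gn_groups <- function(C, requested = 8L) {
  for (g in seq(min(requested, C), 1L)) if (C %% g == 0L) return(g)
  1L
}

gn_fw <- function(x, gamma, beta, groups, eps = 1e-5, min_group_elems = 8L) {
  d <- dim(x)
  C <- d[4]
  nvox <- prod(d[1:3])
  M <- matrix(x, nvox, C)
  # merge groups until each holds enough elements for a meaningful variance
  # (tiny groups degenerate: a 2-element group always normalizes to +/-1,
  # which quantizes the representation at small spatial sizes)
  while (groups > 1L && nvox * (C %/% groups) < min_group_elems)
    groups <- max(which(C %% seq_len(groups - 1L) == 0L))
  cg <- C %/% groups
  xhat <- M
  invstd <- numeric(groups)
  passthrough <- nvox * cg < 2L   # single-element groups: variance undefined
  for (g in seq_len(groups)) {
    idx <- ((g - 1L) * cg + 1L):(g * cg)
    blk <- M[, idx, drop = FALSE]
    if (passthrough) {
      invstd[g] <- 1
      xhat[, idx] <- blk
      next
    }
    mu <- mean(blk)
    v <- mean((blk - mu)^2)
    invstd[g] <- 1 / sqrt(v + eps)
    xhat[, idx] <- (blk - mu) * invstd[g]
  }
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, groups = groups,
                           dim = d, passthrough = passthrough))
}

gn_bw <- function(cache, gamma, gy) {
  d <- cache$dim
  C <- d[4]
  nvox <- prod(d[1:3])
  gym <- matrix(gy, nvox, C)
  xhat <- cache$xhat
  dgamma <- colSums(gym * xhat)
  dbeta <- colSums(gym)
  dxhat <- sweep(gym, 2, gamma, `*`)
  groups <- cache$groups
  cg <- C %/% groups
  gx <- dxhat
  if (!isTRUE(cache$passthrough)) {
    for (g in seq_len(groups)) {
      idx <- ((g - 1L) * cg + 1L):(g * cg)
      blk <- dxhat[, idx, drop = FALSE]
      xb <- xhat[, idx, drop = FALSE]
      n <- length(blk)
      gx[, idx] <- cache$invstd[g] * (blk - sum(blk) / n - xb * (sum(blk * xb) / n))
    }
  }
  dim(gx) <- d
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}

lrelu_fw <- function(x, slope = 0.1) {
  y <- lrelu_fw_cpp(x, slope)
  list(y = y, cache = y)   # sign of the output recovers the mask
}

lrelu_bw <- function(cache, gy, slope = 0.1) {
  lrelu_bw_cpp(cache, gy, slope)
}

fc_fw <- function(x, W, b) as.vector(W %*% x + b)

# returns list(gx, gW, gb)
fc_bw <- function(x, W, gy) {
  list(gx = as.vector(crossprod(W, gy)), gW = outer(gy, x), gb = gy)
}

# He-style initialisation for conv / fc weights
init_conv_w <- function(cin, cout, seed_rng_active = TRUE) {
  array(rnorm(27 * cin * cout, 0, sqrt(2 / (27 * cin))),
        dim = c(3, 3, 3, cin, cout))
}

init_tconv_w <- function(cin, cout) {
  array(rnorm(8 * cin * cout, 0, sqrt(2 / (8 * cin))),
        dim = c(2, 2, 2, cin, cout))
}

init_fc_w <- function(nin, nout) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

# conv + group-norm + leaky-ReLU block
block_fw <- function(x, W, prefix, stride, groups, slope) {
  cv <- conv_fw(x, W[[paste0(prefix, "_w")]], W[[paste0(prefix, "_b")]], stride)
  C <- dim(cv$y)[4]
  g <- gn_groups(C, groups)
  gn <- gn_fw(cv$y, W[[paste0(prefix, "_g")]], W[[paste0(prefix, "_bb")]], g)
  ac <- lrelu_fw(gn$y, slope)
  list(y = ac$y, cache = list(conv = cv$cache, gn = gn$cache, act = ac$cache))
}

block_bw <- function(cache, W, prefix, gy, slope, need_gx = TRUE) {
  gy <- lrelu_bw(cache$act, gy, slope)
  gnb <- gn_bw(cache$gn, W[[paste0(prefix, "_g")]], gy)
  cvb <- conv_bw(cache$conv, W[[paste0(prefix, "_w")]], gnb$gx, need_gx)
  grads <- list()
  grads[[paste0(prefix, "_w")]] <- cvb$gw
  grads[[paste0(prefix, "_b")]] <- cvb$gb
  grads[[paste0(prefix, "_g")]] <- gnb$dgamma
  grads[[paste0(prefix, "_bb")]] <- gnb$dbeta
  list(gx = cvb$gx, grads = grads)
}

# transposed-conv (x2 upsampling) + group-norm + leaky-ReLU block
upblock_fw <- function(x, W, prefix, groups, slope) {
  y <- tconv3d_fw(x, W[[paste0(prefix, "_w")]], W[[paste0(prefix, "_b")]])
  C <- dim(y)[4]
  g <- gn_groups(C, groups)
  gn <- gn_fw(y, W[[paste0(prefix, "_g")]], W[[paste0(prefix, "_bb")]], g)
  ac <- lrelu_fw(gn$y, slope)
  list(y = ac$y, cache = list(x = x, gn = gn$cache, act = ac$cache))
}

upblock_bw <- function(cache, W, prefix, gy, slope) {
  gy <- lrelu_bw(cache$act, gy, slope)
  gnb <- gn_bw(cache$gn, W[[paste0(prefix, "_g")]], gy)
  tb <- tconv3d_bw(cache$x, W[[paste0(prefix, "_w")]], gnb$gx)
  grads <- list()
  grads[[paste0(prefix, "_w")]] <- tb$gw
  grads[[paste0(prefix, "_b")]] <- tb$gb
  grads[[paste0(prefix, "_g")]] <- gnb$dgamma
  grads[[paste0(prefix, "_bb")]] <- gnb$dbeta
  list(gx = tb$gx, grads = grads)
}
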