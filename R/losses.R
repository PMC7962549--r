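#' Loss configuration
#'
#' The registration objective is the correlation-coefficient loss between
#' the (curriculum-smoothed) fixed and warped moving image, plus three
#' displacement-field penalties that discourage unlikely morphological
#' deformations: spatial smoothness (squared forward-difference gradients),
#' anti-folding (negative-Jacobian-determinant), and displacement magnitude.
#' Each penalty enters the total loss with weight 1/10 by default.
#'
#' @param smoothness,folding,magnitude non-negative penalty weights
#'   (defaults all 0.1).
#' @return list of class `mt_loss_config`.
#' @export
loss_config <- function(smoothness = 0.1, folding = 0.1, magnitude = 0.1) {
  stopifnot(smoothness >= 0, folding >= 0, magnitude >= 0)
  structure(list(smoothness = smoothness, folding = folding,
                 magnitude = magnitude), class = "mt_loss_config")
}

#' Correlation-coefficient loss
#'
#' `1 - Pearson r` of the flattened intensities, in `[0, 2]`: 0 for
#' perfectly (positively) correlated images, 2 for anti-correlated ones.
#' Invariant to positive affine rescaling of either argument.  If either
#' image is constant the correlation is undefined; the loss is then defined
#' as 1 (zero information) and flagged via the `degenerate` attribute.
#'
#' @param a,b [volume()]s or arrays of identical shape.
#' @return scalar loss, with attribute `degenerate`.
#' @export
correlation_loss <- function(a, b) {
  va <- as.vector(vol_values(a))
  vb <- as.vector(vol_values(b))
  if (length(va) != length(vb)) stop("shapes differ")
  l <- correlation_loss_grad(va, vb)
  structure(l$loss, degenerate = l$degenerate)
}

# returns loss plus gradient w.r.t. b
correlation_loss_grad <- function(va, vb) {
  ac <- va - mean(va)
  bc <- vb - mean(vb)
  Saa <- sum(ac * ac)
  Sbb <- sum(bc * bc)
  if (Saa <= 0 || Sbb <= 0)
    return(list(loss = 1, grad_b = numeric(length(vb)) * 0, degenerate = TRUE))
  Sab <- sum(ac * bc)
  denom <- sqrt(Saa * Sbb)
  r <- Sab / denom
  grad <- -(ac / denom - (r / Sbb) * bc)
  list(loss = 1 - r, grad_b = grad, degenerate = FALSE)
}

field_as_array <- function(field) {
  d <- dim(field)
  if (length(d) != 4L || d[4] != 3L) stop("field must have dim c(nx, ny, nz, 3)")
  field
}

#' Smoothness penalty
#'
#' Mean, over voxels and the three spatial axes, of the squared
#' forward-difference gradient magnitude of the displacement field:
#' `mean_{x, d} || u(x + e_d) - u(x) ||^2`.  Zero iff the field is spatially
#' constant (any pure translation).
#'
#' @param field displacement array `c(nx, ny, nz, 3)`.
#' @return scalar penalty.
#' @export
smoothness_penalty <- function(field) smoothness_penalty_grad(field)$value

smoothness_penalty_grad <- function(field) {
  field <- field_as_array(field)
  d <- dim(field)[1:3]
  nsites <- sum(vapply(1:3, function(ax) prod(d) / d[ax] * (d[ax] - 1), 0))
  g <- array(0, dim = dim(field))
  total <- 0
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    idx_hi <- slice_idx(d, ax, 2:n)
    idx_lo <- slice_idx(d, ax, 1:(n - 1))
    for (c in 1:3) {
      uc <- field[, , , c]
      df <- uc[idx_hi] - uc[idx_lo]
      total <- total + sum(df * df)
      gc <- array(0, dim = d)
      gc[idx_hi] <- gc[idx_hi] + 2 * df
      gc[idx_lo] <- gc[idx_lo] - 2 * df
      g[, , , c] <- g[, , , c] + gc
    }
  }
  list(value = total / nsites, grad = g / nsites)
}

# logical index selecting given positions along one axis
slice_idx <- function(d, ax, pos) {
  out <- list(1:d[1], 1:d[2], 1:d[3])
  out[[ax]] <- pos
  array_index <- array(FALSE, dim = d)
  array_index[out[[1]], out[[2]], out[[3]]] <- TRUE
  array_index
}

#' Anti-folding penalty
#'
#' Mean over interior voxels of `max(0, -det J(x))` where
#' `J = I + grad u` by forward differences: positive wherever the local
#' transform folds space (negative Jacobian determinant), zero for any
#' orientation-preserving field.
#'
#' @param field displacement array `c(nx, ny, nz, 3)`.
#' @return scalar penalty.
#' @export
folding_penalty <- function(field) folding_penalty_grad(field)$value

folding_penalty_grad <- function(field) {
  field <- field_as_array(field)
  d <- dim(field)[1:3]
  m <- d - 1L
  if (any(m < 1)) return(list(value = 0, grad = array(0, dim = dim(field))))
  J <- vector("list", 9)   # J[[3*(dd-1)+cc]] = dd-th partial of component cc
  lo <- lapply(1:3, function(k) 1:m[k])
  for (cc in 1:3) {
    uc <- field[, , , cc]
    base <- uc[lo[[1]], lo[[2]], lo[[3]]]
    for (dd in 1:3) {
      hi <- lo
      hi[[dd]] <- hi[[dd]] + 1L
      df <- uc[hi[[1]], hi[[2]], hi[[3]]] - base
      J[[3 * (dd - 1) + cc]] <- df + (cc == dd)
    }
  }
  Jm <- function(cc, dd) J[[3 * (dd - 1) + cc]]
  det <- Jm(1, 1) * (Jm(2, 2) * Jm(3, 3) - Jm(2, 3) * Jm(3, 2)) -
         Jm(1, 2) * (Jm(2, 1) * Jm(3, 3) - Jm(2, 3) * Jm(3, 1)) +
         Jm(1, 3) * (Jm(2, 1) * Jm(3, 2) - Jm(2, 2) * Jm(3, 1))
  nvox <- prod(m)
  mask <- det < 0
  value <- sum(pmax(0, -det)) / nvox
  grad <- array(0, dim = dim(field))
  if (any(mask)) {
    # d det / d J_{cc,dd} = cofactor C_{cc,dd}
    cof <- function(cc, dd) {
      r <- setdiff(1:3, cc); s <- setdiff(1:3, dd)
      sign <- (-1)^(cc + dd)
      sign * (Jm(r[1], s[1]) * Jm(r[2], s[2]) - Jm(r[1], s[2]) * Jm(r[2], s[1]))
    }
    for (cc in 1:3) {
      gc <- array(0, dim = d)
      for (dd in 1:3) {
        # dL/dJ_{cc,dd} = -C_{cc,dd}/nvox on folded voxels (relu of -det)
        gJ <- -cof(cc, dd) * as.numeric(mask) / nvox
        hi <- lo
        hi[[dd]] <- hi[[dd]] + 1L
        gc[hi[[1]], hi[[2]], hi[[3]]] <- gc[hi[[1]], hi[[2]], hi[[3]]] + gJ
        gc[lo[[1]], lo[[2]], lo[[3]]] <- gc[lo[[1]], lo[[2]], lo[[3]]] - gJ
      }
      grad[, , , cc] <- gc
    }
  }
  list(value = value, grad = grad)
}

#' Magnitude penalty
#'
#' Mean squared displacement norm, `mean_x || u(x) ||^2`, in voxel units.
#'
#' @param field displacement array `c(nx, ny, nz, 3)`.
#' @return scalar penalty.
#' @export
magnitude_penalty <- function(field) {
  field <- field_as_array(field)
  sum(field^2) / prod(dim(field)[1:3])
}

magnitude_penalty_grad <- function(field) {
  nvox <- prod(dim(field)[1:3])
  list(value = sum(field^2) / nvox, grad = 2 * field / nvox)
}

#' Total registration loss
#'
#' `correlation_loss(fixed, warped) + w_s * smoothness + w_f * folding +
#' w_m * magnitude`, each term also reported separately via the `terms`
#' attribute.
#'
#' @param fixed,warped images of identical shape.
#' @param field displacement array `c(dim, 3)`.
#' @param config a [loss_config()].
#' @return scalar loss with attribute `terms`.
#' @export
total_loss <- function(fixed, warped, field, config = loss_config()) {
  lc <- as.numeric(correlation_loss(fixed, warped))
  ls <- smoothness_penalty(field)
  lf <- folding_penalty(field)
  lm <- magnitude_penalty(field)
  tot <- lc + config$smoothness * ls + config$folding * lf + config$magnitude * lm
  structure(tot, terms = c(correlation = lc, smoothness = ls,
                           folding = lf, magnitude = lm))
}
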