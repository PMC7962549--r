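#' Curriculum smoothing schedule
#'
#' Coarse-to-fine curriculum: the loss is computed on smoothed copies of the
#' images, with the average-pooling kernel starting at 9 and reduced by 3 at
#' epochs 100, 150 and 175 (after which no smoothing is applied).
#'
#' @param milestones epochs at which the kernel shrinks.
#' @param kernels kernel size active before each milestone; after the last
#'   milestone no smoothing is applied.
#' @return list of class `mt_curriculum`.
#' @export
curriculum_schedule <- function(milestones = c(100L, 150L, 175L),
                                kernels = c(9L, 6L, 3L)) {
  stopifnot(length(kernels) == length(milestones),
            all(kernels > 0), !is.unsorted(milestones, strictly = TRUE),
            all(diff(kernels) <= 0))
  structure(list(milestones = as.integer(milestones),
                 kernels = as.integer(kernels)),
            class = "mt_curriculum")
}

#' Scale a curriculum schedule for shorter runs
#'
#' Divides the milestones by `factor` (rounding down, keeping them strictly
#' increasing), so short training runs traverse the same coarse-to-fine
#' progression.
#'
#' @param schedule a [curriculum_schedule()].
#' @param factor positive divisor.
#' @return scaled [curriculum_schedule()].
#' @export
scale_schedule <- function(schedule, factor) {
  m <- pmax(1L, as.integer(floor(schedule$milestones / factor)))
  for (i in seq_along(m)[-1]) if (m[i] <= m[i - 1]) m[i] <- m[i - 1] + 1L
  curriculum_schedule(m, schedule$kernels)
}

# active kernel size at a (0-based) epoch; 0 = no smoothing
kernel_at_epoch <- function(epoch, schedule) {
  idx <- which(epoch < schedule$milestones)
  if (length(idx) == 0) 0L else schedule$kernels[idx[1]]
}

#' Curriculum smoothing of an image
#'
#' Average pooling with the epoch's kernel size, stride 1 and symmetric
#' boundary padding (a pure blur: resolution is unchanged, and for odd
#' kernels the global mean is preserved exactly).
#'
#' @param vol a [volume()] or 3D array.
#' @param epoch 0-based training epoch.
#' @param schedule a [curriculum_schedule()].
#' @return smoothed image, same type as input.
#' @export
curriculum_smooth <- function(vol, epoch, schedule = curriculum_schedule()) {
  k <- kernel_at_epoch(epoch, schedule)
  box_smooth(vol, k)
}

box_smooth <- function(vol, k) {
  if (k <= 1L) return(vol)
  v <- vol_values(vol)
  for (axis in 0:2) v <- boxblur3d_axis(v, k, axis, FALSE)
  if (is_volume(vol)) volume(v, vol$spacing, vol$origin) else v
}

# adjoint of box_smooth, for backprop through the smoothed loss
box_smooth_adjoint <- function(g, k) {
  if (k <= 1L) return(g)
  for (axis in 2:0) g <- boxblur3d_axis(g, k, axis, TRUE)
  g
}

#' Training-holdout split by patient identifier
#'
#' Patients whose ID is a multiple of 10 are held out (10% of a corpus with
#' ids 1..N when N is a multiple of 10).
#'
#' @param patient_ids integer vector.
#' @return list with `train_ids` and `holdout_ids`.
#' @export
split_by_id <- function(patient_ids) {
  patient_ids <- as.integer(patient_ids)
  hold <- patient_ids[patient_ids %% 10L == 0L]
  list(train_ids = patient_ids[patient_ids %% 10L != 0L], holdout_ids = hold)
}

#' Training configuration
#'
#' @param lr initial Adam learning rate (default 8e-5, matched to the
#'   full-scale 200-epoch protocol; short small-volume runs typically use a
#'   larger rate, see [train_registration()]).
#' @param batch_size minibatch size (default 2).
#' @param epochs number of epochs (default 200, past the last curriculum
#'   milestone at 175).
#' @param seed integer seed controlling initialisation and batch order.
#' @param affine_warmup_epochs initial epochs in which only the affine
#'   stage is trained (the dense field is held at zero). Without a warm-up
#'   the flexible dense stage absorbs rigid misalignment into the
#'   displacement field and the affine head settles into a constant — a
#'   joint-training local minimum; a short affine-only phase gives global
#'   alignment a head start. Default 10% of the epochs.
#' @return list of class `mt_train_config`.
#' @export
train_config <- function(lr = 8e-5, batch_size = 2L, epochs = 200L, seed = 1L,
                         affine_warmup_epochs = min(epochs - 1L,
                                                    max(1L, epochs %/% 10L))) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1, affine_warmup_epochs >= 0,
            affine_warmup_epochs < epochs)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 affine_warmup_epochs = as.integer(affine_warmup_epochs)),
            class = "mt_train_config")
}

adam_init <- function(W) {
  list(m = lapply(W, function(p) p * 0), v = lapply(W, function(p) p * 0),
       t = 0L)
}

adam_step <- function(W, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(W)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    W[[nm]] <- W[[nm]] - lr * (state$m[[nm]] / b1t) /
      (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(W = W, state = state)
}

# affine-only warm-up step: the dense field is held at zero, so the loss is
# the correlation of the smoothed fixed and affine-warped moving images and
# only the affine-stage parameters receive gradients
affine_pair_step <- function(W, cfg, fixed, moving, k_smooth) {
  f <- vol_values(fixed)
  m <- vol_values(moving)
  d <- dim(f)
  x_aff <- abind4(array(f, c(d, 1L)), array(m, c(d, 1L)))
  af <- affine_forward(W, x_aff, cfg, with_cache = TRUE)
  P <- grid_coords(d)
  coords_aff <- P %*% t(af$A[, 1:3]) + matrix(af$A[, 4], nrow(P), 3,
                                              byrow = TRUE)
  m_aff <- array(sample3d_fw(m, coords_aff), dim = d)
  sm_f <- box_smooth(f, k_smooth)
  sm_w <- box_smooth(m_aff, k_smooth)
  cl <- correlation_loss_grad(as.vector(sm_f), as.vector(sm_w))
  g_warped <- box_smooth_adjoint(array(cl$grad_b, dim = d), k_smooth)
  aw <- sample3d_bw(m, coords_aff, as.vector(g_warped))
  gA <- t(aw$gcoords) %*% cbind(P, 1)
  grads <- affine_backward(W, af$cache, gA, cfg)
  list(loss = cl$loss,
       terms = c(correlation = cl$loss, smoothness = 0, folding = 0,
                 magnitude = 0),
       grads = grads)
}

# forward + loss + full backward for one pair; returns loss terms and grads
train_pair_step <- function(W, cfg, fixed, moving, k_smooth, loss_cfg) {
  res <- forward_register(fixed, moving, W, with_cache = TRUE)
  sm_f <- box_smooth(res$cache$fixed, k_smooth)
  sm_w <- box_smooth(res$warped_moving, k_smooth)
  cl <- correlation_loss_grad(as.vector(sm_f), as.vector(sm_w))
  pen <- field_penalties(res$field, loss_cfg$smoothness, loss_cfg$folding,
                         loss_cfg$magnitude)
  terms <- c(correlation = cl$loss, smoothness = pen$smoothness,
             folding = pen$folding, magnitude = pen$magnitude)
  loss <- cl$loss + loss_cfg$smoothness * pen$smoothness +
    loss_cfg$folding * pen$folding + loss_cfg$magnitude * pen$magnitude

  d <- res$dim
  g_sm_w <- array(cl$grad_b, dim = d)
  g_warped <- box_smooth_adjoint(g_sm_w, k_smooth)
  # through the dense warp
  dw <- sample3d_bw(res$cache$m_aff, res$cache$coords_dense,
                    as.vector(g_warped))
  g_field <- array(dw$gcoords, dim = c(d, 3)) + pen$grad
  # through the deformable network (input ch 2 is the affine-warped moving)
  db <- deform_backward(W, res$cache$deform, g_field, cfg, need_gx = TRUE)
  g_maff <- dw$gimg + array(db$gx[, , , 2L], dim = d)
  # through the affine warp to the affine parameters
  aw <- sample3d_bw(res$cache$moving, res$cache$coords_aff, as.vector(g_maff))
  gA <- t(aw$gcoords) %*% cbind(res$cache$P, 1)
  ab <- affine_backward(W, res$cache$affine, gA, cfg)
  grads <- c(db$grads, ab)
  list(loss = loss, terms = terms, grads = grads)
}

#' Train the registration network
#'
#' Unsupervised training: for each pair the network is run forward, the
#' correlation loss is computed between curriculum-smoothed fixed and
#' curriculum-smoothed warped moving images, the three field penalties are
#' added, and all weights (affine and deformable stages jointly) are updated
#' with Adam.  Deterministic given the seed.
#'
#' @param pairs list of pairs; each element a list with `fixed` and `moving`
#'   ([volume()]s or arrays of identical shape, divisible by 16).
#' @param net_config a [regnet_config()].
#' @param config a [train_config()].
#' @param loss a [loss_config()].
#' @param schedule a [curriculum_schedule()].
#' @param verbose print per-epoch loss summaries.
#' @return trained weights (`mt_regnet_weights`) with attribute `log`, a
#'   data.frame of per-epoch mean loss terms.
#' @export
train_registration <- function(pairs, net_config = regnet_config(),
                               config = train_config(),
                               loss = loss_config(),
                               schedule = curriculum_schedule(),
                               verbose = FALSE) {
  stopifnot(length(pairs) >= 1)
  W <- regnet_init(net_config, seed = config$seed)
  cfg <- attr(W, "config")
  state <- adam_init(W)
  log <- vector("list", config$epochs)
  with_seed(mix_seed(config$seed, 97), {
    for (epoch in seq_len(config$epochs) - 1L) {
      k <- kernel_at_epoch(epoch, schedule)
      ord <- sample(length(pairs))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_terms <- NULL
      for (bt in batches) {
        acc <- NULL
        tacc <- NULL
        for (j in bt) {
          st <- if (epoch < config$affine_warmup_epochs)
            affine_pair_step(W, cfg, pairs[[j]]$fixed, pairs[[j]]$moving, k)
          else
            train_pair_step(W, cfg, pairs[[j]]$fixed, pairs[[j]]$moving,
                            k, loss)
          if (!is.finite(st$loss)) {
            bad <- names(st$terms)[!is.finite(st$terms)]
            stop("non-finite loss at epoch ", epoch, " (offending term: ",
                 paste(if (length(bad)) bad else "total", collapse = ", "), ")")
          }
          if (is.null(acc)) {
            acc <- st$grads
            tacc <- st$terms
          } else {
            for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + st$grads[[nm]]
            tacc <- tacc + st$terms
          }
        }
        nb <- length(bt)
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nb
        upd <- adam_step(W, acc, state, config$lr)
        # adam_step strips attributes via [[<-; restore class/config
        attrs <- attributes(W)
        W <- upd$W
        attributes(W) <- attrs
        state <- upd$state
        epoch_terms <- rbind(epoch_terms, tacc / nb)
      }
      mean_terms <- colMeans(epoch_terms)
      log[[epoch + 1L]] <- data.frame(epoch = epoch, kernel = k,
                                      t(mean_terms),
                                      total = mean_terms["correlation"] +
                                        loss$smoothness * mean_terms["smoothness"] +
                                        loss$folding * mean_terms["folding"] +
                                        loss$magnitude * mean_terms["magnitude"])
      if (verbose)
        message(sprintf("epoch %3d  k=%d  corr %.4f  total %.4f", epoch, k,
                        mean_terms["correlation"], log[[epoch + 1L]]$total))
    }
  })
  attr(W, "log") <- do.call(rbind, log)
  W
}
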