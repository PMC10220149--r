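#' Training configuration
#'
#' Defaults follow the reference schedule: Adam with initial learning rate
#' 1e-4 decayed by sqrt(2) every 14 epochs, batch size 16, 200 epochs;
#' checkpoints are ranked by validation relative speed error.
#'
#' @param initial_lr Initial learning rate.
#' @param decay_factor Learning-rate divisor applied every
#'   `decay_interval` epochs.
#' @param decay_interval Epochs between decays.
#' @param batch_size Patches per optimisation step.
#' @param epochs Training epochs.
#' @param seed RNG seed for shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-4, decay_factor = sqrt(2),
                         decay_interval = 14, batch_size = 16, epochs = 200,
                         seed = 1) {
  stopifnot(initial_lr > 0, decay_factor > 0, decay_interval >= 1,
            batch_size >= 1, epochs >= 1)
  structure(list(initial_lr = initial_lr, decay_factor = decay_factor,
                 decay_interval = decay_interval,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint_metric = "relative_speed_error"),
            class = "train_config")
}

#' Stepped learning-rate schedule
#'
#' `initial_lr / decay_factor^floor(epoch / decay_interval)`:
#' non-increasing and piecewise constant, halving every two decay
#' intervals at the default sqrt(2) factor.
#'
#' @param epoch 0-based epoch index.
#' @param cfg A [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  stopifnot(all(epoch >= 0))
  cfg$initial_lr / cfg$decay_factor^(floor(epoch / cfg$decay_interval))
}

#' Fluid/non-fluid split mean-squared-error loss
#'
#' The voxel-wise loss is the sum over the three velocity components of the
#' squared prediction error; it is averaged separately over the fluid and
#' the non-fluid region (equalising the influence of the two imbalanced
#' regions) and the two means are added. A region with no voxels
#' contributes 0.
#'
#' @param pred,target Velocity arrays `[x, y, z, 3]` of equal shape.
#' @param mask Logical fluid mask `[x, y, z]`.
#' @return List with `fluid_mse`, `nonfluid_mse` and `total` (their sum).
#' @export
mse_loss <- function(pred, target, mask) {
  if (!identical(dim(pred), dim(target)))
    stop("pred/target shape mismatch")
  if (!identical(dim(mask), dim(pred)[1:3]))
    stop("mask shape mismatch")
  d2 <- (pred - target)^2
  sq <- d2[, , , 1] + d2[, , , 2] + d2[, , , 3]
  nf <- sum(mask); nn <- sum(!mask)
  fluid <- if (nf > 0) sum(sq[mask]) / nf else 0
  nonfluid <- if (nn > 0) sum(sq[!mask]) / nn else 0
  list(fluid_mse = fluid, nonfluid_mse = nonfluid, total = fluid + nonfluid)
}

# Pack a list of patch pairs into batched tensors; velocities are
# VENC-normalised, magnitudes scaled by the maximum intensity level.
pack_pairs <- function(pairs) {
  if (length(pairs) == 0) stop("empty patch set")
  n <- dim(pairs[[1]]$lr)[1]
  nh <- dim(pairs[[1]]$hr)[1]
  N <- length(pairs)
  vel <- array(0, c(n, n, n, 3, N))
  mag <- array(0, c(n, n, n, 3, N))
  hr <- array(0, c(nh, nh, nh, 3, N))
  mask <- array(FALSE, c(nh, nh, nh, N))
  venc <- matrix(0, 3, N)
  for (i in seq_len(N)) {
    p <- pairs[[i]]
    venc[, i] <- p$venc
    for (j in 1:3) {
      vel[, , , j, i] <- p$lr[, , , j] / p$venc[j]
      hr[, , , j, i] <- p$hr[, , , j] / p$venc[j]
    }
    mag[, , , , i] <- p$lr[, , , 4:6] / MAG_SCALE
    mask[, , , i] <- p$hr_mask
  }
  list(vel = vel, mag = mag, hr = hr, mask = mask, venc = venc, n = N)
}

# Split-region loss and its gradient on a normalised batch.
batch_loss_grad <- function(pred, target, mask, grad = TRUE) {
  d <- dim(pred)
  N <- d[5]; V <- prod(d[1:3])
  diff <- pred - target
  sq <- diff[, , , 1, , drop = FALSE]^2 + diff[, , , 2, , drop = FALSE]^2 +
        diff[, , , 3, , drop = FALSE]^2
  dim(sq) <- c(d[1:3], N)
  nf <- apply(mask, 4, sum)
  nn <- V - nf
  wf <- rep(ifelse(nf > 0, 1 / nf, 0), each = V)
  wn <- rep(ifelse(nn > 0, 1 / nn, 0), each = V)
  w <- mask * wf + (!mask) * wn
  dim(w) <- c(d[1:3], N)
  loss <- sum(sq * w) / N
  if (!grad) return(list(loss = loss))
  w5 <- array(0, d)
  for (j in 1:3) w5[, , , j, ] <- w
  list(loss = loss, dpred = 2 * diff * w5 / N)
}

# Mean per-patch relative speed error of a batch, in m/s space.
batch_re <- function(pred_n, target_n, mask, venc, epsilon = 1e-4) {
  d <- dim(pred_n)
  N <- d[5]
  res <- numeric(0)
  for (i in seq_len(N)) {
    m <- mask[, , , i]
    if (!any(m)) next
    p <- pred_n[, , , , i]
    t <- target_n[, , , , i]
    for (j in 1:3) {
      p[, , , j] <- p[, , , j] * venc[j, i]
      t[, , , j] <- t[, , , j] * venc[j, i]
    }
    res <- c(res, relative_speed_error(p, t, m, epsilon))
  }
  mean(res)
}

adam_init <- function(params) {
  lapply(params, function(p)
    list(mw = p$w * 0, vw = p$w * 0, mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]; p <- params[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    p$w <- p$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + eps)
    p$b <- p$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
    params[[nm]] <- p
  }
  list(params = params, state = state)
}

#' Train a super-resolution network
#'
#' Adam optimisation of the fluid/non-fluid split MSE loss
#' ([mse_loss()], computed on VENC-normalised velocities) with the stepped
#' learning-rate schedule of [lr_schedule()]. Validation relative speed
#' error (in m/s space, averaged per patch) is computed before training
#' (epoch 0) and after every epoch; the checkpoint with the lowest
#' validation error is returned. Fully deterministic given `cfg$seed`.
#'
#' @param model An `sr_network` from [build_network()].
#' @param train_pairs,val_pairs Non-empty lists of `patch_pair`s.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best checkpoint), `last_model`, `history`
#'   (data frame: epoch, lr, train_loss, val_re) and `best_epoch`.
#' @export
train_network <- function(model, train_pairs, val_pairs,
                          cfg = train_config(), verbose = FALSE) {
  if (length(train_pairs) == 0 || length(val_pairs) == 0)
    stop("training and validation patch sets must be non-empty")
  tr <- pack_pairs(train_pairs)
  va <- pack_pairs(val_pairs)
  set.seed(cfg$seed)
  state <- adam_init(model$params)
  val_model_re <- function() {
    out <- nn_forward(model, va$vel, va$mag, keep = FALSE)$out
    batch_re(out, va$hr, va$mask, va$venc)
  }
  history <- data.frame(epoch = 0, lr = NA_real_, train_loss = NA_real_,
                        val_re = val_model_re())
  best <- list(re = history$val_re[1], params = model$params, epoch = 0L)
  step <- 0
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch - 1, cfg)
    idx <- sample.int(tr$n)
    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, tr$n, by = cfg$batch_size)) {
      sel <- idx[b0:min(b0 + cfg$batch_size - 1, tr$n)]
      fw <- nn_forward(model,
                       tr$vel[, , , , sel, drop = FALSE],
                       tr$mag[, , , , sel, drop = FALSE], keep = TRUE)
      lg <- batch_loss_grad(fw$out, tr$hr[, , , , sel, drop = FALSE],
                            tr$mask[, , , sel, drop = FALSE])
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      grads <- nn_backward(model, fw$tape, lg$dpred)
      step <- step + 1
      up <- adam_step(model$params, grads, state, lr, step)
      model$params <- up$params
      state <- up$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    vre <- val_model_re()
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                train_loss = ep_loss / nb, val_re = vre))
    if (vre < best$re)
      best <- list(re = vre, params = model$params, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.5f  val RE %.4f",
                      epoch, lr, ep_loss / nb, vre))
  }
  last_model <- model
  model$params <- best$params
  list(model = model, last_model = last_model, history = history,
       best_epoch = best$epoch)
}
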