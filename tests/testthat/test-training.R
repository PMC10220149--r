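test_that("split-region loss matches hand-computed examples", {
  fx <- get_fixtures()
  lp <- fx$loss_patch
  # one fluid voxel off by (0.1,0,0), one non-fluid voxel off by (0,0.2,0)
  l <- mse_loss(lp$pred, lp$target, lp$mask)
  expect_equal(l$fluid_mse, 0.01)
  expect_equal(l$nonfluid_mse, 0.04)
  expect_equal(l$total, 0.05)
  # identical prediction: zero everywhere
  l0 <- mse_loss(lp$target, lp$target, lp$mask)
  expect_equal(l0$total, 0)
  # an all-fluid mask leaves the non-fluid term at its empty-region value
  la <- mse_loss(lp$pred, lp$target, array(TRUE, c(2, 1, 1)))
  expect_equal(la$nonfluid_mse, 0)
  expect_equal(la$total, la$fluid_mse)
  expect_error(mse_loss(lp$pred, array(0, c(3, 1, 1, 3)), lp$mask),
               "mismatch")
})

test_that("loss is voxel-permutation invariant within regions and additive", {
  p <- random_patch(4, seed = 5)
  t <- random_patch(4, seed = 6)
  set.seed(7)
  mask <- array(runif(64) > 0.4, c(4, 4, 4))
  l <- mse_loss(p, t, mask)
  expect_equal(l$total, l$fluid_mse + l$nonfluid_mse)
  # permute fluid voxels among themselves (same for every component)
  perm <- seq_len(64)
  fl <- which(as.vector(mask))
  perm[fl] <- sample(fl)
  p2 <- p; t2 <- t
  for (j in 1:3) {
    pj <- as.vector(p[, , , j]); tj <- as.vector(t[, , , j])
    p2[, , , j] <- array(pj[perm], c(4, 4, 4))
    t2[, , , j] <- array(tj[perm], c(4, 4, 4))
  }
  l2 <- mse_loss(p2, t2, mask)
  expect_equal(l2$total, l$total)
})

test_that("learning-rate schedule steps down by sqrt(2) every 14 epochs", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(14, cfg), 1e-4 / sqrt(2))
  expect_equal(lr_schedule(28, cfg), 5e-5)
  lrs <- lr_schedule(0:60, cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(length(unique(lrs[1:14])), 1)   # piecewise constant
})

test_that("analytic gradients agree with central differences", {
  set.seed(3)
  spec <- network_spec("res", lr_blocks = 2, hr_blocks = 1, channels = 4,
                       in_patch = 4)
  m <- build_network(spec, seed = 9)
  vel <- array(rnorm(4^3 * 3), c(4, 4, 4, 3, 1))
  mag <- array(abs(rnorm(4^3 * 3)), c(4, 4, 4, 3, 1))
  tgt <- array(rnorm(16^3 * 3), c(16, 16, 16, 3, 1))
  mask <- array(runif(16^3) > 0.5, c(16, 16, 16, 1))
  lossfn <- function() {
    fw <- network_forward(m, vel, mag, keep = TRUE)
    list(fw = fw, lg = sr4dflow:::batch_loss_grad(fw$out, tgt, mask))
  }
  r <- lossfn()
  grads <- sr4dflow:::nn_backward(m, r$fw$tape, r$lg$dpred)
  set.seed(11)
  for (trial in 1:8) {
    nm <- sample(names(grads), 1)
    i <- sample(length(m$params[[nm]]$w), 1)
    eps <- 1e-6
    m$params[[nm]]$w[i] <- m$params[[nm]]$w[i] + eps
    lp <- lossfn()$lg$loss
    m$params[[nm]]$w[i] <- m$params[[nm]]$w[i] - 2 * eps
    lm_ <- lossfn()$lg$loss
    m$params[[nm]]$w[i] <- m$params[[nm]]$w[i] + eps
    num <- (lp - lm_) / (2 * eps)
    ana <- grads[[nm]]$w[i]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-12), 1e-4)
  }
})

test_that("training plumbing: history, checkpointing and degenerate input", {
  s <- get_lr_frame()
  set.seed(21)
  pairs <- sample_patches(s$lr, s$hr, s$flow$mask, patch_lr = 4,
                          n_base = 6)
  spec <- network_spec("res", channels = 4, in_patch = 4)
  model <- build_network(spec, seed = 2)
  cfg <- train_config(initial_lr = 1e-3, epochs = 2, batch_size = 4,
                      seed = 2)
  fit <- train_network(model, pairs[1:8], pairs[9:12], cfg)
  expect_equal(fit$history$epoch, 0:2)
  expect_true(all(is.finite(fit$history$val_re)))
  expect_true(all(is.finite(fit$history$train_loss[-1])))
  expect_true(fit$best_epoch %in% 0:2)
  expect_s3_class(fit$model, "sr_network")
  # the loss of an identical prediction/target batch is zero
  pk <- sr4dflow:::pack_pairs(pairs[1:4])
  lg <- sr4dflow:::batch_loss_grad(pk$hr, pk$hr, pk$mask)
  expect_equal(lg$loss, 0)
  expect_error(train_network(model, list(), pairs[1:2], cfg), "non-empty")
})
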