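test_that("VENC phase encoding wraps and round-trips correctly", {
  expect_equal(velocity_to_phase(0, 2.4), 0)
  v <- seq(-1.9, 1.9, by = 0.1)
  expect_equal(decode_velocity(velocity_to_phase(v, 2), 2), v)
  # beyond-VENC velocity wraps to the opposite sign
  expect_equal(decode_velocity(velocity_to_phase(1.5 * 2, 2), 2), -0.5 * 2)
  expect_equal(decode_velocity(pi / 2, 2), 1)
  expect_equal(velocity_to_phase(2, 2), pi)       # boundary maps to +pi
  expect_error(velocity_to_phase(1, 0), "positive")
  # decoded magnitudes never exceed the VENC
  big <- runif(100, -20, 20)
  expect_true(all(abs(decode_velocity(velocity_to_phase(big, 0.9), 0.9))
                  <= 0.9 + 1e-12))
})

test_that("k-space truncation preserves uniform fields and the shape rule", {
  d <- c(16, 8, 8)
  vel <- array(0, c(d, 3)); vel[, , , 1] <- 0.8
  mask <- array(TRUE, d)
  acq <- acquisition(c(1.2, 1.2, 1.2), snr_db = 15, intensity = 100)
  lr <- simulate_lr(vel, mask, acq, factor = 4, noise = FALSE)
  expect_equal(dim(lr$velocity_lr), c(4, 2, 2, 3))
  expect_equal(as.vector(lr$velocity_lr[, , , 1]), rep(0.8, 16),
               tolerance = 1e-10)
  expect_equal(max(abs(lr$velocity_lr[, , , 2:3])), 0, tolerance = 1e-10)
  expect_equal(as.vector(lr$magnitude_lr), rep(100, 48), tolerance = 1e-8)
  # block-centre alignment: a low-frequency harmonic at small phase
  # amplitude (where the complex encoding is effectively linear) survives
  # truncation and must be resampled at HR block centres
  # (positions m * factor + (factor - 1) / 2)
  nharm <- 32
  xs <- seq_len(nharm) - 1
  velh <- array(0, c(nharm, 8, 8, 3))
  velh[, , , 1] <- 0.02 * sin(2 * pi * xs / nharm)
  lrh <- simulate_lr(velh, array(TRUE, c(nharm, 8, 8)),
                     acquisition(c(2, 2, 2), 15, 100), 4, noise = FALSE)
  centres <- (seq_len(nharm / 4) - 1) * 4 + 1.5
  expect_equal(lrh$velocity_lr[, 1, 1, 1],
               0.02 * sin(2 * pi * centres / nharm), tolerance = 1e-4)
  # non-divisible axes are padded: LR length = ceiling(HR / factor)
  d2 <- c(10, 8, 8)
  vel2 <- array(0, c(d2, 3))
  lr2 <- simulate_lr(vel2, array(TRUE, d2), acq, factor = 4, noise = FALSE)
  expect_equal(dim(lr2$velocity_lr)[1:3], ceiling(d2 / 4))
  expect_error(simulate_lr(vel, mask, acq, factor = 0), "positive integer")
})

test_that("complex-noise level matches the configured SNR", {
  d <- c(192, 64, 64)
  vel <- array(0, c(d, 3))
  mask <- array(TRUE, d)
  set.seed(99)
  phs <- c()
  for (rep in 1:3) {
    acq <- acquisition(c(3, 3, 3), snr_db = 17, intensity = 200)
    lr <- simulate_lr(vel, mask, acq, factor = 4)
    # at zero velocity the decoded phase is pure noise: sd(phase) ~ sigma/A
    phs <- c(phs, as.vector(lr$velocity_lr) * pi / 3)
  }
  expect_gte(length(phs), 1e5)
  snr_est <- 20 * log10(1 / sd(phs))
  expect_lt(abs(snr_est - 17), 0.5)
})

test_that("acquisition sampling follows the VENC grid and aliasing policy", {
  grid <- venc_grid()
  expect_equal(grid, seq(0.3, 6, by = 0.3))
  set.seed(5)
  for (i in 1:50) {
    a <- sample_acquisition(c(2.0, 0.25, 4.9))
    expect_true(all(sapply(a$venc, function(v) any(abs(v - grid) < 1e-9))))
    expect_true(a$snr_db >= 14 && a$snr_db <= 17)
    expect_true(a$intensity >= 60 && a$intensity <= 240)
  }
  # the aliasing branch picks a grid VENC 0.3-0.6 below the peak speed
  set.seed(8)
  al <- replicate(200, sample_acquisition(c(2.0, 2.0, 2.0),
                                          alias_prob = 1)$venc[1])
  expect_true(all(al %in% c(1.5, 1.8)))
  # a zero component receives the minimum VENC
  set.seed(9)
  expect_equal(sample_acquisition(c(0, 1, 1), alias_prob = 0)$venc[1], 0.3)
  expect_error(sample_acquisition(c(-1, 1, 1)), "non-negative")
  expect_error(sample_acquisition(c(1, 1, 1), alias_prob = 2), "alias_prob")
})

test_that("empirical aliasing rate matches the 10 % policy", {
  set.seed(123)
  n <- 1e4
  hit <- logical(n)
  for (i in seq_len(n)) hit[i] <- sample_acquisition(c(2, 2, 2))$venc[1] < 2
  expect_lt(abs(mean(hit) - 0.10), 0.01)
})

test_that("aliased flag equals the direct peak-speed scan", {
  fx <- get_fixtures()
  w <- fx$wrap
  set.seed(2)
  lr <- simulate_lr(w$velocity, w$mask, w$acq, factor = 4)
  truth <- vapply(1:3, function(j)
    w$acq$venc[j] < max(abs(w$velocity[, , , j])), logical(1))
  expect_equal(lr$aliased, truth)
  expect_true(lr$aliased[1])    # peak 2.0 m/s against VENC 1.5
  # raising the VENC above the peak clears the flag
  acq2 <- acquisition(c(2.1, 0.3, 0.3), 15, 120)
  expect_false(simulate_lr(w$velocity, w$mask, acq2, 4)$aliased[1])
})
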