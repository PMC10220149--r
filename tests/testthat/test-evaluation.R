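test_that("relative speed error: worked value, bounds and invariance", {
  m1 <- array(TRUE, c(1, 1, 1))
  v <- array(0, c(1, 1, 1, 3)); v[1, 1, 1, 1] <- 1
  expect_equal(relative_speed_error(v, v, m1), 0)
  # unit error orthogonal to a unit velocity: atan(1 / (1 + 1e-4))
  p <- v; p[1, 1, 1, 2] <- 1
  expect_equal(relative_speed_error(p, v, m1), atan(1 / (1 + 1e-4)),
               tolerance = 1e-9)
  expect_equal(round(relative_speed_error(p, v, m1), 5), 0.78535)
  # zero reference velocity with a huge error stays below pi/2
  z <- array(0, c(1, 1, 1, 3))
  big <- z; big[1, 1, 1, 1] <- 1e6
  expect_lt(relative_speed_error(big, z, m1), pi / 2)
  expect_error(relative_speed_error(v, v, array(FALSE, c(1, 1, 1))),
               "empty")
  # norm-based: invariant under a simultaneous cube rotation
  pr <- random_patch(4, 1); tr <- random_patch(4, 2)
  set.seed(3)
  mask <- array(runif(64) > 0.3, c(4, 4, 4))
  R <- cube_rotations()[[17]]
  rot <- function(a) sr4dflow:::rotate_vector_field(a, R)
  mrot <- array(sr4dflow:::rotate_spatial(array(mask, c(4, 4, 4, 1)), R),
                c(4, 4, 4))
  expect_equal(relative_speed_error(rot(pr), rot(tr), mrot),
               relative_speed_error(pr, tr, mask))
})

test_that("component RMSE matches closed forms and a brute-force oracle", {
  m <- array(TRUE, c(3, 3, 3))
  t <- random_patch(3, 4)
  expect_equal(unname(rmse_components(t, t, m)), c(0, 0, 0))
  p <- t; p[, , , 1] <- p[, , , 1] + 0.05
  expect_equal(unname(rmse_components(p, t, m)), c(0.05, 0, 0))
  # oracle: explicit loop over fluid voxels
  for (seed in 1:3) {
    p <- random_patch(5, seed); t2 <- random_patch(5, seed + 10)
    set.seed(seed)
    mk <- array(runif(125) > 0.4, c(5, 5, 5))
    oracle <- sapply(1:3, function(j) {
      acc <- c()
      for (i in which(mk)) {
        d <- as.vector(p[, , , j])[i] - as.vector(t2[, , , j])[i]
        acc <- c(acc, d^2)
      }
      sqrt(mean(acc))
    })
    expect_equal(unname(rmse_components(p, t2, mk)), oracle)
  }
})

test_that("SSIM: identity, anticorrelation, decorrelation and symmetry", {
  set.seed(6)
  t <- array(rnorm(48^3 * 3), c(48, 48, 48, 3))
  expect_equal(unname(ssim_components(t, t)), c(1, 1, 1))
  # anticorrelated fields have negative similarity
  expect_true(all(ssim_components(-t, t) < 0))
  # independent random fields decorrelate
  p <- array(rnorm(48^3 * 3), c(48, 48, 48, 3))
  expect_true(all(abs(ssim_components(p, t)) < 0.1))
  # symmetric under argument swap at a fixed data range
  s1 <- ssim_components(p, t, data_range = 4)
  s2 <- ssim_components(t, p, data_range = 4)
  expect_equal(s1, s2)
  # equal constant volumes are perfectly similar by convention
  k <- array(1, c(8, 8, 8, 3))
  expect_equal(unname(ssim_components(k, k)), c(1, 1, 1))
})

test_that("regression and Bland-Altman recover affine relations", {
  t <- random_patch(5, 9, scale = 0.5)
  m <- array(TRUE, c(5, 5, 5))
  r0 <- regression_bland_altman(t, t, m)
  expect_equal(r0$slope, rep(1, 4))
  expect_equal(r0$offset, rep(0, 4), tolerance = 1e-12)
  expect_equal(r0$bias, rep(0, 4))
  # constant shift: slope 1, offset = bias = shift (per component)
  r1 <- regression_bland_altman(t + 0.02, t, m)
  expect_equal(r1$slope[1:3], rep(1, 3))
  expect_equal(r1$offset[1:3], rep(0.02, 3))
  expect_equal(r1$bias[1:3], rep(0.02, 3))
  expect_equal(r1$loa_lower[1:3], r1$bias[1:3] - 1.96 * 0)
  # pure scaling: slope 0.9, offset 0
  r2 <- regression_bland_altman(0.9 * t, t, m)
  expect_equal(r2$slope[1:3], rep(0.9, 3))
  expect_equal(r2$offset[1:3], rep(0, 3), tolerance = 1e-12)
  expect_error(regression_bland_altman(t, t, array(FALSE, c(5, 5, 5))),
               "voxels")
  # axial-slab restriction ignores voxels outside the constriction window
  t2 <- t
  t2[1, , , ] <- 99    # corrupt a slab outside the window
  r3 <- regression_bland_altman(t2 + 0.01, t2, m, region_x = c(3, 5))
  expect_equal(r3$bias[1:3], rep(0.01, 3))
})

test_that("full evaluation report assembles every metric", {
  s <- get_lr_frame()
  tri <- interp_upsample(s$lr$velocity_lr, 4)
  rep <- evaluate_sr(tri, s$hr, s$flow$mask,
                     region_x = constriction_region(s$flow))
  expect_s3_class(rep, "eval_report")
  expect_true(rep$re > 0 && rep$re < pi / 2)
  expect_true(all(rep$rmse >= 0))
  expect_true(all(abs(rep$ssim) <= 1))
  expect_equal(nrow(rep$agreement), 4)
})
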