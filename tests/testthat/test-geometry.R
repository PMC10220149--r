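test_that("geometry catalogue reproduces the published parameter tables", {
  cat20 <- geometry_catalogue()
  expect_equal(nrow(cat20), 20)
  expect_equal(cat20$id, 1:20)
  g1 <- cat20[cat20$id == 1, ]
  expect_equal(g1$v_I, 0.30)
  expect_equal(g1$R_I, 5.0)
  expect_equal(g1$R_C, 1.00)
  g19 <- cat20[cat20$id == 19, ]
  expect_equal(g19$theta, 30.0)
  expect_equal(g19$delta, 2.25)
  expect_equal(g19$direction, "sideways")
  # the shaped set inherits the dimensions of geometry 3
  shaped <- cat20[cat20$id > 10, ]
  expect_true(all(shaped$v_I == 0.50 & shaped$R_I == 5 & shaped$R_C == 1.5))
  basic <- cat20[cat20$shape_class == "basic", ]
  expect_true(all(basic$theta == 0 & basic$delta == 0))
  expect_true(all(cat20$R_C < cat20$R_I & cat20$v_I > 0))
})

test_that("parabolic inlet profile: worked values, rim, and flow rate", {
  expect_equal(inlet_profile(0, 0, 0.30, 5), 0.30)
  expect_equal(inlet_profile(3, 4, 0.77, 5), 0)   # rim for any v_I
  expect_equal(inlet_profile(2.5, 2.5, 0.30, 5), 0.15)
  expect_error(inlet_profile(4, 4, 0.3, 5), "outside")
  # numerical integral over the disc at 0.1 mm sampling matches the
  # closed-form parabolic flow rate pi R^2 v/2 to < 1 %
  h <- 0.1
  xs <- seq(-5, 5, by = h)
  gr <- expand.grid(x = xs, y = xs)
  gr <- gr[gr$x^2 + gr$y^2 <= 25, ]
  q_num <- sum(inlet_profile(gr$x, gr$y, 0.30, 5)) * h^2
  q_ref <- pi * 25 * 0.30 / 2
  expect_lt(abs(q_num - q_ref) / q_ref, 0.01)
})

test_that("temporal envelope peaks once at tau and decays", {
  expect_equal(temporal_envelope(0.013, 0.013), 1)
  expect_equal(temporal_envelope(0, 0.013), 0)
  expect_equal(temporal_envelope(2 * 0.02, 0.02), 2 * exp(-1))
  t <- seq(0.02, 0.2, by = 0.002)
  g <- temporal_envelope(t, 0.02)
  expect_true(all(diff(g) < 0))          # strictly decreasing past the peak
  expect_true(all(g >= 0 & g <= 1))
  expect_error(temporal_envelope(0.1, -1), "tau")
})

test_that("synthesised flow respects mask, frame count and peak location", {
  fx <- get_fixtures()
  flow <- fx$flow
  expect_s3_class(flow, "flow_series")
  expect_equal(length(flow$times), flow$geom$n_frames)
  fr <- flow_frame(flow, 3)
  for (j in 1:3) expect_true(all(fr[, , , j][!flow$mask] == 0))
  # peak speed is inside the constricted segment and exceeds v_I
  xpk <- flow$peak_voxel[1] * flow$grid$spacing + flow$grid$origin[1]
  x0 <- flow$geom$upstream_length
  expect_gte(xpk, x0)
  expect_lte(xpk, x0 + flow$geom$constriction_length + 1)
  expect_gt(max(flow$base_max_abs), flow$geom$v_I)
  # separable time factor: one envelope scales every voxel identically
  f2 <- flow_frame(flow, 5)
  expect_equal(f2, flow$base * flow$envelope[5])
  # deterministic: re-synthesis is bit-identical
  flow2 <- synthesize_flow(flow$geom, flow$grid)
  expect_identical(flow2$base, flow$base)
  expect_identical(flow2$mask, flow$mask)
  # unresolvable constriction errors out
  tiny <- geometry_config(geometry_catalogue()[5, ])
  expect_error(synthesize_flow(tiny, flow_grid(c(24, 12, 12), 1)),
               "not representable")
})

test_that("knn mask agrees with a brute-force distance-sort oracle", {
  set.seed(31)
  fluid <- cbind(runif(40, 2, 8), runif(40, 2, 8), runif(40, 2, 8))
  wall <- cbind(runif(60, 0, 10), runif(60, 0, 10), runif(60, 0, 10))
  grid <- flow_grid(c(6, 5, 4), 1.7, origin = c(0.3, 0.2, 0.1))
  oracle <- function(k) {
    xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing
    ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing
    zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing
    q <- as.matrix(expand.grid(xs, ys, zs))
    pts <- rbind(fluid, wall)
    lab <- c(rep(TRUE, nrow(fluid)), rep(FALSE, nrow(wall)))
    res <- apply(q, 1, function(p) {
      d <- sqrt(colSums((t(pts) - p)^2))
      sum(lab[order(d)[1:k]]) > k / 2
    })
    array(res, grid$shape)
  }
  expect_equal(knn_mask(fluid, wall, grid, k = 1), oracle(1))
  expect_equal(knn_mask(fluid, wall, grid, k = 5), oracle(5))
  # a voxel centre coincident with a fluid point is fluid at k = 1
  g1 <- flow_grid(c(1, 1, 1), 1, origin = fluid[1, ])
  expect_true(knn_mask(fluid, wall, g1, k = 1)[1, 1, 1])
  expect_error(knn_mask(fluid[0, ], wall, grid), "non-empty")
  expect_error(knn_mask(fluid, wall, grid, k = 2), "odd")
})
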