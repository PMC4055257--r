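test_that("linear-gradient map honors the quarter-maximum convention", {
  g <- grid_spec(64, 64, voxel_size = 0.005)
  m <- linear_gradient_map(g, 37.5e-9, axis_length = 0.32)
  # continuous edge maximum 8 nT; voxel centers sit half a voxel inside
  expect_equal(max(Re(m$values)), 8e-9 - 37.5e-9 * 0.0025, tolerance = 1e-12)
  # value at the exact midpoint (average of the two central columns)
  mid <- mean(Re(m$values[32, 32:33, 1]))
  expect_equal(mid, 2e-9, tolerance = 1e-12)
  # linearity: neighboring columns differ by G * voxel
  expect_equal(Re(m$values[10, 11, 1]) - Re(m$values[10, 12, 1]),
               37.5e-9 * 0.005, tolerance = 1e-9)
  expect_true(all(Im(m$values) == 0))
  # field crosses zero inside the FOV (far side negative)
  expect_lt(min(Re(m$values)), 0)
})

test_that("loop map matches the analytic on-axis Biot-Savart field", {
  g <- grid_spec(33, 33, voxel_size = 0.005)
  r <- 0.1; off <- 0.4
  m <- loop_coil_map(g, r, off, n_segments = 3600L)
  co <- grid_coords(g)
  on_axis <- which(co$y == 0 & co$z == 0)
  d <- off - co$x[on_axis]
  analytic <- 2 * pi * 1e-7 * r^2 / (r^2 + d^2)^1.5
  expect_equal(Mod(m$values[on_axis]), analytic, tolerance = 1e-4)
  # magnitude decreases monotonically with distance along the axis
  ord <- order(d)
  expect_true(all(diff(Mod(m$values[on_axis])[ord]) < 0))
})

test_that("loop map is mirror-symmetric about its axis and rejects bad geometry", {
  g <- grid_spec(21, 21, voxel_size = 0.005)
  m <- loop_coil_map(g, 0.08, 0.3)
  v <- Mod(m$values[, , 1])
  expect_equal(v, v[21:1, ], tolerance = 1e-10)   # +y vs -y
  expect_error(loop_coil_map(g, 0.08, 0.04), "intersects")
  expect_true(m$rotate_phase)
})

test_that("map rotation: identity, quarter-turn oracle, full-turn closure", {
  g <- grid_spec(32, 32, voxel_size = 0.01)
  # smooth test map supported away from the boundary
  co <- grid_coords(g)
  rad2 <- co$x^2 + co$y^2
  v <- exp(-rad2 / (2 * 0.05^2)) * (1 + co$x / 0.16)
  m <- b1_map(g, v)
  expect_identical(rotate_map(m, 0)$values, m$values)
  # 90 degrees counterclockwise must agree with the exact index quarter-turn
  q <- rotate_map(m, 90)
  oracle <- aperm(v[, dim(v)[2]:1, , drop = FALSE], c(2, 1, 3))
  expect_equal(max(abs(q$values - oracle)) / max(abs(v)), 0, tolerance = 1e-6)
  # four quarter turns recover the map
  m4 <- rotate_map(rotate_map(rotate_map(rotate_map(m, 90), 90), 90), 90)
  expect_equal(max(abs(m4$values - m$values)) / max(abs(v)), 0,
               tolerance = 1e-6)
  expect_equal(m4$nominal_angle, 360)
})

test_that("rotation approximately conserves energy and composes", {
  g <- grid_spec(32, 32, voxel_size = 0.01)
  co <- grid_coords(g)
  v <- exp(-(co$x^2 + co$y^2) / (2 * 0.05^2)) * (1 + 3 * co$y)
  m <- b1_map(g, v)
  e0 <- sum(Mod(m$values)^2)
  r1 <- rotate_map(m, 37)
  expect_equal(sum(Mod(r1$values)^2) / e0, 1, tolerance = 1e-3)
  # rotate(a) then rotate(b) ~ rotate(a + b)
  r2 <- rotate_map(r1, 53)
  r3 <- rotate_map(m, 90)
  # two interpolation passes versus one: bounded by the kernel accuracy
  expect_equal(max(abs(r2$values - r3$values)) / max(abs(v)), 0,
               tolerance = 0.02)
})

test_that("global phase flag multiplies by e^{i angle}", {
  g <- grid_spec(16, 16, voxel_size = 0.01)
  m <- uniform_map(g, 1e-9)
  r <- rotate_map(m, 45, rotation_options(apply_global_phase = TRUE))
  inner <- r$values[8, 8, 1]
  expect_equal(Arg(inner), pi / 4, tolerance = 1e-6)
  # default for a plain map: no phase
  r0 <- rotate_map(m, 45)
  expect_equal(Arg(r0$values[8, 8, 1]), 0, tolerance = 1e-12)
})

test_that("linear interpolation order is available and behaves", {
  g <- grid_spec(24, 24, voxel_size = 0.01)
  co <- grid_coords(g)
  v <- exp(-(co$x^2 + co$y^2) / (2 * 0.06^2))
  m <- b1_map(g, v)
  rl <- rotate_map(m, 30, rotation_options(order = "linear"))
  rc <- rotate_map(m, 30, rotation_options(order = "cubic"))
  expect_false(identical(rl$values, rc$values))
  expect_equal(max(abs(rl$values - rc$values)) / max(abs(v)), 0,
               tolerance = 0.05)
})

test_that("map noise is bounded, seeded, and off at fraction zero", {
  g <- grid_spec(16, 16, voxel_size = 0.01)
  m <- linear_gradient_map(g, 37.5e-9)
  expect_identical(add_map_noise(m, 0), m)
  peak <- max(Mod(m$values))
  n1 <- add_map_noise(m, 0.002, seed = 7)
  n2 <- add_map_noise(m, 0.002, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_lte(max(abs(Re(n1$values - m$values))), 0.002 * peak)
  expect_lte(max(abs(Im(n1$values - m$values))), 0.002 * peak)
  expect_gt(max(abs(n1$values - m$values)), 0)
})
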