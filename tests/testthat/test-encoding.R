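# Shared small configuration for encoding tests
enc_setup <- function(n = 16, M = n, spr = 2 * n, cycles = 3) {
  g <- tiny_grid(n)
  pulse <- gauss_pulse(5e-3, 64)
  sch <- build_schedule(M, spr, 2 * pi / pulse$duration, pulse, dims = 2)
  map <- linear_gradient_map(g, 37.5e-9)
  cal <- calibrate_encoding(map, sch, cycles_per_g = cycles)
  list(g = g, sch = sch, map = map, cal = cal)
}

test_that("zero phantom and zero drive produce zero data", {
  s <- enc_setup()
  ph <- single_voxel_image(s$g, 8, 8, 0)
  ph$values[8, 8, 1] <- 0
  m <- full_mask(s$g)
  expect_true(all(simulate_measurement_linear(scalar_image(s$g,
    array(0, c(16, 16, 1))), s$map, s$cal, s$sch, mask = m) == 0))
  cal0 <- s$cal; cal0$amplitude_scale <- 1e-30
  D <- simulate_measurement_bloch(make_shepp_logan(s$g), s$map, cal0, s$sch)
  expect_lt(max(Mod(D)), 1e-12)
})

test_that("a single voxel at the isocenter gives |D| = sin(accumulated flip)", {
  s <- enc_setup(n = 17)           # odd grid: a voxel sits exactly at center
  ph <- single_voxel_image(s$g, 9, 9)
  u <- uniform_map(s$g, 4e-9)
  cal <- calibrate_amplitude(s$sch$pulse, s$sch$M_encodes, 4e-9,
                             target_max_flip = 30)
  D <- simulate_measurement_linear(ph, u, cal, s$sch)
  # flip accumulated at sample s: gamma g A B1 * cumulative envelope integral
  spr <- s$sch$samples_per_rotation
  dt <- 5e-3 / spr
  env <- s$sch$pulse$env_fun((seq_len(spr) - 0.5) * dt)
  phi_end <- cal$gamma * cal$amplitude_scale * 4e-9 *
    outer(cumsum(env) * dt, phase_encode_scale(seq_len(s$sch$M_encodes),
                                               s$sch$M_encodes))
  expect_equal(Mod(D), abs(sin(as.vector(phi_end))), tolerance = 1e-10)
  # phase equals the map phase (0 or pi for the real map)
  expect_true(all(abs(sin(Arg(D)[Mod(D) > 0])) < 1e-10))
})

test_that("an encode with g = 0 measures nothing", {
  s <- enc_setup(n = 11, M = 11)   # odd M: alpha = 6 has g = 0
  ph <- make_shepp_logan(s$g)
  D <- simulate_measurement_linear(ph, s$map, s$cal, s$sch)
  idx <- which(s$sch$events$g == 0)
  expect_gt(length(idx), 0)
  expect_true(all(Mod(D[idx]) == 0))
  expect_gt(max(Mod(D[-idx])), 0)
})

test_that("the linear model is exactly linear in the phantom", {
  s <- enc_setup(n = 12)
  m <- full_mask(s$g)
  set.seed(9)
  a <- scalar_image(s$g, array(runif(144), c(12, 12, 1)))
  b <- scalar_image(s$g, array(runif(144), c(12, 12, 1)))
  ab <- scalar_image(s$g, a$values + b$values)
  Da <- simulate_measurement_linear(a, s$map, s$cal, s$sch, mask = m)
  Db <- simulate_measurement_linear(b, s$map, s$cal, s$sch, mask = m)
  Dab <- simulate_measurement_linear(ab, s$map, s$cal, s$sch, mask = m)
  expect_equal(Dab, Da + Db, tolerance = 1e-12)
})

test_that("encoding matrix columns are point-source measurements (superposition)", {
  s <- enc_setup(n = 12)
  ph <- make_shepp_logan(s$g)
  mask <- make_mask(ph, 0)
  for (mode in c("linear", "bloch")) {
    sim <- if (mode == "linear") simulate_measurement_linear
           else simulate_measurement_bloch
    E <- build_encoding_matrix(mode, mask, s$map, s$cal, s$sch)
    D <- sim(ph, s$map, s$cal, s$sch, mask = mask)
    expect_lt(max(Mod(drop(E %*% ph$values[mask$values]) - D)) /
                max(Mod(D)), 1e-12)
    # and with identical noise seed the identity still holds exactly
    En <- build_encoding_matrix(mode, mask, s$map, s$cal, s$sch,
                                noise_fraction = 0.002, noise_seed = 5)
    Dn <- sim(ph, s$map, s$cal, s$sch, noise_fraction = 0.002,
              noise_seed = 5, mask = mask)
    expect_lt(max(Mod(drop(En %*% ph$values[mask$values]) - Dn)) /
                max(Mod(Dn)), 1e-12)
    # a 2-voxel mask gives a 2-column matrix of the point-source signals
    two <- mask; two$values[] <- FALSE
    sel <- which(mask$values)[c(3, 10)]
    two$values[sel] <- TRUE
    E2 <- build_encoding_matrix(mode, two, s$map, s$cal, s$sch)
    expect_identical(dim(E2), c(nrow(s$sch$events), 2L))
    expect_equal(E2[, 1], E[, which(which(mask$values) == sel[1])],
                 tolerance = 1e-12)
  }
})

test_that("Bloch data converge to the sine model in the small-tip regime", {
  s <- enc_setup(n = 16)
  ph <- make_shepp_logan(s$g)
  mask <- make_mask(ph, 0)
  # decreasing-amplitude ladder: relative gap shrinks with the flip
  gaps <- vapply(c(5, 1), function(fa) {
    cal <- calibrate_amplitude(s$sch$pulse, s$sch$M_encodes,
                               max(Mod(s$map$values)), target_max_flip = fa)
    Dl <- simulate_measurement_linear(ph, s$map, cal, s$sch, mask = mask)
    Db <- simulate_measurement_bloch(ph, s$map, cal, s$sch, mask = mask)
    sqrt(sum(Mod(Dl - Db)^2) / sum(Mod(Db)^2))
  }, numeric(1))
  expect_lt(gaps[1], 0.01)
  expect_lt(gaps[2], gaps[1])
})

test_that("a constant transverse field flipping 90 deg converts all Mz to signal", {
  g <- tiny_grid(9)
  ph <- single_voxel_image(g, 5, 5, 2.5)   # Mz = 2.5 A/m
  u <- uniform_map(g, 4e-9)
  p <- rect_pulse(5e-3, 64)
  sch <- build_schedule(2, 32, 2 * pi / 5e-3, p, dims = 2)
  # alpha = 2 has g = +1/2; calibrate its end-of-TR flip to 90 deg
  cal <- calibrate_amplitude(p, 2, 4e-9, target_max_flip = 90)
  D <- simulate_measurement_bloch(ph, u, cal, sch)
  expect_equal(Mod(D[length(D)]), 2.5, tolerance = 1e-6)
})

test_that("the masked reference system has full column rank", {
  s <- enc_setup(n = 32, spr = 6 * 32)
  ph <- make_shepp_logan(s$g)
  mask <- make_mask(ph, 0)
  E <- build_encoding_matrix("linear", mask, s$map, s$cal, s$sch)
  d <- svd(E, nu = 0, nv = 0)$d
  expect_equal(sum(d > max(dim(E)) * .Machine$double.eps * d[1]), ncol(E))
  # comfortably conditioned, which is what makes the inversion work
  expect_lt(d[1] / d[length(d)], 1e3)
})
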