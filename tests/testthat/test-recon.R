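test_that("pinv solves identity and well-conditioned complex systems", {
  D <- complex(real = rnorm(8), imaginary = rnorm(8))
  expect_equal(drop(solve_pinv(diag(8) + 0i, D)), D, tolerance = 1e-12,
               ignore_attr = TRUE)
  set.seed(11)
  E <- matrix(complex(real = rnorm(2500), imaginary = rnorm(2500)), 50, 50)
  G0 <- complex(real = rnorm(50), imaginary = rnorm(50))
  x <- solve_pinv(E, drop(E %*% G0))
  expect_lt(max(Mod(x - G0)) / max(Mod(G0)), 1e-10)
  expect_lt(attr(x, "rel_residual"), 1e-10)
})

test_that("pinv gives the minimum-norm solution on rank-deficient systems", {
  # 5x3 rank-2 instance; oracle from explicit regularized normal equations
  set.seed(12)
  B <- matrix(rnorm(10), 5, 2)
  C <- matrix(rnorm(6), 2, 3)
  E <- B %*% C                       # rank 2
  D <- rnorm(5)
  oracle <- function(lambda)
    solve(t(E) %*% E + lambda * diag(3), t(E) %*% D)
  # Tikhonov limit lambda -> 0 converges to the minimum-norm LS solution
  # (lambda small enough for negligible bias, large enough to keep the
  # regularized normal equations numerically solvable)
  x_o <- oracle(1e-8)
  x <- solve_pinv(E, D, rel_tol = 1e-8)
  expect_equal(drop(x), drop(x_o), tolerance = 1e-4, ignore_attr = TRUE)
  expect_identical(attr(x, "rank"), 2L)
})

test_that("lsqr matches pinv on consistent systems and honors its defaults", {
  D <- complex(real = rnorm(6), imaginary = rnorm(6))
  x <- solve_lsqr(diag(6) + 0i, D, residual_tol = 1e-6)
  expect_equal(drop(x), D, tolerance = 1e-6, ignore_attr = TRUE)
  set.seed(13)
  E <- matrix(rnorm(60 * 40), 60, 40)
  G0 <- rnorm(40)
  Dv <- drop(E %*% G0)
  xl <- solve_lsqr(E, Dv)
  xp <- solve_pinv(E, Dv)
  # accuracy is set by the residual tolerance times the conditioning
  expect_lt(max(abs(xl - xp)) / max(abs(xp)), 1e-5)
  expect_identical(formals(solve_lsqr)$max_iter, 400L)
  expect_identical(formals(solve_lsqr)$residual_tol, 1e-6)
  expect_error(solve_lsqr(E, rnorm(10)), "mismatch")
  expect_error(solve_pinv(matrix(0, 0, 0), numeric(0)), "empty")
})

test_that("deviation metrics are zero for perfect and rescaled reconstructions", {
  g <- tiny_grid(16)
  ph <- make_shepp_logan(g)
  mask <- make_mask(ph, 0)
  m <- deviation_metrics(ph, ph, mask)
  expect_equal(m$max_abs, 0)
  expect_equal(m$mean, 0)
  # peak normalization removes a global scale
  m2 <- deviation_metrics(scalar_image(g, 1.05 * ph$values), ph, mask)
  expect_lt(m2$max_abs, 1e-12)
})

test_that("a single-voxel 5% defect reads as a 5.0 maximum deviation", {
  g <- tiny_grid(16)
  ph <- make_shepp_logan(g)
  mask <- make_mask(ph, 0)
  sel <- which(mask$values & ph$values < 0.5)[1]
  v <- ph$values
  v[sel] <- v[sel] + 0.05 * max(v)
  m <- deviation_metrics(scalar_image(g, v), ph, mask)
  expect_equal(m$max_abs, 5, tolerance = 1e-10)
  # histogram counts account for every masked voxel
  expect_identical(sum(m$histogram$counts), sum(mask$values))
  expect_identical(sum(!is.na(m$map)), sum(mask$values))
})

test_that("rrfc_fit returns a usable model object with both solvers", {
  g <- tiny_grid(12)
  ph <- make_shepp_logan(g)
  mask <- make_mask(ph, 0)
  pulse <- gauss_pulse(5e-3, 64)
  sch <- build_schedule(12, 24, 2 * pi / 5e-3, pulse, dims = 2)
  map <- linear_gradient_map(g, 37.5e-9)
  cal <- calibrate_encoding(map, sch)
  E <- build_encoding_matrix("linear", mask, map, cal, sch)
  D <- simulate_measurement_linear(ph, map, cal, sch, mask = mask)
  for (method in c("pinv", "lsqr")) {
    fit <- rrfc_fit(E, D, method = method, mask = mask)
    expect_s3_class(fit, "rrfc_fit")
    expect_length(coef(fit), sum(mask$values))
    expect_equal(fitted(fit) + residuals(fit), D, tolerance = 1e-12)
    expect_equal(predict(fit), fitted(fit))
    expect_equal(drop(predict(fit, E[1:5, ])), fitted(fit)[1:5],
                 tolerance = 1e-12)
    expect_output(print(fit), method)
    expect_s3_class(fit$image, "scalar_image")
    # noiseless consistent system: essentially exact recovery
    expect_lt(deviation_metrics(fit, ph, mask)$max_abs, 1e-3)
  }
})

test_that("masked solve does not hurt the masked-support residual", {
  g <- tiny_grid(12)
  ph <- make_shepp_logan(g)
  mask <- make_mask(ph, 0)
  pulse <- gauss_pulse(5e-3, 64)
  sch <- build_schedule(12, 24, 2 * pi / 5e-3, pulse, dims = 2)
  map <- linear_gradient_map(g, 37.5e-9)
  cal <- calibrate_encoding(map, sch)
  D <- simulate_measurement_linear(ph, map, cal, sch, mask = mask)
  E_full <- build_encoding_matrix("linear", full_mask(g), map, cal, sch)
  E_mask <- build_encoding_matrix("linear", mask, map, cal, sch)
  r_full <- attr(solve_pinv(E_full, D), "rel_residual")
  r_mask <- attr(solve_pinv(E_mask, D), "rel_residual")
  expect_lte(r_mask, r_full + 1e-10)
})
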