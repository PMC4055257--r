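# Shared fixtures: small grids, a uniform map, and an all-in mask.

tiny_grid <- function(n = 16, vox = 0.32 / n) grid_spec(n, n, voxel_size = vox)

uniform_map <- function(grid, value = 5e-9) {
  b1_map(grid, array(value, c(grid$n_rows, grid$n_cols, grid$n_slices)))
}

full_mask <- function(grid) {
  make_mask(scalar_image(grid, array(1, c(grid$n_rows, grid$n_cols,
                                          grid$n_slices))), 0)
}

single_voxel_image <- function(grid, row, col, value = 1) {
  v <- array(0, c(grid$n_rows, grid$n_cols, grid$n_slices))
  v[row, col, 1] <- value
  scalar_image(grid, v)
}

# independent brute-force point-in-ellipse rendering of the head phantom,
# used as an oracle against make_shepp_logan()
brute_force_shepp_logan <- function(n) {
  ell <- list(
    c( 1.00, 0.6900, 0.9200,  0.00,  0.0000,   0),
    c(-0.98, 0.6624, 0.8740,  0.00, -0.0184,   0),
    c(-0.02, 0.1100, 0.3100,  0.22,  0.0000, -18),
    c(-0.02, 0.1600, 0.4100, -0.22,  0.0000,  18),
    c( 0.01, 0.2100, 0.2500,  0.00,  0.3500,   0),
    c( 0.01, 0.0460, 0.0460,  0.00,  0.1000,   0),
    c( 0.01, 0.0460, 0.0460,  0.00, -0.1000,   0),
    c( 0.01, 0.0460, 0.0230, -0.08, -0.6050,   0),
    c( 0.01, 0.0230, 0.0230,  0.00, -0.6060,   0),
    c( 0.01, 0.0230, 0.0460,  0.06, -0.6050,   0))
  img <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- (j - (n + 1) / 2) / (n / 2)
    y <- ((n + 1) / 2 - i) / (n / 2)
    v <- 0
    for (e in ell) {
      ph <- e[6] * pi / 180
      xr <- (x - e[4]) * cos(ph) + (y - e[5]) * sin(ph)
      yr <- -(x - e[4]) * sin(ph) + (y - e[5]) * cos(ph)
      if ((xr / e[2])^2 + (yr / e[3])^2 <= 1) v <- v + e[1]
    }
    img[i, j] <- v
  }
  img[img < 0 & img > -1e-12] <- 0
  img
}
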