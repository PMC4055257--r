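## Digital test objects: Shepp-Logan head phantom, three-layer block, masks.

# Canonical (original, non-contrast-modified) Shepp-Logan ellipse table:
# additive intensity, semi-axes a/b, center x0/y0 (units of half field of
# view), rotation angle in degrees.
shepp_logan_ellipses <- function() {
  m <- matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.98, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.02, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.02, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.01, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.01, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.01, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.01, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.01, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.01, 0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE)
  colnames(m) <- c("A", "a", "b", "x0", "y0", "phi")
  m
}

#' Shepp-Logan head phantom
#'
#' Renders the standard ten-ellipse Shepp-Logan phantom (original intensity
#' set, values in \[0, 1\]) on a 2D grid.  A voxel takes an ellipse's additive
#' intensity if its center lies inside the ellipse; there is no anti-aliasing,
#' so the rendering is deterministic and matches a brute-force
#' point-in-ellipse test exactly.
#'
#' @param grid A 2D [grid_spec()] (`n_slices == 1`).
#' @return A [scalar_image()].
#' @examples
#' ph <- make_shepp_logan(grid_spec(64, 64))
#' range(ph$values)
#' @export
make_shepp_logan <- function(grid) {
  if (!grid_is_2d(grid)) stop("make_shepp_logan requires a 2D grid")
  e <- shepp_logan_ellipses()
  co <- grid_coords(grid)
  half_fov <- max(grid$n_rows, grid$n_cols) * grid$voxel_size / 2
  X <- co$x[, , 1L] / half_fov
  Y <- co$y[, , 1L] / half_fov
  img <- matrix(0, grid$n_rows, grid$n_cols)
  for (k in seq_len(nrow(e))) {
    ph <- e[k, "phi"] * pi / 180
    xr <- (X - e[k, "x0"]) * cos(ph) + (Y - e[k, "y0"]) * sin(ph)
    yr <- -(X - e[k, "x0"]) * sin(ph) + (Y - e[k, "y0"]) * cos(ph)
    inside <- (xr / e[k, "a"])^2 + (yr / e[k, "b"])^2 <= 1
    img[inside] <- img[inside] + e[k, "A"]
  }
  # additive composition can leave values like 1 - 0.98 - 0.02 = -1e-17
  img[img < 0 & img > -1e-12] <- 0
  scalar_image(grid, img)
}

#' Three-layer rectangular phantom
#'
#' A rectangular block centered in a 3D grid: the block spans the central
#' `ceiling(2/3)` of the in-plane dimensions and the full slice extent, and is
#' partitioned along the slice axis into three near-equal-thickness slabs with
#' the given intensities.  Voxels outside the block are zero.
#'
#' @param grid A 3D [grid_spec()].
#' @param layer_values Numeric vector of exactly 3 slab intensities
#'   (default `c(1.0, 0.6, 0.3)`).
#' @return A [scalar_image()].
#' @examples
#' ph <- make_layer_phantom(grid_spec(21, 21, 21))
#' @export
make_layer_phantom <- function(grid, layer_values = c(1.0, 0.6, 0.3)) {
  if (grid_is_2d(grid)) stop("make_layer_phantom requires a 3D grid")
  if (length(layer_values) != 3L) stop("exactly 3 layer intensities required")
  d <- grid_dim(grid)
  block_extent <- function(n) {
    w <- ceiling(2 * n / 3)
    lo <- floor((n - w) / 2) + 1L
    lo:(lo + w - 1L)
  }
  rows <- block_extent(d[1]); cols <- block_extent(d[2])
  if (length(rows) > d[1] || length(cols) > d[2])
    stop("block does not fit inside grid")
  # near-equal thirds of the slice axis
  cuts <- round(seq(0, d[3], length.out = 4))
  v <- array(0, d)
  for (s in 1:3) {
    sl <- (cuts[s] + 1L):cuts[s + 1L]
    v[rows, cols, sl] <- layer_values[s]
  }
  scalar_image(grid, v)
}

#' Threshold mask from an image
#'
#' A voxel is inside the mask iff its intensity exceeds
#' `threshold_fraction * max(intensity)`.  With `threshold_fraction = 0` the
#' mask is the nonzero support of the image.
#'
#' @param image A [scalar_image()].
#' @param threshold_fraction Fraction of the peak intensity in `[0, 1)`.
#' @return An object of class `b1_mask` with logical `values`.
#' @export
make_mask <- function(image, threshold_fraction = 0) {
  stopifnot(inherits(image, "scalar_image"),
            threshold_fraction >= 0, threshold_fraction < 1)
  peak <- max(image$values)
  if (peak <= 0) stop("cannot build a mask from an all-zero image")
  inside <- image$values > threshold_fraction * peak
  if (!any(inside)) stop("mask is empty")
  structure(list(grid = image$grid, values = inside), class = "b1_mask")
}

#' @export
print.b1_mask <- function(x, ...) {
  cat(sprintf("<b1_mask> %s, %d voxels in\n",
              paste(grid_dim(x$grid), collapse = " x "), sum(x$values)))
  invisible(x)
}

mask_count <- function(mask) sum(mask$values)
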