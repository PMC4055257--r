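#' Spatial grid specification
#'
#' Defines the voxel grid on which phantoms, coil maps and reconstructions
#' live.  The isocenter (rotation pivot) is the geometric center of the grid:
#' voxel `(i, j)` (1-based row/column) has physical in-plane coordinates
#' `x = (j - (n_cols + 1)/2) * voxel_size` (along columns) and
#' `y = ((n_rows + 1)/2 - i) * voxel_size` (row index increasing downward
#' maps to physical +y up).  Slices are stacked along z with the same spacing.
#'
#' @param n_rows,n_cols,n_slices Grid dimensions (`n_slices = 1` for 2D).
#' @param voxel_size Isotropic voxel edge length in meters.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(64, 64, voxel_size = 0.005)  # 32 cm field of view
#' @export
grid_spec <- function(n_rows, n_cols, n_slices = 1L, voxel_size = 0.005) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_slices >= 1, voxel_size > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_slices = as.integer(n_slices), voxel_size = voxel_size),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.3g mm isotropic\n",
              x$n_rows, x$n_cols, x$n_slices, 1e3 * x$voxel_size))
  invisible(x)
}

grid_dim <- function(grid) c(grid$n_rows, grid$n_cols, grid$n_slices)

grid_is_2d <- function(grid) grid$n_slices == 1L

#' Physical voxel-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A list with arrays `x`, `y`, `z` of dimension
#'   `n_rows x n_cols x n_slices` giving the physical coordinate (meters)
#'   of every voxel center relative to the isocenter.
#' @export
grid_coords <- function(grid) {
  d <- grid_dim(grid)
  xs <- (seq_len(d[2]) - (d[2] + 1) / 2) * grid$voxel_size
  ys <- ((d[1] + 1) / 2 - seq_len(d[1])) * grid$voxel_size
  zs <- (seq_len(d[3]) - (d[3] + 1) / 2) * grid$voxel_size
  list(x = array(rep(xs, each = d[1]), d),
       y = array(ys, d),
       z = array(rep(zs, each = d[1] * d[2]), d))
}

same_grid <- function(a, b) {
  identical(grid_dim(a), grid_dim(b)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

check_values_shape <- function(grid, values) {
  d <- grid_dim(grid)
  v <- if (is.matrix(values) && d[3] == 1L) array(values, d) else values
  if (!identical(dim(v), as.integer(d)))
    stop("value array shape does not match grid (", paste(d, collapse = "x"), ")")
  if (!all(is.finite(Re(v))) || (is.complex(v) && !all(is.finite(Im(v)))))
    stop("values must be finite")
  v
}

#' Scalar image on a grid
#'
#' @param grid A [grid_spec()].
#' @param values Non-negative real intensities, matrix (2D) or 3D array
#'   matching the grid.
#' @return An object of class `scalar_image` with fields `grid` and `values`.
#' @export
scalar_image <- function(grid, values) {
  v <- check_values_shape(grid, values)
  if (any(v < 0)) stop("scalar_image intensities must be >= 0")
  structure(list(grid = grid, values = v), class = "scalar_image")
}

#' @export
print.scalar_image <- function(x, ...) {
  d <- grid_dim(x$grid)
  cat(sprintf("<scalar_image> %s, range [%.4g, %.4g]\n",
              paste(d, collapse = " x "), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.scalar_image <- function(x, main = "scalar image", ...) {
  v <- x$values[, , 1L]
  graphics::image(t(v[nrow(v):1, , drop = FALSE]), asp = 1, axes = FALSE,
                  col = grDevices::gray.colors(256, 0, 1), main = main, ...)
  invisible(x)
}
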