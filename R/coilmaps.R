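## Complex B1+ transmit sensitivity maps: construction, rotation, noise.

#' Construct a coil sensitivity map from raw values
#'
#' @param grid A [grid_spec()].
#' @param values Complex (or real) field values per voxel, tesla per unit
#'   drive; matrix (2D) or 3D array matching the grid.
#' @param nominal_angle Coil angular position in degrees.
#' @param rotate_phase Whether [rotate_map()] should apply the
#'   angle-dependent global phase `e^{i theta}` by default.
#' @return A `b1_map`.
#' @export
b1_map <- function(grid, values, nominal_angle = 0, rotate_phase = FALSE) {
  new_b1_map(grid, values, nominal_angle, rotate_phase)
}

new_b1_map <- function(grid, values, nominal_angle = 0, rotate_phase = FALSE) {
  v <- check_values_shape(grid, values)
  if (!is.complex(v)) v <- v + 0i
  if (all(v == 0)) stop("B1 map must not be identically zero")
  structure(list(grid = grid, values = v, nominal_angle = nominal_angle,
                 rotate_phase = rotate_phase),
            class = "b1_map")
}

#' @export
print.b1_map <- function(x, ...) {
  cat(sprintf("<b1_map> %s, |B1| in [%.3g, %.3g] T, angle %.3g deg%s\n",
              paste(grid_dim(x$grid), collapse = " x "),
              min(Mod(x$values)), max(Mod(x$values)), x$nominal_angle,
              if (x$rotate_phase) ", angle-dependent phase" else ""))
  invisible(x)
}

#' Linear-gradient transmit field map
#'
#' The transmit amplitude varies linearly along the +x (column) axis with
#' slope `unit_gradient`, maximal at the edge nearest the virtual coil
#' (x = -axis_length/2).  The quarter-maximum convention fixes the peak: the
#' amplitude at the axis midpoint (the isocenter) is one quarter of the
#' maximum, so `B1max = unit_gradient * (axis_length/2) / (3/4)`.  Beyond the
#' zero crossing the field amplitude is negative (a pi phase flip), as for a
#' real linearly polarized field.  The phase is uniform (zero) at nominal
#' angle 0, and rotation does not add a global phase for this map.
#'
#' @param grid A [grid_spec()].
#' @param unit_gradient Field slope in tesla per meter (> 0).
#' @param axis_length Extent of the gradient axis in meters; defaults to the
#'   grid's column extent.
#' @return A `b1_map`.
#' @examples
#' m <- linear_gradient_map(grid_spec(64, 64), 37.5e-9)
#' max(Mod(m$values))  # 8e-9 T at the 0.32 m field of view
#' @export
linear_gradient_map <- function(grid, unit_gradient, axis_length = NULL) {
  stopifnot(unit_gradient > 0)
  if (is.null(axis_length)) axis_length <- grid$n_cols * grid$voxel_size
  stopifnot(axis_length > 0)
  b1max <- unit_gradient * (axis_length / 2) / 0.75
  if (b1max <= 0) stop("geometry gives a non-positive peak field")
  co <- grid_coords(grid)
  v <- b1max - unit_gradient * (co$x + axis_length / 2)
  new_b1_map(grid, v, rotate_phase = FALSE)
}

#' Surface-loop transmit field map (quasi-static Biot-Savart surrogate)
#'
#' Complex sensitivity of a circular current loop placed beside the imaging
#' region, with the loop axis horizontal (+x), computed by discretizing the
#' loop into straight segments and summing Biot-Savart contributions.  The
#' map value is the transverse circular component `(Bx + i By)` per unit
#' current; its magnitude decreases monotonically with distance from the loop
#' along the axis, and its phase is the transverse-field orientation.
#' Rotation of this map applies the angle-dependent global phase `e^{i theta}`.
#'
#' @param grid A [grid_spec()].
#' @param loop_radius Loop radius in meters (> 0).
#' @param loop_center_offset Distance from the isocenter to the loop center
#'   along +x, meters.  The loop plane (perpendicular to +x) must not
#'   intersect the grid.
#' @param loop_z_offset Loop-center displacement along the slice axis,
#'   meters.  For 3D encoding a nonzero value is essential: a loop centered
#'   on the rotation axis has a field magnitude and transverse phase that are
#'   mirror-symmetric in z, and rotation about z preserves that symmetry, so
#'   slices at +z and -z would be indistinguishable.
#' @param n_segments Number of straight segments for the loop discretization.
#' @return A `b1_map`.
#' @export
loop_coil_map <- function(grid, loop_radius, loop_center_offset,
                          loop_z_offset = 0, n_segments = 72L) {
  stopifnot(loop_radius > 0)
  half_x <- grid$n_cols * grid$voxel_size / 2
  if (loop_center_offset <= half_x)
    stop("loop intersects the imaging grid; increase loop_center_offset")
  co <- grid_coords(grid)
  pts <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
  # loop in the plane x = loop_center_offset, center displaced by loop_z_offset
  ph <- seq(0, 2 * pi, length.out = n_segments + 1L)
  nodes <- cbind(loop_center_offset, loop_radius * cos(ph),
                 loop_z_offset + loop_radius * sin(ph))
  bx <- numeric(nrow(pts)); by <- numeric(nrow(pts))
  for (s in seq_len(n_segments)) {
    a <- nodes[s, ]; b <- nodes[s + 1L, ]
    dl <- b - a
    mid <- (a + b) / 2
    rx <- pts[, 1] - mid[1]; ry <- pts[, 2] - mid[2]; rz <- pts[, 3] - mid[3]
    r3 <- (rx^2 + ry^2 + rz^2)^1.5
    # dl x r, transverse components; mu0/(4 pi) = 1e-7
    bx <- bx + 1e-7 * (dl[2] * rz - dl[3] * ry) / r3
    by <- by + 1e-7 * (dl[3] * rx - dl[1] * rz) / r3
  }
  new_b1_map(grid, array(complex(real = bx, imaginary = by), grid_dim(grid)),
             rotate_phase = TRUE)
}

## --- interpolation kernels -------------------------------------------------

keys_cubic_weight <- function(s) {
  s <- abs(s)
  ifelse(s <= 1, 1.5 * s^3 - 2.5 * s^2 + 1,
         ifelse(s < 2, -0.5 * s^3 + 2.5 * s^2 - 4 * s + 2, 0))
}

# Interpolate a real matrix at fractional (row, col) positions, zero outside.
interp_plane <- function(m, rr, cc, order = c("cubic", "linear")) {
  order <- match.arg(order)
  nr <- nrow(m); nc <- ncol(m)
  out <- numeric(length(rr))
  if (order == "linear") {
    r0 <- floor(rr); c0 <- floor(cc)
    for (dr in 0:1) for (dc in 0:1) {
      ri <- r0 + dr; ci <- c0 + dc
      w <- (1 - abs(rr - ri)) * (1 - abs(cc - ci))
      ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc & w > 0
      out[ok] <- out[ok] + w[ok] * m[(ci[ok] - 1) * nr + ri[ok]]
    }
  } else {
    r0 <- floor(rr); c0 <- floor(cc)
    for (dr in -1:2) for (dc in -1:2) {
      ri <- r0 + dr; ci <- c0 + dc
      w <- keys_cubic_weight(rr - ri) * keys_cubic_weight(cc - ci)
      ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc & w != 0
      out[ok] <- out[ok] + w[ok] * m[(ci[ok] - 1) * nr + ri[ok]]
    }
  }
  out
}

# Evaluate a map's complex values at physical points rotated by -theta
# (i.e. the map rotated by +theta evaluated at x, y), one slice.
map_eval_rotated_slice <- function(slice_vals, grid, theta_rad, x, y,
                                   order = "cubic") {
  ct <- cos(theta_rad); st <- sin(theta_rad)
  xr <- ct * x + st * y
  yr <- -st * x + ct * y
  cc <- xr / grid$voxel_size + (grid$n_cols + 1) / 2
  rr <- (grid$n_rows + 1) / 2 - yr / grid$voxel_size
  re <- interp_plane(Re(slice_vals), rr, cc, order)
  if (is.complex(slice_vals) && any(Im(slice_vals) != 0)) {
    complex(real = re, imaginary = interp_plane(Im(slice_vals), rr, cc, order))
  } else re
}

#' Rotation options for coil maps
#'
#' @param order Interpolation order, `"cubic"` (Catmull-Rom cubic
#'   convolution, the default) or `"linear"`.
#' @param apply_global_phase Multiply the rotated map by `e^{i angle}`
#'   (angle-dependent coil phase).  `NULL` (default) defers to the map's own
#'   `rotate_phase` flag.
#' @return A list of class `rotation_options`.
#' @export
rotation_options <- function(order = c("cubic", "linear"),
                             apply_global_phase = NULL) {
  structure(list(order = match.arg(order),
                 apply_global_phase = apply_global_phase),
            class = "rotation_options")
}

#' Rotate a coil map about the isocenter
#'
#' Real and imaginary channels are rotated independently by `angle`
#' (counterclockwise, degrees) about the grid center with the chosen
#' interpolation; points mapped from outside the support fill with zero.  3D
#' maps rotate slice-wise about the slice axis.  If the global phase is
#' enabled the result is multiplied by `e^{i angle}`, and the map's nominal
#' angle is incremented either way.
#'
#' @param map A `b1_map`.
#' @param angle Rotation angle in degrees.
#' @param options A [rotation_options()].
#' @return The rotated `b1_map`.
#' @export
rotate_map <- function(map, angle, options = rotation_options()) {
  stopifnot(inherits(map, "b1_map"))
  apply_phase <- options$apply_global_phase
  if (is.null(apply_phase)) apply_phase <- map$rotate_phase
  if (angle == 0) {
    out <- map
  } else {
    th <- angle * pi / 180
    d <- grid_dim(map$grid)
    co <- grid_coords(map$grid)
    x <- co$x[, , 1L]; y <- co$y[, , 1L]
    v <- array(0i, d)
    for (s in seq_len(d[3])) {
      v[, , s] <- array(map_eval_rotated_slice(map$values[, , s], map$grid,
                                               th, x, y, options$order),
                        d[1:2])
    }
    out <- map
    out$values <- v
  }
  if (apply_phase && angle != 0)
    out$values <- out$values * exp(1i * angle * pi / 180)
  out$nominal_angle <- map$nominal_angle + angle
  out
}

#' Add bounded uniform acquisition noise to a map
#'
#' Perturbs the real and imaginary part of every voxel by independent uniform
#' draws in `[-fraction, +fraction]` times a reference peak magnitude
#' (by default the map's own peak `|B1|`).  Reproducible for a fixed seed.
#'
#' @param map A `b1_map`.
#' @param fraction Noise bound as a fraction of the reference peak (>= 0);
#'   the stated acquisition condition is `0.002` (0.2 percent).
#' @param seed Integer RNG seed.
#' @param ref_peak Reference peak magnitude in tesla; `NULL` uses the map's
#'   own peak.
#' @return The perturbed `b1_map`.
#' @export
add_map_noise <- function(map, fraction, seed = NULL, ref_peak = NULL) {
  stopifnot(inherits(map, "b1_map"), fraction >= 0)
  if (fraction == 0) return(map)
  if (is.null(ref_peak)) ref_peak <- max(Mod(map$values))
  if (!is.null(seed)) set.seed(seed)
  n <- length(map$values)
  map$values <- map$values + complex(
    real = stats::runif(n, -fraction, fraction) * ref_peak,
    imaginary = stats::runif(n, -fraction, fraction) * ref_peak)
  map
}
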