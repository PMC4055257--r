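## Import/export of images, masks and coil maps as NIfTI and CSV.

nifti_with_pixdim <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr)
  # NIfTI spatial units are mm by convention; single-slice volumes are
  # treated as 2D by RNifti, so match the image's own dimensionality
  RNifti::pixdim(img) <- rep(voxel_size * 1e3, length(RNifti::pixdim(img)))
  img
}

#' Write a scalar image or mask as NIfTI
#'
#' Identity orientation, pixel dimensions from the grid's voxel size (mm).
#'
#' @param x A [scalar_image()] or `b1_mask`.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @export
write_image_nifti <- function(x, file) {
  stopifnot(inherits(x, "scalar_image") || inherits(x, "b1_mask"))
  RNifti::writeNifti(nifti_with_pixdim(x$values + 0, x$grid$voxel_size), file)
  invisible(file)
}

#' Read a NIfTI volume as a scalar image
#'
#' @param file NIfTI path.
#' @return A [scalar_image()]; the voxel size is taken from the first pixel
#'   dimension (mm converted to meters).
#' @export
read_image_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  vs <- RNifti::pixdim(img)[1] / 1e3
  scalar_image(grid_spec(dim(arr)[1], dim(arr)[2], dim(arr)[3],
                         voxel_size = vs), arr)
}

#' Write a 2D scalar image as CSV
#'
#' @param x A [scalar_image()] with a single slice.
#' @param file Output path.
#' @export
write_image_csv <- function(x, file) {
  stopifnot(inherits(x, "scalar_image"), grid_is_2d(x$grid))
  utils::write.table(x$values[, , 1L], file, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write a coil map as paired NIfTI volumes (magnitude, phase)
#'
#' @param map A `b1_map`.
#' @param magnitude_file,phase_file Output paths; phase in radians.
#' @export
write_map_nifti <- function(map, magnitude_file, phase_file) {
  stopifnot(inherits(map, "b1_map"))
  RNifti::writeNifti(nifti_with_pixdim(Mod(map$values), map$grid$voxel_size),
                     magnitude_file)
  RNifti::writeNifti(nifti_with_pixdim(Arg(map$values), map$grid$voxel_size),
                     phase_file)
  invisible(c(magnitude_file, phase_file))
}

#' Write a coil map as a two-channel CSV (real, imaginary)
#'
#' One row per voxel in column-major scan order, with voxel indices.
#'
#' @param map A `b1_map`.
#' @param file Output path.
#' @export
write_map_csv <- function(map, file) {
  stopifnot(inherits(map, "b1_map"))
  d <- grid_dim(map$grid)
  idx <- arrayInd(seq_along(map$values), d)
  utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2],
                              slice = idx[, 3],
                              re = Re(as.vector(map$values)),
                              im = Im(as.vector(map$values))),
                   file, row.names = FALSE)
  invisible(file)
}

#' Read a two-channel CSV back into a coil map
#'
#' @param file CSV written by [write_map_csv()].
#' @param voxel_size Voxel edge in meters.
#' @param rotate_phase Whether rotation should apply the angle-dependent
#'   global phase.
#' @return A `b1_map`.
#' @export
read_map_csv <- function(file, voxel_size = 0.005, rotate_phase = FALSE) {
  df <- utils::read.csv(file)
  d <- c(max(df$row), max(df$col), max(df$slice))
  v <- array(0i, d)
  v[cbind(df$row, df$col, df$slice)] <- complex(real = df$re, imaginary = df$im)
  new_b1_map(grid_spec(d[1], d[2], d[3], voxel_size = voxel_size), v,
             rotate_phase = rotate_phase)
}
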