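#' 3D intensity stack with voxel metadata
#'
#' A `VoxelGrid` is the package's in-memory representation of a single-channel
#' Z-stack: a 3D integer-valued array indexed `[z, y, x]` (slice 1 is the top
#' of the sample, nearest the objective) together with the lateral pixel size,
#' the Z-step between consecutive optical sections, and the bit depth.
#'
#' Intensities must lie in `[0, 2^bit_depth - 1]`.  The stack must have at
#' least 2 slices and at least 2 pixels along y and x.
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`, integer-valued.
#' @param pixel_size_um lateral pixel size in micrometers (isotropic in XY).
#' @param z_step_um distance between consecutive slices in micrometers.
#' @param bit_depth 8 or 16.
#' @return An object of class `VoxelGrid`.
#' @examples
#' g <- voxel_grid(array(0:15, dim = c(2, 2, 4)), 0.363, 0.5, 8)
#' dim(g$data)
#' @export
voxel_grid <- function(data, pixel_size_um, z_step_um, bit_depth = 8L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_parameter("'data' must be a 3D array indexed (z, y, x)")
  d <- dim(data)
  if (d[1] < 2L || d[2] < 2L || d[3] < 2L)
    abort_parameter("VoxelGrid needs >= 2 slices and >= 2 pixels in y and x")
  if (!bit_depth %in% c(8L, 16L))
    abort_parameter("'bit_depth' must be 8 or 16")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    abort_parameter("'pixel_size_um' must be a positive number")
  if (!is.numeric(z_step_um) || length(z_step_um) != 1L ||
      is.na(z_step_um) || z_step_um <= 0)
    abort_parameter("'z_step_um' must be a positive number")
  storage.mode(data) <- "double"
  if (any(data != floor(data)))
    abort_parameter("VoxelGrid intensities must be integer-valued")
  maxv <- 2^bit_depth - 1
  if (any(data < 0) || any(data > maxv))
    abort_parameter(sprintf("intensities must lie in [0, %d]", maxv))
  structure(
    list(data = data,
         pixel_size_um = as.numeric(pixel_size_um),
         z_step_um = as.numeric(z_step_um),
         bit_depth = as.integer(bit_depth)),
    class = "VoxelGrid")
}

#' @export
print.VoxelGrid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<VoxelGrid> %d slices x %d x %d px, %d-bit, %.4g um/px XY, %.4g um Z-step\n",
    d[1], d[2], d[3], x$bit_depth, x$pixel_size_um, x$z_step_um))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.VoxelGrid <- function(x) dim(x$data)

is_voxel_grid <- function(x) inherits(x, "VoxelGrid")

#' 2D contour image
#'
#' The maximal-intensity projection of a cropped signal layer: a 2D numeric
#' matrix indexed `[y, x]` carrying the pixel size and bit depth of the stack
#' it came from.
#'
#' @param data 2D numeric matrix `[y, x]`.
#' @param pixel_size_um lateral pixel size in micrometers.
#' @param bit_depth 8 or 16.
#' @return An object of class `ContourImage` (a matrix with attributes).
#' @export
contour_image <- function(data, pixel_size_um, bit_depth = 8L) {
  if (!is.matrix(data)) abort_parameter("'data' must be a 2D matrix")
  structure(data,
            pixel_size_um = as.numeric(pixel_size_um),
            bit_depth = as.integer(bit_depth),
            class = c("ContourImage", "matrix", "array"))
}

#' @export
print.ContourImage <- function(x, ...) {
  cat(sprintf("<ContourImage> %d x %d px, %d-bit, %.4g um/px, max %g\n",
              nrow(x), ncol(x), attr(x, "bit_depth"),
              attr(x, "pixel_size_um"), max(x)))
  invisible(x)
}

# Binary stacks share shape with their source grid; a SurfaceMask is a
# BinaryStack whose columns never switch off again with depth.
binary_stack <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    abort_parameter("a BinaryStack is a 3D logical array")
  structure(list(data = data), class = "BinaryStack")
}

surface_mask <- function(data) {
  x <- binary_stack(data)
  class(x) <- c("SurfaceMask", "BinaryStack")
  x
}

#' @export
print.BinaryStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d, %d voxels on\n",
              class(x)[1], d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}
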