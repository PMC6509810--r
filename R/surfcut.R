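#' Parameters for surface-layer extraction
#'
#' The four knobs of the extraction pipeline: the Gaussian blur radius used to
#' de-noise the stack before binarization, the 8-bit intensity threshold for
#' the binary conversion, and the depth window (in micrometers below the
#' detected surface) whose signal is kept.  The window is half-open
#' `[depth_top_um, depth_bottom_um)`: at a 0.5 um Z-step, a 6-8 um window
#' keeps 4 slices.
#'
#' @param blur_radius_px Gaussian sigma in pixels, applied per slice; 0 skips
#'   blurring.
#' @param threshold integer in `[0, 255]`; voxels at or above it count as
#'   signal (binarization happens after 8-bit conversion).
#' @param depth_top_um,depth_bottom_um crop window below the surface, in
#'   micrometers; `depth_bottom_um > depth_top_um >= 0`.
#' @return An object of class `SurfCutParams`.
#' @examples
#' surfcut_params(blur_radius_px = 1, threshold = 60,
#'                depth_top_um = 0, depth_bottom_um = 2)
#' @export
surfcut_params <- function(blur_radius_px = 1, threshold = 100,
                           depth_top_um = 0, depth_bottom_um = 2) {
  if (!is.numeric(blur_radius_px) || length(blur_radius_px) != 1L ||
      is.na(blur_radius_px) || blur_radius_px < 0)
    abort_parameter("'blur_radius_px' must be a non-negative number")
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold != floor(threshold) || threshold < 0 || threshold > 255)
    abort_parameter("'threshold' must be an integer in [0, 255]")
  if (!is.numeric(depth_top_um) || depth_top_um < 0)
    abort_parameter("'depth_top_um' must be >= 0")
  if (!is.numeric(depth_bottom_um) || depth_bottom_um <= depth_top_um)
    abort_parameter("'depth_bottom_um' must exceed 'depth_top_um'")
  structure(list(blur_radius_px = as.numeric(blur_radius_px),
                 threshold = as.integer(threshold),
                 depth_top_um = as.numeric(depth_top_um),
                 depth_bottom_um = as.numeric(depth_bottom_um)),
            class = "SurfCutParams")
}

#' @export
print.SurfCutParams <- function(x, ...) {
  cat(sprintf(
    "<SurfCutParams> blur sigma %.3g px, threshold %d, depth window [%g, %g) um\n",
    x$blur_radius_px, x$threshold, x$depth_top_um, x$depth_bottom_um))
  invisible(x)
}

# round half away from zero (the convention of integer image arithmetic;
# base::round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a stack to 8 bit
#'
#' Linear min-max rescale of the stack-wide intensity range onto `[0, 255]`,
#' rounding half up.  An 8-bit stack is returned unchanged.  A constant stack
#' has no contrast to threshold and is rejected.
#'
#' @param grid a [voxel_grid()].
#' @return An 8-bit [voxel_grid()].
#' @export
to_8bit <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  if (grid$bit_depth == 8L) return(grid)
  lo <- min(grid$data); hi <- max(grid$data)
  if (lo == hi)
    abort_degenerate(sprintf(
      "stack is constant (all voxels %g): no contrast to threshold", lo))
  scaled <- round_half_up((grid$data - lo) * (255 / (hi - lo)))
  voxel_grid(scaled, grid$pixel_size_um, grid$z_step_um, 8L)
}

# reflected-boundary 1D Gaussian convolution matrix for a signal of length n
gaussian_conv_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (t in seq(-r, r)) {
      j <- i + t
      # reflect-101 style mirroring (a b c | b a) clamped to valid range
      while (j < 1L || j > n) {
        if (j < 1L) j <- 2L - j
        if (j > n) j <- 2L * n - j
      }
      C[i, j] <- C[i, j] + k[t + r + 1L]
    }
  }
  C
}

#' De-noise a stack with a per-slice Gaussian blur
#'
#' Each z-slice is convolved independently with a 2D Gaussian of standard
#' deviation `blur_radius_px` (separable, reflected boundaries), then rounded
#' back to the stack's integer bit depth.  Radius 0 is the identity.  The blur
#' is 2D per slice, not 3D: it mirrors how slice-wise Gaussian filtering of a
#' stack behaves in standard image-processing toolkits.
#'
#' @param grid a [voxel_grid()].
#' @param blur_radius_px Gaussian sigma in pixels, `>= 0`.
#' @return A blurred [voxel_grid()] of the same shape and bit depth.
#' @export
gaussian_denoise <- function(grid, blur_radius_px) {
  stopifnot(is_voxel_grid(grid))
  if (!is.numeric(blur_radius_px) || length(blur_radius_px) != 1L ||
      is.na(blur_radius_px) || blur_radius_px < 0)
    abort_parameter("'blur_radius_px' must be a non-negative number")
  if (blur_radius_px == 0) return(grid)
  d <- dim(grid$data)
  Cy <- gaussian_conv_matrix(d[2], blur_radius_px)
  Cx <- gaussian_conv_matrix(d[3], blur_radius_px)
  out <- grid$data
  for (z in seq_len(d[1])) {
    out[z, , ] <- Cy %*% grid$data[z, , , drop = TRUE] %*% t(Cx)
  }
  out <- pmin(pmax(round_half_up(out), 0), 2^grid$bit_depth - 1)
  voxel_grid(out, grid$pixel_size_um, grid$z_step_um, grid$bit_depth)
}

#' Binarize an 8-bit stack
#'
#' A voxel is foreground iff its intensity is at or above `threshold`.
#'
#' @param grid an 8-bit [voxel_grid()].
#' @param threshold integer in `[0, 255]`.
#' @return A `BinaryStack` (3D logical array wrapper).
#' @export
binarize <- function(grid, threshold) {
  stopifnot(is_voxel_grid(grid))
  if (grid$bit_depth != 8L)
    abort_parameter("binarize() expects an 8-bit stack; run to_8bit() first")
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold != floor(threshold) || threshold < 0 || threshold > 255)
    abort_parameter("'threshold' must be an integer in [0, 255]")
  binary_stack(grid$data >= threshold)
}

#' Fill the binary object by cumulative down-projection
#'
#' Starting from the top slice, each slice is OR-ed with everything above it:
#' `out[z] = bin[1] | ... | bin[z]`.  A column `(y, x)` is therefore on at
#' depth z iff any signal was seen at or above z — holes inside cells (which
#' have wall signal above them) are filled, and the result is a solid mask
#' below the first detected signal per column.
#'
#' @param bin a `BinaryStack`.
#' @return A `SurfaceMask` (downward-monotone `BinaryStack`).
#' @export
edge_fill <- function(bin) {
  stopifnot(inherits(bin, "BinaryStack"))
  m <- bin$data
  nz <- dim(m)[1]
  for (z in seq_len(nz)[-1]) m[z, , ] <- m[z, , ] | m[z - 1L, , ]
  surface_mask(m)
}

#' Convert a depth in micrometers to a slice count
#'
#' Rounds `depth_um / z_step_um` to the nearest whole slice, ties away from
#' zero.  Whole slices are shifted during cropping; there is no sub-slice
#' interpolation.
#'
#' @param depth_um depth in micrometers, `>= 0`.
#' @param z_step_um Z-interval in micrometers, `> 0`.
#' @return Integer slice count.
#' @examples
#' depth_to_slices(6, 0.5)   # 12
#' depth_to_slices(8, 0.5)   # 16
#' @export
depth_to_slices <- function(depth_um, z_step_um) {
  if (!is.numeric(z_step_um) || z_step_um <= 0)
    abort_parameter("'z_step_um' must be positive")
  if (!is.numeric(depth_um) || any(depth_um < 0))
    abort_parameter("'depth_um' must be >= 0")
  as.integer(round_half_up(depth_um / z_step_um))
}

#' Crop a stack between two surface-relative depths
#'
#' The filled surface mask, shifted down by `top_slices` and `bottom_slices`,
#' selects which raw voxels survive: voxel `(z, y, x)` keeps its intensity iff
#' the mask is on at `z - top_slices` and off at `z - bottom_slices` (shifts
#' falling above the stack read as off).  For a column whose first signal sits
#' at slice s, the kept slices are exactly the half-open window
#' `[s + top_slices, s + bottom_slices)`; columns with no signal are zeroed.
#'
#' @param raw the stack to crop (the original, un-blurred 8-bit stack).
#' @param mask a `SurfaceMask` from [edge_fill()], same shape as `raw`.
#' @param top_slices,bottom_slices window in slices, `bottom > top >= 0`.
#' @return A [voxel_grid()] with out-of-window voxels set to 0.
#' @export
crop_by_shifted_mask <- function(raw, mask, top_slices, bottom_slices) {
  stopifnot(is_voxel_grid(raw), inherits(mask, "SurfaceMask"))
  if (!identical(dim(raw$data), dim(mask$data)))
    abort_parameter("stack and mask shapes differ")
  top_slices <- as.integer(top_slices); bottom_slices <- as.integer(bottom_slices)
  if (top_slices < 0 || bottom_slices <= top_slices)
    abort_parameter("need bottom_slices > top_slices >= 0")
  nz <- dim(raw$data)[1]
  if (top_slices >= nz)
    abort_parameter(sprintf(
      "top depth (%d slices) is at or below the bottom of the %d-slice stack",
      top_slices, nz))
  out <- array(0, dim = dim(raw$data))
  for (z in seq_len(nz)) {
    zt <- z - top_slices      # mask slice whose 'on' admits this voxel
    zb <- z - bottom_slices   # mask slice whose 'on' expels this voxel
    keep_top <- if (zt >= 1L) mask$data[zt, , , drop = TRUE] else
      matrix(FALSE, dim(raw$data)[2], dim(raw$data)[3])
    expel <- if (zb >= 1L) mask$data[zb, , , drop = TRUE] else
      matrix(FALSE, dim(raw$data)[2], dim(raw$data)[3])
    keep <- keep_top & !expel
    out[z, , ] <- raw$data[z, , , drop = TRUE] * keep
  }
  voxel_grid(out, raw$pixel_size_um, raw$z_step_um, raw$bit_depth)
}

#' Maximum-intensity projection along z
#'
#' @param cropped a [voxel_grid()] (typically the output of
#'   [crop_by_shifted_mask()]).
#' @return A [contour_image()] where `out[y, x] = max_z cropped[z, y, x]`.
#' @export
max_project <- function(cropped) {
  stopifnot(is_voxel_grid(cropped))
  contour_image(apply(cropped$data, c(2, 3), max),
                cropped$pixel_size_um, cropped$bit_depth)
}

#' Extract a surface-relative signal layer and project it to 2D
#'
#' The full extraction chain: convert to 8 bit, blur per slice, binarize,
#' build the filled surface mask by cumulative down-projection, crop the
#' *un-blurred* 8-bit stack between the two surface-relative depths, and
#' maximum-project the cropped layer.  The blurred, binarized stack is used
#' only to build the mask; intensities in the output come from the original
#' signal.  The first slice of the stack must be the top surface of the
#' sample — this is a contract on the input that cannot be checked.
#'
#' @param raw a [voxel_grid()].
#' @param p a [surfcut_params()].
#' @return A list of class `SurfCutResult` with elements `contour` (the
#'   [contour_image()]), `cropped` (the cropped [voxel_grid()]), `mask` (the
#'   `SurfaceMask`), and `params`.  All three artifacts are returned so a
#'   calibration run can inspect intermediates.
#' @examples
#' ph <- make_flat_sheet(n_cells_y = 2, n_cells_x = 2, cell_size_px = 10)
#' res <- surfcut(ph$grid, surfcut_params(0, 100, 0, 2))
#' max(res$contour)
#' @export
surfcut <- function(raw, p) {
  stopifnot(is_voxel_grid(raw), inherits(p, "SurfCutParams"))
  g8 <- to_8bit(raw)
  blurred <- gaussian_denoise(g8, p$blur_radius_px)
  bin <- binarize(blurred, p$threshold)
  mask <- edge_fill(bin)
  if (!any(mask$data))
    abort_extraction(sprintf(
      "no voxel reaches threshold %d (stack max after 8-bit conversion: %g); recalibrate the threshold",
      p$threshold, max(g8$data)))
  top <- depth_to_slices(p$depth_top_um, raw$z_step_um)
  bottom <- depth_to_slices(p$depth_bottom_um, raw$z_step_um)
  if (bottom <= top)
    abort_parameter("depth window collapses to zero slices at this Z-step")
  cropped <- crop_by_shifted_mask(g8, mask, top, bottom)
  structure(list(contour = max_project(cropped), cropped = cropped,
                 mask = mask, params = p),
            class = "SurfCutResult")
}

#' @export
print.SurfCutResult <- function(x, ...) {
  d <- dim(x$cropped$data)
  cat(sprintf("<SurfCutResult> %dx%dx%d stack -> %dx%d contour image; %d voxels kept\n",
              d[1], d[2], d[3], nrow(x$contour), ncol(x$contour),
              sum(x$cropped$data > 0)))
  print(x$params)
  invisible(x)
}
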