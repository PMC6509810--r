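# Synthetic phantoms: 3D stacks with a bright cell-wall lattice on a dark
# background and a known surface geometry. They emulate propidium-iodide
# stained epidermis (flat cotyledon, tilted sheet, cylindrical hypocotyl,
# hemispherical meristem apex) and carry analytic ground truth so the
# extraction pipeline and the projection-bias study can be tested without
# real confocal data.

#' @keywords internal
phantom_truth <- function(surface_height_px, wall_mask_2d, cell_labels_2d,
                          cells, file_angle_deg, pixel_size_um, z_step_um,
                          geometry) {
  storage.mode(surface_height_px) <- "integer"
  structure(list(surface_height_px = surface_height_px,
                 wall_mask_2d = wall_mask_2d,
                 cell_labels_2d = cell_labels_2d,
                 cells = cells,
                 file_angle_deg = file_angle_deg,
                 pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um,
                 geometry = geometry),
            class = "PhantomTruth")
}

#' @export
print.PhantomTruth <- function(x, ...) {
  cat(sprintf("<PhantomTruth> %s: %d cells, %d cell files\n",
              x$geometry, nrow(x$cells), length(x$file_angle_deg)))
  invisible(x)
}

# rectangular wall lattice helpers: walls of thickness t surround and
# separate n cells of interior size cs, so the lattice spans n*cs + (n+1)*t
lattice_extent <- function(n, cs, t) n * cs + (n + 1L) * t

lattice_wall_idx <- function(n, cs, t) {
  unlist(lapply(0:n, function(k) k * (cs + t) + seq_len(t)))
}

lattice_cell_idx <- function(k, cs, t) (k - 1L) * (cs + t) + t + seq_len(cs)

# integrate sqrt(1 + |grad h|^2) over the pixels of one cell, h in um over
# projected um coordinates; grad_fun(xu, yu) returns list(gx, gy)
surface_area_over_pixels <- function(ys, xs, pixel_size_um, grad_fun,
                                     oversample = 3L) {
  sub <- (seq_len(oversample) - 0.5) / oversample
  total <- 0
  for (y in ys) {
    yy <- (y - 1 + sub) * pixel_size_um
    for (x in xs) {
      xx <- (x - 1 + sub) * pixel_size_um
      g <- grad_fun(rep(xx, each = oversample), rep(yy, times = oversample))
      total <- total + mean(sqrt(1 + g$gx^2 + g$gy^2))
    }
  }
  total * pixel_size_um^2
}

#' Flat-sheet phantom
#'
#' A rectangular lattice of `n_cells_y` by `n_cells_x` cells with interior
#' size `cell_size_px`, separated and surrounded by bright anticlinal walls
#' of thickness `wall_thickness_px` that extend `wall_depth_slices` slices
#' below a flat surface at slice `surface_slice`.  Background is 0.  The
#' stack's XY extent equals the lattice extent, so the outer walls lie on the
#' image border.  This is the zero-curvature regime in which Z-direction
#' cropping and surface-normal cropping agree and extracted areas equal true
#' areas.
#'
#' @param n_cells_y,n_cells_x lattice size in cells.
#' @param cell_size_px cell interior side length in pixels.
#' @param wall_intensity wall gray value (8-bit).
#' @param surface_slice 1-based slice index of the surface (first wall slice).
#' @param wall_thickness_px wall thickness in pixels.
#' @param wall_depth_slices how many slices the anticlinal walls extend down.
#' @param n_slices total stack depth; default leaves two empty slices below
#'   the walls.
#' @param pixel_size_um,z_step_um voxel sizes; defaults are the reference
#'   confocal sampling (0.363 um XY, 0.5 um Z).
#' @param periclinal_intensity optional gray value painted across the whole
#'   lattice surface (outer periclinal walls); 0 disables it so that only the
#'   anticlinal contours carry signal.
#' @return A list of class `Phantom` with elements `grid` (a [voxel_grid()])
#'   and `truth` (a `PhantomTruth`).
#' @examples
#' ph <- make_flat_sheet(2, 2, cell_size_px = 20, pixel_size_um = 1)
#' ph$truth$cells$true_area_um2   # 400 um^2 each
#' @export
make_flat_sheet <- function(n_cells_y = 3, n_cells_x = 3, cell_size_px = 40,
                            wall_intensity = 200, surface_slice = 3,
                            wall_thickness_px = 2, wall_depth_slices = 8,
                            n_slices = NULL, pixel_size_um = 0.363,
                            z_step_um = 0.5, periclinal_intensity = 0) {
  if (n_cells_y < 1 || n_cells_x < 1 || cell_size_px < 2)
    abort_parameter("need >= 1 cell per axis and cell_size_px >= 2")
  ny <- lattice_extent(n_cells_y, cell_size_px, wall_thickness_px)
  nx <- lattice_extent(n_cells_x, cell_size_px, wall_thickness_px)
  nz <- n_slices %||% (surface_slice + wall_depth_slices + 1L)
  if (nz < surface_slice + wall_depth_slices - 1L)
    abort_parameter("stack too shallow for the requested walls")

  wy <- lattice_wall_idx(n_cells_y, cell_size_px, wall_thickness_px)
  wx <- lattice_wall_idx(n_cells_x, cell_size_px, wall_thickness_px)
  wall2d <- matrix(FALSE, ny, nx)
  wall2d[wy, ] <- TRUE; wall2d[, wx] <- TRUE

  labels <- matrix(0L, ny, nx)
  for (iy in seq_len(n_cells_y)) for (ix in seq_len(n_cells_x)) {
    labels[lattice_cell_idx(iy, cell_size_px, wall_thickness_px),
           lattice_cell_idx(ix, cell_size_px, wall_thickness_px)] <-
      (iy - 1L) * n_cells_x + ix
  }

  data <- array(0, dim = c(nz, ny, nx))
  zw <- surface_slice + seq_len(wall_depth_slices) - 1L
  for (z in zw) data[z, , ][wall2d] <- wall_intensity
  if (periclinal_intensity > 0)
    data[surface_slice, , ][!wall2d] <-
      pmax(data[surface_slice, , ][!wall2d], periclinal_intensity)

  height <- matrix(NA_integer_, ny, nx)
  height[wall2d] <- surface_slice
  if (periclinal_intensity > 0) height[] <- surface_slice

  cell_area <- cell_size_px^2 * pixel_size_um^2
  ids <- seq_len(n_cells_y * n_cells_x)
  cells <- data.frame(cell_id = ids,
                      file_id = rep(seq_len(n_cells_x), times = n_cells_y),
                      true_area_um2 = cell_area,
                      projected_area_um2 = cell_area,
                      angle_deg = 0)
  file_angle <- stats::setNames(rep(0, n_cells_x), seq_len(n_cells_x))

  grid <- voxel_grid(data, pixel_size_um, z_step_um, 8L)
  structure(list(grid = grid,
                 truth = phantom_truth(height, wall2d, labels, cells,
                                       file_angle, pixel_size_um, z_step_um,
                                       "flat_sheet")),
            class = "Phantom")
}

#' Tilted-plane phantom
#'
#' The flat-sheet lattice on a plane rotated about the y axis by `angle_deg`:
#' the phantom is described in projected (top-down) coordinates, so the 2D
#' lattice is unchanged while the surface deepens along x with slope
#' `tan(angle)`.  The true (on-surface) cell area is the projected area
#' divided by `cos(angle)` — the analytic form of the tissue-curvature bias
#' that Z-direction cropping cannot see.  Every cell file shares the tilt
#' angle.
#'
#' @param angle_deg tilt about the y axis, `0 <= angle < 80` degrees.
#' @inheritParams make_flat_sheet
#' @return A `Phantom` (list with `grid` and `truth`).
#' @export
make_tilted_plane <- function(angle_deg, n_cells_y = 3, n_cells_x = 3,
                              cell_size_px = 40, wall_intensity = 200,
                              surface_slice = 3, wall_thickness_px = 2,
                              wall_depth_slices = 8, n_slices = NULL,
                              pixel_size_um = 0.363, z_step_um = 0.5) {
  if (!is.numeric(angle_deg) || angle_deg < 0 || angle_deg >= 80)
    abort_parameter("'angle_deg' must lie in [0, 80)")
  flat <- make_flat_sheet(n_cells_y, n_cells_x, cell_size_px, wall_intensity,
                          surface_slice, wall_thickness_px, wall_depth_slices,
                          n_slices = surface_slice + wall_depth_slices + 1L,
                          pixel_size_um = pixel_size_um, z_step_um = z_step_um)
  th <- angle_deg * pi / 180
  ny <- nrow(flat$truth$wall_mask_2d); nx <- ncol(flat$truth$wall_mask_2d)
  # per-column surface drop in slices, measured from column centers
  drop_sl <- as.integer(round_half_up(
    (seq_len(nx) - 1) * pixel_size_um * tan(th) / z_step_um))
  nz <- n_slices %||% (surface_slice + max(drop_sl) + wall_depth_slices + 1L)
  if (nz < surface_slice + max(drop_sl) + wall_depth_slices - 1L)
    abort_parameter("stack too shallow for this tilt; increase n_slices")

  wall2d <- flat$truth$wall_mask_2d
  data <- array(0, dim = c(nz, ny, nx))
  for (x in seq_len(nx)) {
    cols <- which(wall2d[, x])
    if (!length(cols)) next
    zs <- surface_slice + drop_sl[x] + seq_len(wall_depth_slices) - 1L
    data[zs, cols, x] <- wall_intensity
  }

  height <- matrix(NA_integer_, ny, nx)
  for (x in seq_len(nx))
    height[wall2d[, x], x] <- surface_slice + drop_sl[x]

  cells <- flat$truth$cells
  cells$true_area_um2 <- cells$projected_area_um2 / cos(th)
  cells$angle_deg <- angle_deg
  file_angle <- stats::setNames(rep(angle_deg, n_cells_x), seq_len(n_cells_x))

  grid <- voxel_grid(data, pixel_size_um, z_step_um, 8L)
  structure(list(grid = grid,
                 truth = phantom_truth(height, wall2d, flat$truth$cell_labels_2d,
                                       cells, file_angle, pixel_size_um,
                                       z_step_um, "tilted_plane")),
            class = "Phantom")
}

#' Cylinder phantom (hypocotyl analog)
#'
#' The upper half of a cylinder of radius `radius_um` whose axis runs along
#' y.  Cells are organized in `n_files` axial files spanning the
#' circumferential range `[-half_span_deg, half_span_deg]` around the apex,
#' each file `n_cells_axial` cells long.  Walls are drawn in projected
#' coordinates at the file boundaries (x positions `R sin(phi)`) and at axial
#' intervals, starting at the local surface depth.  Each file's angle is
#' measured as the paper-prescribed chord between its two outer wall
#' junctions on a transverse section, averaged at five axial positions.
#'
#' `bumpiness` (um) adds a per-cell sinusoidal dome to the surface height,
#' vanishing on the walls: it raises the true (on-surface) cell area while
#' leaving the projected contour lattice — and hence the extracted 2D area —
#' unchanged.  This is the cell-level curvature the Z-crop cannot account
#' for.
#'
#' @param radius_um cylinder radius in micrometers.
#' @param n_files number of cell files (>= 2).
#' @param bumpiness per-cell dome amplitude in micrometers (0 = smooth).
#' @param n_cells_axial cells per file along the axis.
#' @param axial_cell_px axial cell interior length in pixels.
#' @param half_span_deg circumferential half-span of the lattice in degrees
#'   (< 80 so the surface stays single-valued per column).
#' @inheritParams make_flat_sheet
#' @return A `Phantom` (list with `grid` and `truth`).
#' @export
make_cylinder <- function(radius_um = 30, n_files = 6, bumpiness = 0,
                          n_cells_axial = 2, axial_cell_px = 30,
                          half_span_deg = 60, wall_intensity = 200,
                          surface_slice = 2, wall_thickness_px = 2,
                          wall_depth_slices = 8, pixel_size_um = 0.363,
                          z_step_um = 0.5) {
  if (n_files < 2) abort_parameter("'n_files' must be >= 2")
  if (half_span_deg <= 0 || half_span_deg >= 80)
    abort_parameter("'half_span_deg' must lie in (0, 80)")
  if (bumpiness < 0) abort_parameter("'bumpiness' must be >= 0")
  t <- wall_thickness_px
  phimax <- half_span_deg * pi / 180
  R <- radius_um
  # file boundaries in angle and their projected x positions (um, 0 under axis)
  phib <- seq(-phimax, phimax, length.out = n_files + 1L)
  xb_um <- R * sin(phib)

  ny <- lattice_extent(n_cells_axial, axial_cell_px, t)
  # lay out x so boundary k sits at pixel column round(...); 1 px margin
  x0_um <- xb_um[1]
  xb_px <- as.integer(round_half_up((xb_um - x0_um) / pixel_size_um)) + 1L
  nx <- xb_px[n_files + 1L] + t - 1L
  if (any(diff(xb_px) < t + 2L))
    abort_parameter("files too narrow at this resolution; reduce n_files or raise radius_um")

  wall2d <- matrix(FALSE, ny, nx)
  wy <- lattice_wall_idx(n_cells_axial, axial_cell_px, t)
  wall2d[wy, ] <- TRUE
  for (k in seq_len(n_files + 1L))
    wall2d[, xb_px[k] + seq_len(t) - 1L] <- TRUE

  labels <- matrix(0L, ny, nx)
  for (iy in seq_len(n_cells_axial)) for (k in seq_len(n_files)) {
    xs <- (xb_px[k] + t):(xb_px[k + 1L] - 1L)
    labels[lattice_cell_idx(iy, axial_cell_px, t), xs] <-
      (iy - 1L) * n_files + k
  }

  # surface depth below the apex, in um, at projected offset x from the axis
  xc_um <- -x0_um  # axis x position in lattice um coordinates
  depth_um <- function(x_um) R - sqrt(pmax(R^2 - (x_um - xc_um)^2, 0))

  col_x_um <- (seq_len(nx) - 1) * pixel_size_um
  col_depth_sl <- as.integer(round_half_up(depth_um(col_x_um) / z_step_um))
  nz <- surface_slice + max(col_depth_sl) + wall_depth_slices + 1L

  data <- array(0, dim = c(nz, ny, nx))
  for (x in seq_len(nx)) {
    cols <- which(wall2d[, x])
    if (!length(cols)) next
    zs <- surface_slice + col_depth_sl[x] + seq_len(wall_depth_slices) - 1L
    data[zs, cols, x] <- wall_intensity
  }
  height <- matrix(NA_integer_, ny, nx)
  for (x in seq_len(nx))
    height[wall2d[, x], x] <- surface_slice + col_depth_sl[x]

  # truth areas: numerical surface integral over each cell's interior pixels
  axial_len_um <- axial_cell_px * pixel_size_um
  cells <- data.frame(cell_id = integer(0), file_id = integer(0),
                      true_area_um2 = numeric(0),
                      projected_area_um2 = numeric(0), angle_deg = numeric(0))
  file_angle <- stats::setNames(numeric(n_files), seq_len(n_files))
  for (k in seq_len(n_files)) {
    # chord between the two outer wall junctions, vs the horizontal;
    # sampled (identically, walls carry no bump) at five axial positions
    x1 <- (xb_px[k] - 1 + (t - 1) / 2) * pixel_size_um
    x2 <- (xb_px[k + 1L] - 1 + (t - 1) / 2) * pixel_size_um
    ang <- atan2(abs(depth_um(x2) - depth_um(x1)), abs(x2 - x1)) * 180 / pi
    file_angle[k] <- mean(rep(ang, 5L))
    for (iy in seq_len(n_cells_axial)) {
      id <- (iy - 1L) * n_files + k
      xs <- (xb_px[k] + t):(xb_px[k + 1L] - 1L)
      ys <- lattice_cell_idx(iy, axial_cell_px, t)
      y_lo <- (min(ys) - 1) * pixel_size_um; y_hi <- max(ys) * pixel_size_um
      x_lo <- (min(xs) - 1) * pixel_size_um; x_hi <- max(xs) * pixel_size_um
      grad <- function(xu, yu) {
        dx_c <- (xu - xc_um) / sqrt(pmax(R^2 - (xu - xc_um)^2, 1e-9))
        if (bumpiness > 0) {
          u <- (xu - x_lo) / (x_hi - x_lo); v <- (yu - y_lo) / (y_hi - y_lo)
          u <- pmin(pmax(u, 0), 1); v <- pmin(pmax(v, 0), 1)
          bx <- -bumpiness * (pi / (x_hi - x_lo)) * cos(pi * u) * sin(pi * v)
          by <- -bumpiness * (pi / (y_hi - y_lo)) * sin(pi * u) * cos(pi * v)
          # surface height = -depth + bump; gradient of height
          list(gx = -dx_c + bx, gy = by)
        } else list(gx = -dx_c, gy = rep(0, length(xu)))
      }
      area_true <- surface_area_over_pixels(ys, xs, pixel_size_um, grad)
      cells <- rbind(cells, data.frame(
        cell_id = id, file_id = k,
        true_area_um2 = area_true,
        projected_area_um2 = length(xs) * length(ys) * pixel_size_um^2,
        angle_deg = file_angle[k]))
    }
  }
  cells <- cells[order(cells$cell_id), ]
  rownames(cells) <- NULL

  grid <- voxel_grid(data, pixel_size_um, z_step_um, 8L)
  structure(list(grid = grid,
                 truth = phantom_truth(height, wall2d, labels, cells,
                                       file_angle, pixel_size_um, z_step_um,
                                       "cylinder")),
            class = "Phantom")
}

#' Hemisphere phantom (shoot-apex analog)
#'
#' The upper cap of a sphere of radius `radius_um`, seen from above: a polar
#' lattice with one apex cell (polar angle 0 to the first ring boundary) and
#' `n_rings` rings of `n_sectors` cells each, out to polar angle
#' `max_polar_deg`.  Walls are rasterized along ring circles and sector
#' radii in the projection, placed at the local surface depth.  Cell "files"
#' are the rings; each ring's angle is the polar angle of its mid-latitude,
#' which is the tilt of the tangent plane there.
#'
#' @param radius_um sphere radius in micrometers.
#' @param n_rings number of cell rings outside the apex cell.
#' @param n_sectors cells per ring.
#' @param max_polar_deg outer polar angle of the lattice (< 80 degrees).
#' @inheritParams make_flat_sheet
#' @return A `Phantom` (list with `grid` and `truth`).
#' @export
make_hemisphere <- function(radius_um = 30, n_rings = 3, n_sectors = 8,
                            max_polar_deg = 60, wall_intensity = 200,
                            surface_slice = 2, wall_thickness_px = 2,
                            wall_depth_slices = 8, pixel_size_um = 0.363,
                            z_step_um = 0.5) {
  if (n_rings < 1 || n_sectors < 2)
    abort_parameter("need n_rings >= 1 and n_sectors >= 2")
  if (max_polar_deg <= 0 || max_polar_deg >= 80)
    abort_parameter("'max_polar_deg' must lie in (0, 80)")
  R <- radius_um
  thmax <- max_polar_deg * pi / 180
  thb <- seq(0, thmax, length.out = n_rings + 2L)  # apex cell + n_rings rings
  rho_b <- R * sin(thb)                            # projected ring radii (um)

  half_t_um <- wall_thickness_px * pixel_size_um / 2
  ext_px <- as.integer(ceiling(2 * (rho_b[n_rings + 2L] + half_t_um) /
                                 pixel_size_um)) + 3L
  ny <- nx <- ext_px
  ctr <- (ext_px + 1) / 2  # center pixel (fractional)

  xi <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yi <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  xu <- (xi - ctr) * pixel_size_um; yu <- (yi - ctr) * pixel_size_um
  rho <- sqrt(xu^2 + yu^2)
  psi <- atan2(yu, xu) %% (2 * pi)

  inside <- rho <= rho_b[n_rings + 2L] + half_t_um
  wall2d <- matrix(FALSE, ny, nx)
  for (i in 2:(n_rings + 2L))
    wall2d <- wall2d | (abs(rho - rho_b[i]) <= half_t_um)
  psib <- seq(0, 2 * pi, length.out = n_sectors + 1L)[-(n_sectors + 1L)]
  for (p in psib) {
    dpsi <- abs(((psi - p + pi) %% (2 * pi)) - pi)
    wall2d <- wall2d | (rho > rho_b[2] - half_t_um & inside &
                          rho * dpsi <= half_t_um)
  }
  wall2d <- wall2d & inside

  labels <- matrix(0L, ny, nx)
  apex_sel <- !wall2d & rho < rho_b[2]
  labels[apex_sel] <- 1L
  for (i in seq_len(n_rings)) for (j in seq_len(n_sectors)) {
    p_lo <- psib[j]; p_hi <- p_lo + 2 * pi / n_sectors
    sel <- !wall2d & rho > rho_b[i + 1L] & rho < rho_b[i + 2L] &
      psi >= p_lo & psi < p_hi
    labels[sel] <- 1L + (i - 1L) * n_sectors + j
  }

  depth_um_at <- function(r) R - sqrt(pmax(R^2 - r^2, 0))
  depth_sl <- matrix(0L, ny, nx)
  depth_sl[] <- as.integer(round_half_up(depth_um_at(rho) / z_step_um))
  nz <- surface_slice + max(depth_sl[wall2d]) + wall_depth_slices + 1L

  data <- array(0, dim = c(nz, ny, nx))
  widx <- which(wall2d)
  for (i in widx) {
    y <- ((i - 1L) %% ny) + 1L; x <- ((i - 1L) %/% ny) + 1L
    zs <- surface_slice + depth_sl[y, x] + seq_len(wall_depth_slices) - 1L
    data[zs, y, x] <- wall_intensity
  }
  height <- matrix(NA_integer_, ny, nx)
  height[wall2d] <- surface_slice + depth_sl[wall2d]

  # truth: numerical surface integral per labeled cell
  ids <- sort(unique(labels[labels > 0L]))
  grad_sphere <- function(xg, yg) {
    r2 <- xg^2 + yg^2
    den <- sqrt(pmax(R^2 - r2, 1e-9))
    list(gx = -xg / den, gy = -yg / den)  # height = -depth
  }
  cells <- do.call(rbind, lapply(ids, function(id) {
    sel <- which(labels == id)
    ysel <- ((sel - 1L) %% ny) + 1L; xsel <- ((sel - 1L) %/% ny) + 1L
    sub <- c(-0.25, 0.25)
    tot <- 0
    for (s1 in sub) for (s2 in sub) {
      xg <- (xsel - ctr + s1) * pixel_size_um
      yg <- (ysel - ctr + s2) * pixel_size_um
      g <- grad_sphere(xg, yg)
      tot <- tot + sum(sqrt(1 + g$gx^2 + g$gy^2)) / 4
    }
    ring <- if (id == 1L) 0L else (id - 2L) %/% n_sectors + 1L
    # cell-center tilt: the apex cell is centered on the pole (angle 0),
    # ring cells at their mid-latitude
    th_mid <- if (ring == 0L) 0 else (thb[ring + 1L] + thb[ring + 2L]) / 2
    data.frame(cell_id = id, file_id = ring,
               true_area_um2 = tot * pixel_size_um^2,
               projected_area_um2 = length(sel) * pixel_size_um^2,
               angle_deg = th_mid * 180 / pi)
  }))
  ring_mid <- c(0, (thb[2:(n_rings + 1L)] + thb[3:(n_rings + 2L)]) / 2)
  file_angle <- stats::setNames(ring_mid * 180 / pi, 0:n_rings)

  grid <- voxel_grid(data, pixel_size_um, z_step_um, 8L)
  structure(list(grid = grid,
                 truth = phantom_truth(height, wall2d, labels, cells,
                                       file_angle, pixel_size_um, z_step_um,
                                       "hemisphere")),
            class = "Phantom")
}

#' Add seeded noise to a stack
#'
#' Adds zero-mean Gaussian read noise and/or salt impulses (voxels forced to
#' the bit-depth maximum), reproducibly for a fixed seed.  The caller's RNG
#' state is left untouched.  Intensities are rounded and clipped to the bit
#' depth.
#'
#' @param grid a [voxel_grid()].
#' @param gaussian_sd standard deviation of additive Gaussian noise, in gray
#'   levels.
#' @param salt_prob per-voxel probability of a saturated impulse.
#' @param seed integer seed (required).
#' @return A [voxel_grid()] of the same shape and bit depth.
#' @export
add_noise <- function(grid, gaussian_sd = 0, salt_prob = 0, seed) {
  stopifnot(is_voxel_grid(grid))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_parameter("'seed' is required for reproducible noise")
  if (gaussian_sd < 0 || salt_prob < 0 || salt_prob > 1)
    abort_parameter("need gaussian_sd >= 0 and salt_prob in [0, 1]")
  if (gaussian_sd == 0 && salt_prob == 0) return(grid)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  maxv <- 2^grid$bit_depth - 1
  v <- grid$data
  n <- length(v)
  if (gaussian_sd > 0) v <- v + stats::rnorm(n, 0, gaussian_sd)
  if (salt_prob > 0) v[stats::runif(n) < salt_prob] <- maxv
  v <- pmin(pmax(round_half_up(v), 0), maxv)
  voxel_grid(array(v, dim = dim(grid$data)), grid$pixel_size_um,
             grid$z_step_um, grid$bit_depth)
}

#' Save a phantom to disk
#'
#' Writes the stack as a multi-page TIFF and the truth's per-cell table as a
#' CSV sidecar (`<stem>_truth.csv`), so command-line end-to-end runs can work
#' from files.
#'
#' @param phantom a `Phantom` from one of the `make_*` generators.
#' @param path output TIFF path.
#' @return Paths of the files written, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "Phantom"))
  write_stack(phantom$grid, path)
  truth_path <- paste0(tools::file_path_sans_ext(path), "_truth.csv")
  utils::write.csv(phantom$truth$cells, truth_path, row.names = FALSE)
  invisible(c(stack = path, truth = truth_path))
}
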