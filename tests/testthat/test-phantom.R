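test_that("flat-sheet truth follows from lattice geometry", {
  ph <- make_flat_sheet(2, 2, cell_size_px = 20, pixel_size_um = 1,
                        surface_slice = 3, wall_depth_slices = 4)
  tr <- ph$truth
  expect_equal(nrow(tr$cells), 4L)
  expect_equal(tr$cells$true_area_um2, rep(400, 4))  # 20x20 px at 1 um/px
  expect_equal(sort(unique(as.vector(tr$cell_labels_2d))), 0:4)
  # walls start at the surface slice everywhere
  expect_true(all(tr$surface_height_px[tr$wall_mask_2d] == 3L))
  expect_true(all(is.na(tr$surface_height_px[!tr$wall_mask_2d])))
  # each labeled cell is enclosed by walls: dilating any cell by one pixel
  # only ever meets that cell or wall pixels
  lab <- tr$cell_labels_2d
  for (id in 1:4) {
    sel <- which(lab == id, arr.ind = TRUE)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- cbind(sel[, 1] + d[1], sel[, 2] + d[2])
      vals <- lab[nb]
      expect_true(all(vals %in% c(0L, id)))
    }
  }
  # degenerate wall intensity is rejected downstream by to_8bit
  ph0 <- make_flat_sheet(2, 2, cell_size_px = 8, wall_intensity = 0)
  expect_error(surfcut(voxel_grid(ph0$grid$data, 1, 1, 16L), default_params()),
               class = "surfcutr_degenerate_error")
})

test_that("tilted-plane truth encodes the 1/cos(angle) area inflation", {
  flat <- make_flat_sheet(2, 2, cell_size_px = 12)
  t0 <- make_tilted_plane(0, 2, 2, cell_size_px = 12)
  expect_equal(t0$truth$cells, flat$truth$cells)
  expect_identical(t0$truth$cell_labels_2d, flat$truth$cell_labels_2d)

  t60 <- make_tilted_plane(60, 2, 2, cell_size_px = 12)
  expect_equal(t60$truth$cells$true_area_um2,
               2 * t60$truth$cells$projected_area_um2, tolerance = 1e-9)

  # rasterized height slope tracks tan(30 deg) within one pixel per column
  t30 <- make_tilted_plane(30, 2, 2, cell_size_px = 12,
                           pixel_size_um = 0.5, z_step_um = 0.5)
  h <- t30$truth$surface_height_px
  wallrow <- which(t30$truth$wall_mask_2d[, 1])[1]
  hx <- h[wallrow, ]
  xs <- which(!is.na(hx))
  pred <- (xs - 1) * 0.5 * tan(30 * pi / 180) / 0.5
  expect_true(all(abs((hx[xs] - hx[xs][1]) - pred) <= 1))

  expect_error(make_tilted_plane(85), class = "surfcutr_parameter_error")
})

test_that("cylinder truth matches closed-form arc geometry and chord angles", {
  cyl <- make_cylinder(radius_um = 30, n_files = 4, bumpiness = 0,
                       n_cells_axial = 2, axial_cell_px = 20,
                       half_span_deg = 60)
  tr <- cyl$truth
  # boundaries at -60,-30,0,30,60 degrees: outermost file chord ~ 45 deg
  expect_equal(cell_file_angle(tr, 4), 45, tolerance = 1.5)
  expect_equal(cell_file_angle(tr, 1), 45, tolerance = 1.5)
  expect_lt(abs(cell_file_angle(tr, 2) - 15), 1.5)
  expect_error(cell_file_angle(tr, 99), class = "surfcutr_parameter_error")

  # a file straddling the apex has a near-zero chord angle
  cyl2 <- make_cylinder(radius_um = 30, n_files = 3, half_span_deg = 45)
  expect_lt(abs(cell_file_angle(cyl2$truth, 2)), 2)

  # bumpiness 0: true area equals arc length x axial interior length
  R <- 30; px <- cyl$truth$pixel_size_um
  for (k in 1:4) {
    rows <- tr$cells[tr$cells$file_id == k, ]
    sel <- which(tr$cell_labels_2d == rows$cell_id[1], arr.ind = TRUE)
    x_lo <- (min(sel[, 2]) - 1) * px; x_hi <- max(sel[, 2]) * px
    xc <- -R * sin(-60 * pi / 180)
    arc <- R * (asin((x_hi - xc) / R) - asin((x_lo - xc) / R))
    axial <- 20 * px
    expect_equal(rows$true_area_um2[1], arc * axial, tolerance = 0.02)
  }

  expect_error(make_cylinder(n_files = 1), class = "surfcutr_parameter_error")
})

test_that("hemisphere truth respects spherical-cap geometry", {
  hs <- make_hemisphere(radius_um = 30, n_rings = 3, n_sectors = 8,
                        max_polar_deg = 60)
  tr <- hs$truth
  expect_equal(cell_file_angle(tr, 0), 0)            # apex faces the objective
  expect_lt(sum(tr$cells$true_area_um2), 2 * pi * 30^2)
  # percent difference from truth grows with polar angle ring by ring
  pd <- sapply(0:3, function(ring) {
    rows <- tr$cells[tr$cells$file_id == ring, ]
    mean((rows$true_area_um2 - rows$projected_area_um2) / rows$true_area_um2)
  })
  expect_true(all(diff(pd) > 0))
  # and tracks the spherical closed form 1 - (cos t1 + cos t2)/2 per ring
  thb <- seq(0, 60, length.out = 5) * pi / 180
  closed <- 1 - (cos(thb[2:4]) + cos(thb[3:5])) / 2
  expect_equal(pd[2:4], closed, tolerance = 0.15)
})

test_that("phantom stacks are consistent with their own height-field truth", {
  phs <- list(make_flat_sheet(2, 2, cell_size_px = 10),
              make_tilted_plane(30, 2, 2, cell_size_px = 10),
              make_cylinder(radius_um = 20, n_files = 3, axial_cell_px = 12))
  for (ph in phs) {
    bin <- binarize(ph$grid, 100)
    h <- ph$truth$surface_height_px
    d <- dim(bin$data)
    first <- matrix(NA_integer_, d[2], d[3])
    for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      s <- which(bin$data[, y, x])[1]
      if (!is.na(s)) first[y, x] <- s
    }
    expect_identical(first, h)
  }
})

test_that("seeded noise is reproducible, clipped, and binomially calibrated", {
  ph <- make_flat_sheet(3, 3, cell_size_px = 18)
  g <- ph$grid
  expect_identical(add_noise(g, 0, 0, seed = 1), g)
  n1 <- add_noise(g, 10, 0.01, seed = 7)
  n2 <- add_noise(g, 10, 0.01, seed = 7)
  expect_identical(n1$data, n2$data)
  expect_false(identical(n1$data, add_noise(g, 10, 0.01, seed = 8)$data))
  expect_true(all(n1$data >= 0 & n1$data <= 255))
  expect_error(add_noise(g, 1, 0), class = "surfcutr_parameter_error")

  # salt_prob 0.01 on ~1e5 zero voxels flips 1000 +/- 100 to the maximum
  nvox <- 100000
  z <- voxel_grid(array(0, dim = c(10, 100, 100)), 1, 1, 8L)
  s <- add_noise(z, 0, 0.01, seed = 123)
  flipped <- sum(s$data == 255)
  expect_gt(flipped, 900); expect_lt(flipped, 1100)

  # the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(add_noise(g, 5, 0, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("per-cell true areas track lattice scaling as f^2 (rasterization 2%)", {
  a1 <- make_cylinder(radius_um = 30, n_files = 3, axial_cell_px = 12,
                      half_span_deg = 45)$truth$cells
  a2 <- make_cylinder(radius_um = 60, n_files = 3, axial_cell_px = 12,
                      half_span_deg = 45, pixel_size_um = 0.726)$truth$cells
  # doubling radius and pixel size doubles both arc and axial extent
  expect_equal(a2$true_area_um2 / a1$true_area_um2,
               rep(4, nrow(a1)), tolerance = 0.05)
})
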