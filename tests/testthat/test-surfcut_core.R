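test_that("to_8bit maps the stack range linearly onto [0, 255]", {
  mk16 <- function(vals) voxel_grid(array(vals, dim = c(2, 2, 2)), 1, 1, 16L)
  g <- mk16(c(0, 65535, 0, 0, 65535, 0, 0, 65535))
  out <- to_8bit(g)
  expect_identical(out$bit_depth, 8L)
  expect_setequal(unique(as.vector(out$data)), c(0, 255))

  g8 <- voxel_grid(array(c(3, 7, 250, 0, 1, 2, 3, 4), dim = c(2, 2, 2)), 1, 1, 8L)
  expect_identical(to_8bit(g8), g8)

  expect_error(to_8bit(mk16(rep(100, 8))), class = "surfcutr_degenerate_error")

  # midpoint rounds half up: {0, 30} -> midpoint 15 maps to 127.5 -> 128
  g2 <- mk16(c(0, 30, 15, 0, 30, 15, 0, 30))
  expect_equal(sort(unique(as.vector(to_8bit(g2)$data))), c(0, 128, 255))
})

test_that("per-slice Gaussian blur preserves mass and fixes constants", {
  # identity at radius 0
  g <- rand_grid(4)
  expect_identical(gaussian_denoise(g, 0), g)
  expect_error(gaussian_denoise(g, -1), class = "surfcutr_parameter_error")

  # single bright voxel: kernel mass conservation within 0.5%
  a <- array(0, dim = c(2, 21, 21)); a[1, 11, 11] <- 60000
  g1 <- voxel_grid(a, 1, 1, 16L)
  b <- gaussian_denoise(g1, 1)
  expect_lt(abs(sum(b$data[1, , ]) - 60000) / 60000, 0.005)
  expect_equal(sum(b$data[2, , ]), 0)  # slices are independent

  # peak matches a direct 2D kernel oracle
  r <- ceiling(3.5 * 1); k1 <- dnorm(-r:r, sd = 1); k1 <- k1 / sum(k1)
  expect_equal(b$data[1, 11, 11], round(max(k1)^2 * 60000), tolerance = 1)

  # constant slices are fixed points
  gc <- voxel_grid(array(77, dim = c(2, 9, 9)), 1, 1, 8L)
  expect_equal(gaussian_denoise(gc, 2)$data, gc$data)
})

test_that("binarize thresholds at >= with 8-bit bounds enforced", {
  a <- array(0, dim = c(2, 2, 2))
  a[1, , ] <- c(5, 100, 200, 3)
  g <- voxel_grid(a, 1, 1, 8L)
  b <- binarize(g, 100)
  expect_identical(b$data[1, , ], matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_true(all(binarize(g, 0)$data))
  expect_false(any(binarize(g, 255)$data))  # max is 200
  expect_error(binarize(g, 256), class = "surfcutr_parameter_error")
  g16 <- voxel_grid(array(0:7, dim = c(2, 2, 2)), 1, 1, 16L)
  expect_error(binarize(g16, 10), class = "surfcutr_parameter_error")
})

test_that("edge_fill equals the cumulative-OR oracle and is monotone/idempotent", {
  # hand example: two slices
  b <- array(FALSE, dim = c(2, 2, 2))
  b[1, 1, 2] <- TRUE; b[2, 2, 1] <- TRUE
  m <- edge_fill(binary_stack3(b))
  expect_identical(m$data[1, , ], b[1, , ])
  expect_identical(m$data[2, , ], matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))

  expect_false(any(edge_fill(binary_stack3(array(FALSE, c(3, 4, 4))))$data))

  for (seed in 1:5) {
    set.seed(seed)
    bin <- array(runif(6 * 8 * 8) < 0.15, dim = c(6, 8, 8))
    m <- edge_fill(binary_stack3(bin))
    expect_identical(m$data, oracle_edge_fill(bin))
    # monotone with depth
    for (z in 2:6) expect_true(all(m$data[z, , ] >= m$data[z - 1, , ]))
    # idempotent
    expect_identical(edge_fill(m)$data, m$data)
  }
})

test_that("depth_to_slices rounds to the nearest slice, ties away from zero", {
  expect_identical(depth_to_slices(6, 0.5), 12L)
  expect_identical(depth_to_slices(8, 0.5), 16L)
  expect_identical(depth_to_slices(0, 0.25), 0L)
  expect_identical(depth_to_slices(1.3, 0.5), 3L)   # 2.6 -> 3
  expect_identical(depth_to_slices(1.25, 0.5), 3L)  # tie 2.5 -> 3
  expect_error(depth_to_slices(1, 0), class = "surfcutr_parameter_error")
})

test_that("shifted-mask cropping keeps exactly the per-column depth window", {
  # flat surface at slice 3, window [0, 1): only slice 3 survives
  ph <- make_flat_sheet(2, 2, cell_size_px = 6, surface_slice = 3,
                        wall_depth_slices = 5)
  g <- ph$grid
  mask <- edge_fill(binarize(g, 100))
  out <- crop_by_shifted_mask(g, mask, 0L, 1L)
  expect_identical(out$data[3, , ], g$data[3, , ])
  expect_true(all(out$data[-3, , ] == 0))

  # top=1, bottom=3 with first signal at slice 1: slices 2 and 3 kept
  a <- array(0, dim = c(5, 3, 3)); a[, 2, 2] <- 50
  g2 <- voxel_grid(a, 1, 1, 8L)
  m2 <- edge_fill(binarize(g2, 10))
  out2 <- crop_by_shifted_mask(g2, m2, 1L, 3L)
  expect_equal(out2$data[, 2, 2], c(0, 50, 50, 0, 0))

  # staircase phantom: per-column window matches the first-signal oracle
  set.seed(42)
  d <- c(8, 6, 6)
  a3 <- array(0, dim = d)
  for (y in 1:6) for (x in 1:6) {
    s <- sample(1:5, 1)
    a3[s:min(8, s + 2), y, x] <- sample(120:255, 1)
  }
  g3 <- voxel_grid(a3, 1, 1, 8L)
  m3 <- edge_fill(binarize(g3, 100))
  out3 <- crop_by_shifted_mask(g3, m3, 1L, 3L)
  for (y in 1:6) for (x in 1:6) {
    col <- a3[, y, x]
    s <- which(col >= 100)[1]
    keep <- rep(FALSE, 8)
    if (!is.na(s)) keep[pmin(pmax(seq.int(s + 1, s + 2), 1), 8)] <- TRUE
    expect_equal(out3$data[, y, x], ifelse(keep, col, 0))
  }

  expect_error(crop_by_shifted_mask(g3, m3, 10L, 12L),
               class = "surfcutr_parameter_error")
})

test_that("crop windows OR-decompose: [a,c) is the disjoint union of [a,b), [b,c)", {
  g <- rand_grid(7, dims = c(8, 10, 10), density = 0.3)
  m <- edge_fill(binarize(g, 100))
  for (abc in list(c(0, 1, 3), c(0, 2, 4), c(1, 3, 5))) {
    a <- abc[1]; b <- abc[2]; cc <- abc[3]
    kab <- crop_by_shifted_mask(g, m, a, b)$data > 0
    kbc <- crop_by_shifted_mask(g, m, b, cc)$data > 0
    kac <- crop_by_shifted_mask(g, m, a, cc)$data > 0
    expect_false(any(kab & kbc))
    expect_identical(kac, kab | kbc)
  }
})

test_that("max_project takes the column-wise maximum", {
  a <- array(0, dim = c(3, 2, 2)); a[, 1, 1] <- c(1, 7, 3)
  g <- voxel_grid(a, 1, 1, 8L)
  img <- max_project(g)
  expect_equal(img[1, 1], 7)
  expect_true(all(max_project(voxel_grid(array(0, c(2, 3, 3)), 1, 1, 8L)) == 0))
  g2 <- rand_grid(9)
  img2 <- max_project(g2)
  for (y in 1:8) for (x in 1:8)
    expect_equal(img2[y, x], max(g2$data[, y, x]))
})

test_that("surfcut crops the original stack, not the blurred one", {
  # blur shifts intensities; output values must come from the raw 8-bit stack
  ph <- make_flat_sheet(2, 2, cell_size_px = 10)
  res <- surfcut(ph$grid, surfcut_params(1.5, 60, 0, 2))
  kept <- res$cropped$data[res$cropped$data > 0]
  expect_true(all(kept %in% unique(as.vector(ph$grid$data))))
  expect_true(max(res$contour) <= max(ph$grid$data))
})

test_that("surfcut flags an empty mask and a below-walls window", {
  ph <- make_flat_sheet(2, 2, cell_size_px = 8, wall_depth_slices = 3,
                        surface_slice = 2, n_slices = 14)
  expect_error(surfcut(ph$grid, surfcut_params(0, 255, 0, 2)),
               class = "surfcutr_extraction_error", regexp = "threshold")
  # window entirely below the anticlinal walls -> all-zero projection
  res <- surfcut(ph$grid, surfcut_params(0, 100, 4, 6))
  expect_true(all(res$contour == 0))
})
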