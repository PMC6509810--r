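# Cell segmentation from a 2D contour image and the descriptor subset used
# to compare extraction methods: area, perimeter, circularity, solidity,
# plus the standard small-cell (guard-cell) filter.

#' Segment cells from a contour image
#'
#' Pixels at or above `wall_threshold` are walls; the remaining pixels are
#' partitioned into 4-connected components, each of which becomes one cell
#' label.  4-connectivity for cells (with walls implicitly 8-connected)
#' prevents diagonal leaks through one-pixel walls.  Components touching the
#' image border — incomplete cells cut by the field of view, or the region
#' outside the sample — are labeled but flagged, and are dropped by default
#' downstream ([compute_descriptors()]).
#'
#' @param img a [contour_image()] or 8-bit numeric matrix `[y, x]`.
#' @param wall_threshold integer in `[0, 255]`; wall iff intensity at or
#'   above it.
#' @return An object of class `CellLabelMap`: list with `labels` (integer
#'   matrix, 0 = wall), `pixel_size_um`, and `touches_border` (logical,
#'   named by label).
#' @export
segment_cells <- function(img, wall_threshold) {
  m <- unclass(img)
  if (!is.matrix(m)) abort_parameter("'img' must be a 2D image matrix")
  if (!is.numeric(wall_threshold) || wall_threshold < 0 || wall_threshold > 255)
    abort_parameter("'wall_threshold' must be an integer in [0, 255]")
  wall <- m >= wall_threshold
  if (!any(wall))
    abort_segmentation(sprintf(
      "no wall pixel at or above threshold %d (image max %g); nothing to segment",
      wall_threshold, max(m)))
  labels <- label_components4(!wall)
  ids <- seq_len(max(labels))
  border <- c(labels[1, ], labels[nrow(labels), ],
              labels[, 1], labels[, ncol(labels)])
  touches <- stats::setNames(ids %in% border, ids)
  structure(list(labels = labels,
                 pixel_size_um = attr(img, "pixel_size_um") %||% NA_real_,
                 touches_border = touches),
            class = "CellLabelMap")
}

# 4-connected component labeling by iterative min-label propagation over the
# whole image (vectorized shifts; converges in O(max geodesic diameter)).
label_components4 <- function(fg) {
  ny <- nrow(fg); nx <- ncol(fg)
  lab <- matrix(0, ny, nx)
  lab[fg] <- seq_len(sum(fg))
  big <- sum(fg) + 1
  repeat {
    cur <- lab
    w <- ifelse(fg, lab, big)
    # shift neighbors in: up, down, left, right
    up <- rbind(w[-1, , drop = FALSE], big); dn <- rbind(big, w[-ny, , drop = FALSE])
    lf <- cbind(w[, -1, drop = FALSE], big); rt <- cbind(big, w[, -nx, drop = FALSE])
    best <- pmin(w, up, dn, lf, rt)
    lab[fg] <- best[fg]
    if (identical(cur, lab)) break
  }
  # compact to 1..K in order of first appearance (column-major scan)
  ids <- unique(lab[lab > 0])
  lab[lab > 0] <- match(lab[lab > 0], ids)
  storage.mode(lab) <- "integer"
  lab
}

#' Remove small cells from a label map
#'
#' Labels whose pixel count falls below `min_area_px` are set to 0; surviving
#' labels keep their numbers.  The default of 2500 pixels is the standard
#' guard-cell exclusion threshold for pavement-cell segmentations at typical
#' confocal sampling; the comparison is strict (`< min_area_px` removed, a
#' cell of exactly `min_area_px` pixels survives).
#'
#' @param map a `CellLabelMap`.
#' @param min_area_px minimum pixel count to survive, `>= 0`.
#' @return A `CellLabelMap` with small labels zeroed.
#' @export
filter_small <- function(map, min_area_px = 2500L) {
  stopifnot(inherits(map, "CellLabelMap"))
  if (!is.numeric(min_area_px) || min_area_px < 0)
    abort_parameter("'min_area_px' must be >= 0")
  counts <- tabulate(map$labels[map$labels > 0L])
  kill <- which(counts < min_area_px)
  if (length(kill)) {
    map$labels[map$labels %in% kill] <- 0L
    map$touches_border <- map$touches_border[
      !names(map$touches_border) %in% as.character(kill)]
  }
  map
}

#' Circularity of a shape
#'
#' `4 * pi * area / perimeter^2`: exactly 1 for a circle (`A = pi r^2`,
#' `P = 2 pi r`), `pi / 4` for a square, smaller for lobed shapes.  Units
#' cancel, so area and perimeter may be given in pixels or micrometers as
#' long as they agree.
#'
#' @param area,perimeter positive numerics.
#' @return Dimensionless circularity.
#' @examples
#' r <- 3.7
#' circularity(pi * r^2, 2 * pi * r)  # exactly 1
#' @export
circularity <- function(area, perimeter) 4 * pi * area / perimeter^2

#' Shape descriptors per segmented cell
#'
#' For every surviving label: area (pixel count, converted to um^2),
#' perimeter (8-connected boundary trace through pixel centers, diagonal
#' steps weighted `sqrt(2)`, converted to um), circularity
#' (`4 pi A / P^2`, computed in pixel units), and solidity (pixel area over
#' the area of the convex hull of the pixel corners, so a digital rectangle
#' scores exactly 1).
#'
#' @param map a `CellLabelMap` with at least one nonzero label.
#' @param drop_border drop cells flagged as touching the image border
#'   (default `TRUE`, mirroring the usual incomplete-cell exclusion).
#' @return A data.frame with columns `cell_id`, `area_um2`, `perimeter_um`,
#'   `circularity`, `solidity`, `touches_border`.
#' @export
compute_descriptors <- function(map, drop_border = TRUE) {
  stopifnot(inherits(map, "CellLabelMap"))
  ids <- sort(unique(map$labels[map$labels > 0L]))
  if (drop_border) ids <- ids[!map$touches_border[as.character(ids)]]
  if (!length(ids))
    abort_segmentation("label map has no (non-border) cells to measure")
  px <- map$pixel_size_um
  if (is.na(px)) px <- 1
  rows <- lapply(ids, function(id) {
    sel <- map$labels == id
    area_px <- sum(sel)
    per_px <- trace_perimeter(sel)
    data.frame(cell_id = id,
               area_um2 = area_px * px^2,
               perimeter_um = per_px * px,
               circularity = circularity(area_px, per_px),
               solidity = min(1, area_px / corner_hull_area(sel)),
               touches_border = unname(map$touches_border[as.character(id)]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Moore-neighbor boundary trace through pixel centers; returns path length
# with axial steps of 1 and diagonal steps of sqrt(2). Degenerate shapes
# (single pixel) get the unit-square crack perimeter of 4.
trace_perimeter <- function(mask) {
  if (sum(mask) == 1L) return(4)
  ny <- nrow(mask); nx <- ncol(mask)
  at <- function(y, x) y >= 1L && y <= ny && x >= 1L && x <= nx && mask[y, x]
  # start: leftmost pixel of the topmost occupied row
  ys <- which(rowSums(mask) > 0)[1]
  xs <- which(mask[ys, ])[1]
  # clockwise Moore neighborhood starting north, (dy, dx)
  dirs <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                   1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                 ncol = 2L, byrow = TRUE)
  # entry direction index: neighbor from which we search first; start as if
  # we came from the west (background by construction of the start pixel)
  cy <- ys; cx <- xs; came <- 7L  # index of W in dirs (background at start)
  per <- 0
  for (step in seq_len(8L * ny * nx)) {
    found <- FALSE
    for (j in seq_len(8L)) {
      k <- ((came + j - 1L) %% 8L) + 1L  # scan clockwise from just past backtrack
      yn <- cy + dirs[k, 1L]; xn <- cx + dirs[k, 2L]
      if (at(yn, xn)) {
        per <- per + if (dirs[k, 1L] != 0L && dirs[k, 2L] != 0L) sqrt(2) else 1
        came <- ((k + 3L) %% 8L) + 1L  # backtrack = opposite(k)
        cy <- yn; cx <- xn
        found <- TRUE
        break
      }
    }
    if (!found) return(4)  # isolated pixel among scattered others
    if (cy == ys && cx == xs) break  # closed the outer contour
  }
  per
}

# area of the convex hull of the corners of a pixel set (px^2); always >= the
# pixel count, with equality for axis-aligned digital rectangles
corner_hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  # corners of every pixel: (y +/- .5, x +/- .5); hull only needs extremes
  ys <- idx[, 1]; xs <- idx[, 2]
  pts <- rbind(cbind(ys - .5, xs - .5), cbind(ys - .5, xs + .5),
               cbind(ys + .5, xs - .5), cbind(ys + .5, xs + .5))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  poly <- pts[h, , drop = FALSE]
  n <- nrow(poly)
  if (n < 3L) return(sum(mask))
  x <- poly[, 2]; y <- poly[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Write shape records to CSV
#'
#' @param records data.frame from [compute_descriptors()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_shape_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
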