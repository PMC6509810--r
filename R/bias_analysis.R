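# Projection-bias study: how much does cell area measured on a flat 2D
# contour projection underestimate the true (on-surface, "2.5D") area on
# curved tissue? The 2.5D side of the comparison is the phantom's analytic
# truth; the 2D side is the extraction pipeline plus contour segmentation.

#' Percent difference between true and projected cell area
#'
#' `((area_true - area_2d) / area_true) * 100`.  Positive values mean the
#' on-surface (2.5D) area is larger than the projected 2D area, which is the
#' expected direction on curved tissue; negative values (2D over-estimates)
#' are permitted and reported as such.
#'
#' @param area_true true (on-surface) area; must be positive.
#' @param area_2d projected 2D area.
#' @return Percent difference, vectorized over inputs.
#' @examples
#' percent_difference(100, 90)  # 10
#' percent_difference(100, 50)  # 50, the 60-degree tilt case (cos 60 = 1/2)
#' @export
percent_difference <- function(area_true, area_2d) {
  if (!is.numeric(area_true) || any(is.na(area_true)) || any(area_true <= 0))
    abort_parameter("'area_true' must be positive")
  (area_true - area_2d) / area_true * 100
}

#' Angle of a cell file
#'
#' Returns the transverse tilt of the named cell file, in degrees from the
#' horizontal (0 = facing the objective), as recorded in the phantom truth:
#' the chord between the file's two outer wall junctions, averaged along the
#' file.
#'
#' @param truth a `PhantomTruth`.
#' @param file_id file identifier (matching `truth$file_angle_deg` names).
#' @return Angle in degrees.
#' @export
cell_file_angle <- function(truth, file_id) {
  stopifnot(inherits(truth, "PhantomTruth"))
  key <- as.character(file_id)
  if (!key %in% names(truth$file_angle_deg))
    abort_parameter(sprintf("unknown cell file '%s' (known: %s)", key,
                            paste(names(truth$file_angle_deg), collapse = ", ")))
  unname(truth$file_angle_deg[key])
}

#' Run the projection-bias study on a phantom
#'
#' Runs the extraction pipeline on the phantom stack, segments cells from the
#' contour image, matches every segmented cell to a truth cell by maximal
#' pixel overlap (requiring at least `min_overlap` of the truth cell's
#' pixels), and reports per cell: the 2D projected area, the true on-surface
#' area, their percent difference, and the cell-file angle.  The per-cell
#' (angle, percent difference) pairs are the study's scatter data; a per-file
#' summary is attached as attribute `"files"`.
#'
#' @param phantom a `Phantom` (list with `grid` and `truth`).
#' @param params a [surfcut_params()].
#' @param wall_threshold threshold for contour segmentation; defaults to
#'   `params$threshold`.
#' @param min_overlap minimum fraction of a truth cell's pixels that its
#'   matched segment must cover (default 0.5).
#' @return A data.frame of class `BiasReport` with columns `cell_id`,
#'   `file_id`, `cell_file_angle_deg`, `area_2d_um2`, `area_true_um2`,
#'   `percent_difference`.  Unmatched truth cells are reported with `NA`
#'   areas, never silently dropped.
#' @export
run_bias_study <- function(phantom, params, wall_threshold = NULL,
                           min_overlap = 0.5) {
  stopifnot(inherits(phantom, "Phantom"), inherits(params, "SurfCutParams"))
  truth <- phantom$truth
  res <- surfcut(phantom$grid, params)
  seg <- segment_cells(res$contour, wall_threshold %||% params$threshold)
  px2 <- truth$pixel_size_um^2

  tl <- truth$cell_labels_2d; sl <- seg$labels
  ids <- sort(unique(tl[tl > 0L]))
  match_rows <- lapply(ids, function(id) {
    sel <- tl == id
    n_truth <- sum(sel)
    seg_ids <- sl[sel]
    seg_ids <- seg_ids[seg_ids > 0L]
    if (!length(seg_ids))
      return(data.frame(cell_id = id, seg_id = NA_integer_, overlap = 0,
                        area_2d_um2 = NA_real_))
    tab <- tabulate(seg_ids)
    best <- which.max(tab)
    ov <- tab[best] / n_truth
    if (ov < min_overlap)
      return(data.frame(cell_id = id, seg_id = NA_integer_, overlap = ov,
                        area_2d_um2 = NA_real_))
    data.frame(cell_id = id, seg_id = best, overlap = ov,
               area_2d_um2 = sum(sl == best) * px2)
  })
  m <- do.call(rbind, match_rows)
  n_matched <- sum(!is.na(m$seg_id))
  if (n_matched < length(ids) / 2)
    abort_matching(sprintf(
      "only %d of %d truth cells matched at >= %.0f%% overlap (overlaps: %s)",
      n_matched, length(ids), 100 * min_overlap,
      paste(sprintf("%d:%.2f", m$cell_id, m$overlap), collapse = " ")))

  cells <- truth$cells
  report <- data.frame(
    cell_id = m$cell_id,
    file_id = cells$file_id[match(m$cell_id, cells$cell_id)],
    cell_file_angle_deg = cells$angle_deg[match(m$cell_id, cells$cell_id)],
    area_2d_um2 = m$area_2d_um2,
    area_true_um2 = cells$true_area_um2[match(m$cell_id, cells$cell_id)])
  report$percent_difference <- ifelse(
    is.na(report$area_2d_um2), NA_real_,
    percent_difference(report$area_true_um2, report$area_2d_um2))

  ok <- !is.na(report$percent_difference)
  files <- stats::aggregate(
    report[ok, c("cell_file_angle_deg", "percent_difference")],
    by = list(file_id = report$file_id[ok]), FUN = mean)
  attr(report, "files") <- files
  attr(report, "n_unmatched") <- length(ids) - n_matched
  class(report) <- c("BiasReport", "data.frame")
  report
}

#' Write a bias report to CSV
#'
#' @param report a `BiasReport` from [run_bias_study()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bias_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Render a per-cell percent-difference heatmap
#'
#' Paints each truth cell with its percent difference on the phantom's label
#' image (gray ramp over the observed range; walls black, unmatched cells
#' white) and writes it as PNG — the phantom analog of the per-cell bias
#' heatmaps used to visualize projection error on curved organs.
#'
#' @param report a `BiasReport`.
#' @param truth the `PhantomTruth` the report was computed against.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_bias_heatmap <- function(report, truth, path) {
  stopifnot(inherits(report, "BiasReport"), inherits(truth, "PhantomTruth"))
  lab <- truth$cell_labels_2d
  img <- matrix(0, nrow(lab), ncol(lab))
  pd <- report$percent_difference
  rng <- range(pd, na.rm = TRUE)
  span <- if (diff(rng) > 0) diff(rng) else 1
  for (i in seq_len(nrow(report))) {
    v <- if (is.na(pd[i])) 1 else 0.15 + 0.7 * (pd[i] - rng[1]) / span
    img[lab == report$cell_id[i]] <- v
  }
  png::writePNG(img, target = path)
  invisible(path)
}
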