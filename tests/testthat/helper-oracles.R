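# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the implementation: plain triple loops over
# voxels, per-column first-signal search, direct kernel convolution.

# per-column first-signal/window oracle for the whole extraction chain
# (blur radius 0): find the first voxel >= threshold in each column, keep the
# half-open slice window [s + top, s + bottom), max-project.
oracle_contour <- function(grid8, threshold, top, bottom) {
  d <- dim(grid8$data)
  out <- matrix(0, d[2], d[3])
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    col <- grid8$data[, y, x]
    s <- which(col >= threshold)[1]
    if (!is.na(s)) {
      zs <- seq.int(s + top, s + bottom - 1L)
      zs <- zs[zs >= 1L & zs <= d[1]]
      if (length(zs)) out[y, x] <- max(col[zs])
    }
  }
  out
}

# "any signal at or above this depth" oracle for the cumulative fill
oracle_edge_fill <- function(bin) {
  d <- dim(bin)
  out <- array(FALSE, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    out[z, y, x] <- any(bin[seq_len(z), y, x])
  out
}

rand_grid <- function(seed, dims = c(6, 8, 8), bits = 8L, density = 0.2) {
  set.seed(seed)
  maxv <- 2^bits - 1
  v <- ifelse(stats::runif(prod(dims)) < density,
              sample(seq_len(maxv), prod(dims), replace = TRUE), 0)
  voxel_grid(array(v, dim = dims), 0.363, 0.5, bits)
}

# CellLabelMap built directly from a label matrix (bypasses segmentation)
label_map <- function(labels, pixel_size_um = 1) {
  ids <- sort(unique(labels[labels > 0]))
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 touches_border = stats::setNames(rep(FALSE, length(ids)),
                                                  ids)),
            class = "CellLabelMap")
}

disc_label_map <- function(r, pixel_size_um = 1) {
  n <- 2L * r + 5L
  xi <- matrix(rep(seq_len(n), each = n), n)
  yi <- t(xi)
  lab <- matrix(0L, n, n)
  lab[(xi - (n + 1) / 2)^2 + (yi - (n + 1) / 2)^2 <= r^2] <- 1L
  label_map(lab, pixel_size_um)
}

square_label_map <- function(s, pixel_size_um = 1) {
  lab <- matrix(0L, s + 4L, s + 4L)
  lab[2L + seq_len(s), 2L + seq_len(s)] <- 1L
  label_map(lab, pixel_size_um)
}

# fabricate a tiny RGB TIFF (3 samples/pixel) to exercise the format check
write_rgb_tiff <- function(path) {
  u16le <- surfcutr:::u16le; u32le <- surfcutr:::u32le
  tiff_entry <- surfcutr:::tiff_entry
  short_val <- function(x) c(u16le(x), u16le(0L))
  nx <- 4L; ny <- 4L
  pix <- as.raw(sample(0:255, nx * ny * 3L, replace = TRUE))
  entries <- list(
    tiff_entry(256L, 4L, 1L, u32le(nx)),
    tiff_entry(257L, 4L, 1L, u32le(ny)),
    # IFD spans bytes 8..133 (2 + 10*12 + 4); bits block at 134, pixels at 140
    tiff_entry(258L, 3L, 3L, u32le(134L)),
    tiff_entry(259L, 3L, 1L, short_val(1L)),
    tiff_entry(262L, 3L, 1L, short_val(2L)),               # RGB
    tiff_entry(273L, 4L, 1L, u32le(140L)),
    tiff_entry(277L, 3L, 1L, short_val(3L)),
    tiff_entry(278L, 4L, 1L, u32le(ny)),
    tiff_entry(279L, 4L, 1L, u32le(nx * ny * 3L)),
    tiff_entry(284L, 3L, 1L, short_val(1L)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw("II"), u16le(42L), u32le(8L)), con)
  writeBin(c(u16le(length(entries)), do.call(c, entries), u32le(0L)), con)
  writeBin(c(u16le(8L), u16le(8L), u16le(8L)), con)  # BitsPerSample block
  writeBin(pix, con)
  invisible(path)
}

default_params <- function() surfcut_params(0, 100, 0, 2)

binary_stack3 <- function(x) surfcutr:::binary_stack(x)
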