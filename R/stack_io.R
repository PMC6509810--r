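# Minimal TIFF support: uncompressed, single-channel, 8/16-bit, stripped,
# multi-page. No TIFF-capable package ships with this toolchain, so the
# subset of the format the pipeline needs is implemented here. Both byte
# orders are read; files are written little-endian with ImageJ-style
# metadata (resolution in pixels per micron, Z spacing in the description).

# ---- low-level byte helpers -------------------------------------------------

u16le <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

# TIFF type codes
TIFF_ASCII <- 2L; TIFF_SHORT <- 3L; TIFF_LONG <- 4L; TIFF_RATIONAL <- 5L

tiff_entry <- function(tag, type, count, value4) {
  c(u16le(tag), u16le(type), u32le(count), value4)
}

# ---- writer -----------------------------------------------------------------

# pages: list of [y, x] integer matrices; bits: 8 or 16.
# resolution_px_per_um / z_step_um may be NULL to omit metadata (used by tests
# to fabricate metadata-free files).
write_tiff_pages <- function(pages, path, bits,
                             resolution_px_per_um = NULL, z_step_um = NULL) {
  con <- tryCatch(file(path, "wb"), condition = function(e)
    abort_io(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  on.exit(close(con))

  npages <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  bps <- bits %/% 8L
  strip_bytes <- ny * nx * bps

  desc <- NULL
  if (!is.null(z_step_um)) {
    desc <- sprintf("ImageJ=1.53t\nimages=%d\nslices=%d\nspacing=%.8g\nunit=micron\n",
                    npages, npages, z_step_um)
    desc_raw <- c(charToRaw(desc), as.raw(0L))
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  } else desc_raw <- raw(0)

  has_res <- !is.null(resolution_px_per_um)
  # pixels per micron as an exact rational over 10^6
  if (has_res) res_raw <- c(u32le(1e6), u32le(round(1e6 / resolution_px_per_um)))

  n_entries <- 9L + has_res * 3L  # per-page baseline (desc adds 1 on page 1)
  # page 1 additionally carries the ImageDescription
  ifd_size <- function(ne) 2L + ne * 12L + 4L

  # layout: header | strips | description | rational | IFDs
  offset <- 8
  strip_offsets <- numeric(npages)
  for (i in seq_len(npages)) { strip_offsets[i] <- offset; offset <- offset + strip_bytes }
  desc_offset <- offset; offset <- offset + length(desc_raw)
  res_offset <- offset; if (has_res) offset <- offset + 8L
  ifd_offsets <- numeric(npages)
  for (i in seq_len(npages)) {
    ne <- n_entries + (i == 1L && !is.null(desc))
    ifd_offsets[i] <- offset
    offset <- offset + ifd_size(ne)
  }

  writeBin(c(charToRaw("II"), u16le(42L), u32le(ifd_offsets[1])), con)
  for (p in pages) {
    v <- as.vector(t(p))  # row-major
    if (bits == 8L) writeBin(as.raw(v), con)
    else writeBin(as.raw(rbind(v %% 256L, v %/% 256L)), con)  # little-endian u16
  }
  if (length(desc_raw)) writeBin(desc_raw, con)
  if (has_res) writeBin(res_raw, con)

  short_val <- function(x) c(u16le(x), u16le(0L))
  for (i in seq_len(npages)) {
    with_desc <- (i == 1L && !is.null(desc))
    entries <- list(
      tiff_entry(256L, TIFF_LONG, 1L, u32le(nx)),
      tiff_entry(257L, TIFF_LONG, 1L, u32le(ny)),
      tiff_entry(258L, TIFF_SHORT, 1L, short_val(bits)),
      tiff_entry(259L, TIFF_SHORT, 1L, short_val(1L)),
      tiff_entry(262L, TIFF_SHORT, 1L, short_val(1L)))
    if (with_desc)
      entries <- c(entries, list(
        tiff_entry(270L, TIFF_ASCII, nchar(desc, "bytes") + 1L,
                   u32le(desc_offset))))
    entries <- c(entries, list(
      tiff_entry(273L, TIFF_LONG, 1L, u32le(strip_offsets[i])),
      tiff_entry(277L, TIFF_SHORT, 1L, short_val(1L)),
      tiff_entry(278L, TIFF_LONG, 1L, u32le(ny)),
      tiff_entry(279L, TIFF_LONG, 1L, u32le(strip_bytes))))
    if (has_res)
      entries <- c(entries, list(
        tiff_entry(282L, TIFF_RATIONAL, 1L, u32le(res_offset)),
        tiff_entry(283L, TIFF_RATIONAL, 1L, u32le(res_offset)),
        tiff_entry(296L, TIFF_SHORT, 1L, short_val(1L))))
    next_ifd <- if (i < npages) ifd_offsets[i + 1] else 0
    writeBin(c(u16le(length(entries)), do.call(c, entries), u32le(next_ifd)), con)
  }
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

read_tiff_pages <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: '%s'", path))
  n <- file.size(path)
  if (is.na(n) || n < 8) abort_format(sprintf("'%s' is not a TIFF file", path))
  bytes <- readBin(path, "raw", n)

  order_mark <- rawToChar(bytes[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   abort_format(sprintf("'%s' is not a TIFF file (bad byte-order mark)", path)))
  rd <- function(off, size, count = 1L, signed = FALSE) {
    idx <- seq.int(off + 1L, length.out = size * count)
    if (idx[length(idx)] > n) abort_format("truncated TIFF")
    readBin(bytes[idx], "integer", n = count, size = size, signed = signed,
            endian = endian)
  }
  rd_u16 <- function(off, count = 1L) rd(off, 2L, count)
  rd_u32 <- function(off, count = 1L) {
    v <- rd(off, 4L, count, signed = TRUE)
    ifelse(v < 0, v + 4294967296, v)
  }
  if (rd_u16(2L) != 42L) abort_format(sprintf("'%s' is not a TIFF file (bad magic)", path))

  type_size <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL

  read_values <- function(type, count, entry_off) {
    nbytes <- type_size[type] * count
    off <- if (nbytes <= 4L) entry_off + 8L else rd_u32(entry_off + 8L)
    if (type == TIFF_ASCII) {
      v <- bytes[seq.int(off + 1L, length.out = count)]
      return(rawToChar(v[v != as.raw(0L)]))
    }
    if (type == TIFF_RATIONAL) {
      num <- rd_u32(off); den <- rd_u32(off + 4L)
      return(if (den == 0) NA_real_ else num / den)
    }
    if (type == TIFF_SHORT) return(rd_u16(off, count))
    if (type == TIFF_LONG) return(rd_u32(off, count))
    rd(off, 1L, count)
  }

  pages <- list(); meta <- list(xres = NA_real_, resunit = 1L, desc = NULL)
  ifd_off <- rd_u32(4L)
  while (ifd_off != 0) {
    ne <- rd_u16(ifd_off)
    tags <- list()
    for (j in seq_len(ne)) {
      eoff <- ifd_off + 2L + (j - 1L) * 12L
      tag <- rd_u16(eoff); type <- rd_u16(eoff + 2L); count <- rd_u32(eoff + 4L)
      if (type < 1L || type > 5L) next  # skip exotic types
      tags[[as.character(tag)]] <- read_values(type, count, eoff)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (!is.null(g(322L)))
      abort_format(sprintf("'%s': tiled TIFF not supported", path))
    if (g(259L, 1L) != 1L)
      abort_format(sprintf("'%s': compressed TIFF not supported (compression=%d)",
                           path, g(259L)))
    spp <- g(277L, 1L); photometric <- g(262L, 1L)
    if (spp != 1L || photometric > 1L)
      abort_format(sprintf(
        "'%s': only single-channel grayscale TIFF supported (samples/pixel=%d, photometric=%d)",
        path, spp, photometric))
    bits <- g(258L, 1L)
    if (!bits %in% c(8L, 16L))
      abort_format(sprintf("'%s': unsupported bit depth %d", path, bits))
    if (g(339L, 1L) != 1L)
      abort_format(sprintf("'%s': only unsigned-integer samples supported", path))
    nx <- g(256L); ny <- g(257L)
    if (is.null(nx) || is.null(ny)) abort_format(sprintf("'%s': missing image size", path))

    offs <- g(273L); cnts <- g(279L)
    if (is.null(offs)) abort_format(sprintf("'%s': missing strip offsets", path))
    if (is.null(cnts)) cnts <- rep(ny * nx * bits %/% 8L, length(offs))
    vals <- integer(0)
    for (k in seq_along(offs)) {
      nb <- cnts[k]
      if (bits == 8L) vals <- c(vals, rd(offs[k], 1L, nb))
      else vals <- c(vals, rd(offs[k], 2L, nb %/% 2L))
    }
    if (length(vals) < ny * nx) abort_format(sprintf("'%s': truncated pixel data", path))
    pages[[length(pages) + 1L]] <- matrix(vals[seq_len(ny * nx)],
                                          nrow = ny, ncol = nx, byrow = TRUE)
    if (is.na(meta$xres) && !is.null(g(282L))) meta$xres <- g(282L)
    meta$resunit <- g(296L, meta$resunit)
    if (is.null(meta$desc) && !is.null(g(270L))) meta$desc <- g(270L)
    attr(pages[[length(pages)]], "bits") <- bits
    ifd_off <- rd_u32(ifd_off + 2L + ne * 12L)
  }
  if (!length(pages)) abort_format(sprintf("'%s': no images in TIFF", path))
  list(pages = pages, meta = meta)
}

# pixel size in micrometers implied by the resolution tag, or NA
pixel_size_from_meta <- function(meta) {
  if (is.na(meta$xres) || meta$xres <= 0) return(NA_real_)
  switch(as.character(meta$resunit),
         "2" = 25400 / meta$xres,   # pixels per inch
         "3" = 10000 / meta$xres,   # pixels per cm
         1 / meta$xres)             # unit "none": ImageJ pixels per micron
}

z_step_from_meta <- function(meta) {
  if (is.null(meta$desc)) return(NA_real_)
  m <- regmatches(meta$desc, regexec("spacing=([0-9.eE+-]+)", meta$desc))[[1]]
  if (length(m) < 2L) return(NA_real_)
  as.numeric(m[2])
}

# ---- public API -------------------------------------------------------------

#' Read a Z-stack from a multi-page TIFF
#'
#' Reads an uncompressed single-channel grayscale multi-page TIFF (8- or
#' 16-bit) into a [voxel_grid()].  Page order maps to the z axis, with page 1
#' the top of the sample.  Voxel sizes are taken from the TIFF metadata
#' (resolution tag for the XY pixel size, ImageJ-style `spacing=` in the
#' image description for the Z-step) and may be overridden — explicit
#' arguments always win over metadata.
#'
#' @param path path to the TIFF file.
#' @param pixel_size_um,z_step_um optional voxel-size overrides in micrometers.
#' @return A [voxel_grid()].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, pixel_size_um = NULL, z_step_um = NULL) {
  tf <- read_tiff_pages(path)
  px <- if (!is.null(pixel_size_um)) pixel_size_um else pixel_size_from_meta(tf$meta)
  zs <- if (!is.null(z_step_um)) z_step_um else z_step_from_meta(tf$meta)
  if (is.na(px))
    abort_metadata(sprintf(
      "'%s' carries no pixel-size metadata; supply pixel_size_um", path))
  if (is.na(zs))
    abort_metadata(sprintf(
      "'%s' carries no Z-step metadata; supply z_step_um", path))
  bits <- attr(tf$pages[[1]], "bits")
  nz <- length(tf$pages); ny <- nrow(tf$pages[[1]]); nx <- ncol(tf$pages[[1]])
  data <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) data[z, , ] <- tf$pages[[z]]
  voxel_grid(data, px, zs, bits)
}

#' Write a Z-stack to a multi-page TIFF
#'
#' Writes a [voxel_grid()] as an uncompressed little-endian grayscale
#' multi-page TIFF, one page per slice, embedding the voxel sizes so that
#' [read_stack()] round-trips bit-exactly, metadata included.
#'
#' @param grid a [voxel_grid()].
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  if (!dir.exists(dirname(path)))
    abort_io(sprintf("directory '%s' does not exist", dirname(path)))
  nz <- dim(grid$data)[1]
  pages <- lapply(seq_len(nz), function(z) {
    m <- grid$data[z, , , drop = TRUE]
    storage.mode(m) <- "integer"
    m
  })
  write_tiff_pages(pages, path, grid$bit_depth,
                   resolution_px_per_um = 1 / grid$pixel_size_um,
                   z_step_um = grid$z_step_um)
}

#' Write a 2D image to TIFF or PNG
#'
#' Writes a [contour_image()] (or plain matrix) as a single-page grayscale
#' TIFF, or as PNG when the path ends in `.png`.  PNG output carries no
#' physical pixel size; record voxel sizes in a sidecar report if they matter
#' downstream.
#'
#' @param img a [contour_image()] or numeric matrix `[y, x]`.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @param bit_depth bit depth for plain-matrix input (taken from the
#'   `ContourImage` attribute when present).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = NULL) {
  if (!dir.exists(dirname(path)))
    abort_io(sprintf("directory '%s' does not exist", dirname(path)))
  bits <- bit_depth %||% attr(img, "bit_depth") %||% 8L
  m <- unclass(img); attributes(m) <- attributes(m)["dim"]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m / (2^bits - 1), target = path)
  } else {
    storage.mode(m) <- "integer"
    px <- attr(img, "pixel_size_um")
    write_tiff_pages(list(m), path, as.integer(bits),
                     resolution_px_per_um = if (!is.null(px)) 1 / px else NULL)
  }
  invisible(path)
}

#' Read a 2D image written by [write_image()]
#'
#' @param path path to a single-page grayscale TIFF or PNG.
#' @param pixel_size_um optional pixel size to attach (overrides metadata).
#' @return A [contour_image()].
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) abort_format(sprintf("'%s' is not grayscale", path))
    return(contour_image(round(m * 255), pixel_size_um %||% NA_real_, 8L))
  }
  tf <- read_tiff_pages(path)
  if (length(tf$pages) != 1L)
    abort_format(sprintf("'%s' has %d pages; expected a single 2D image",
                         path, length(tf$pages)))
  px <- pixel_size_um %||% pixel_size_from_meta(tf$meta)
  contour_image(tf$pages[[1]], px, attr(tf$pages[[1]], "bits"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
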