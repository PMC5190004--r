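# Minimal baseline TIFF codec.
#
# The analysis only needs uncompressed grayscale/multi-sample rasters with
# calibration metadata, so this codec supports exactly that subset of
# baseline TIFF 6.0:
#   write: little-endian, one strip per page, sample-interleaved
#          (PlanarConfiguration 1), 8/16-bit unsigned or 32-bit float,
#          multi-page (one page per z slice), JSON calibration block in
#          ImageDescription of the first page.
#   read:  II or MM byte order, uncompressed, PlanarConfiguration 1,
#          any strip layout, 8/16-bit unsigned or 32-bit float.
# Anything else (compression, tiles, palettes) raises an explicit error.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)  # BYTE..DOUBLE

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) {
  # values can exceed .Machine$integer.max (file offsets); encode manually
  x <- as.numeric(x)
  b <- as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  b
}

tiff_entry <- function(tag, type, count, value_raw4) {
  c(u16le(tag), u16le(type), u32le(count), value_raw4)
}

#' Write a pixel array as a multi-page baseline TIFF
#'
#' Pages correspond to z slices; samples within a page are interleaved
#' channels. The storage type is chosen automatically: 8- or 16-bit unsigned
#' when all values are non-negative integers in range, 32-bit float
#' otherwise. A JSON metadata block (pixel size, z step, channel roles,
#' source id) is embedded in the ImageDescription tag of the first page.
#'
#' @param pixels numeric array with dim (z, y, x, channel)
#' @param path output file path
#' @param description list serialized to JSON into ImageDescription, or NULL
#' @return `path`, invisibly
#' @keywords internal
write_tiff <- function(pixels, path, description = NULL) {
  d <- dim(pixels)
  if (length(d) != 4L) stopf("pixels must have dim (z, y, x, channel), got %s",
                             paste(d, collapse = "x"))
  nz <- d[1]; ny <- d[2]; nx <- d[3]; nc <- d[4]
  finite_ok <- all(is.finite(pixels))
  if (!finite_ok) stopf("pixels contain non-finite values")
  if (min(pixels) < 0) stopf("pixels must be non-negative")
  ints <- all(pixels == round(pixels))
  mx <- max(pixels)
  if (ints && mx <= 255) { bits <- 8L; fmt <- 1L }
  else if (ints && mx <= 65535) { bits <- 16L; fmt <- 1L }
  else { bits <- 32L; fmt <- 3L }
  bytes_per_px <- as.integer(bits / 8) * nc
  strip_len <- bytes_per_px * nx * ny

  desc_raw <- NULL
  if (!is.null(description)) {
    js <- jsonlite::toJSON(description, auto_unbox = TRUE, digits = NA)
    desc_raw <- c(charToRaw(as.character(js)), as.raw(0))
    if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
  }

  pad2 <- function(n) n + n %% 2
  cur <- 8
  data_off <- numeric(nz)
  for (z in seq_len(nz)) { data_off[z] <- cur; cur <- cur + pad2(strip_len) }
  desc_off <- NA_real_
  if (!is.null(desc_raw)) { desc_off <- cur; cur <- cur + length(desc_raw) }
  aux_needed <- nc > 2  # BitsPerSample / SampleFormat arrays no longer inline
  bits_off <- fmt_off <- NA_real_
  if (aux_needed) {
    bits_off <- cur; cur <- cur + 2 * nc
    fmt_off <- cur; cur <- cur + 2 * nc
  }
  n_entries <- function(z) 11L + as.integer(z == 1L && !is.null(desc_raw))
  ifd_off <- numeric(nz)
  for (z in seq_len(nz)) { ifd_off[z] <- cur; cur <- cur + 2 + 12 * n_entries(z) + 4 }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(u16le(42), con)
  writeBin(u32le(ifd_off[1]), con)

  inline_short <- function(v) {
    # SHORT values left-justified in the 4-byte value field
    out <- raw(4)
    vr <- unlist(lapply(v, u16le))
    out[seq_along(vr)] <- vr
    out
  }

  for (z in seq_len(nz)) {
    slice <- pixels[z, , , , drop = FALSE]
    dim(slice) <- c(ny, nx, nc)
    v <- as.vector(aperm(slice, c(3, 2, 1)))  # channel fastest, then x, then y
    if (fmt == 1L) writeBin(as.integer(v), con, size = bits / 8, endian = "little")
    else writeBin(as.numeric(v), con, size = 4, endian = "little")
    if (strip_len %% 2 == 1) writeBin(raw(1), con)
  }
  if (!is.null(desc_raw)) writeBin(desc_raw, con)
  if (aux_needed) {
    writeBin(unlist(lapply(rep(bits, nc), u16le)), con)
    writeBin(unlist(lapply(rep(fmt, nc), u16le)), con)
  }

  for (z in seq_len(nz)) {
    ents <- list(
      tiff_entry(256, 4, 1, u32le(nx)),
      tiff_entry(257, 4, 1, u32le(ny)),
      if (aux_needed) tiff_entry(258, 3, nc, u32le(bits_off))
      else            tiff_entry(258, 3, nc, inline_short(rep(bits, nc))),
      tiff_entry(259, 3, 1, inline_short(1)),
      tiff_entry(262, 3, 1, inline_short(1))
    )
    if (z == 1L && !is.null(desc_raw))
      ents <- c(ents, list(tiff_entry(270, 2, length(desc_raw), u32le(desc_off))))
    ents <- c(ents, list(
      tiff_entry(273, 4, 1, u32le(data_off[z])),
      tiff_entry(277, 3, 1, inline_short(nc)),
      tiff_entry(278, 4, 1, u32le(ny)),
      tiff_entry(279, 4, 1, u32le(strip_len)),
      tiff_entry(284, 3, 1, inline_short(1)),
      if (aux_needed) tiff_entry(339, 3, nc, u32le(fmt_off))
      else            tiff_entry(339, 3, nc, inline_short(rep(fmt, nc)))
    ))
    writeBin(u16le(length(ents)), con)
    for (e in ents) writeBin(e, con)
    writeBin(u32le(if (z < nz) ifd_off[z + 1] else 0), con)
  }
  invisible(path)
}

rd_uint <- function(raw, pos, size, endian) {
  b <- as.integer(raw[pos:(pos + size - 1)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

read_ifd_value <- function(raw, type, count, value_field_pos, endian) {
  size <- TIFF_TYPE_SIZES[type] * count
  pos <- if (size <= 4) value_field_pos else rd_uint(raw, value_field_pos, 4, endian) + 1
  if (type == 2L) {  # ASCII
    bytes <- raw[pos:(pos + count - 1)]
    nul <- which(bytes == as.raw(0))
    if (length(nul)) bytes <- bytes[seq_len(nul[1] - 1)]
    return(rawToChar(bytes))
  }
  unit <- TIFF_TYPE_SIZES[type]
  vapply(seq_len(count), function(i) rd_uint(raw, pos + (i - 1) * unit, unit, endian),
         numeric(1))
}

#' Read a baseline TIFF into pages of (y, x, channel) arrays
#'
#' @param path TIFF file path
#' @return list with `pages` (list of numeric arrays) and `description`
#'   (first page's ImageDescription string, or NULL)
#' @keywords internal
read_tiff <- function(path) {
  if (!file.exists(path)) stopf("cannot read TIFF: no such file '%s'", path)
  raw <- readBin(path, "raw", n = file.size(path))
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stopf("not a TIFF file: '%s'", path))
  if (rd_uint(raw, 3, 2, endian) != 42) stopf("not a TIFF file: '%s'", path)
  ifd_off <- rd_uint(raw, 5, 4, endian)
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    n <- rd_uint(raw, ifd_off + 1, 2, endian)
    tags <- list()
    for (i in seq_len(n)) {
      ep <- ifd_off + 1 + 2 + (i - 1) * 12
      tag <- rd_uint(raw, ep, 2, endian)
      type <- rd_uint(raw, ep + 2, 2, endian)
      count <- rd_uint(raw, ep + 4, 4, endian)
      if (type >= 1 && type <= 12)
        tags[[as.character(tag)]] <- read_ifd_value(raw, type, count, ep + 8, endian)
    }
    g <- function(t, default = NULL) tags[[as.character(t)]] %||% default
    nx <- g(256); ny <- g(257)
    if (is.null(nx) || is.null(ny)) stopf("TIFF page missing dimensions")
    comp <- g(259, 1)
    if (comp != 1) stopf("unsupported TIFF compression scheme %d", comp)
    nc <- g(277, 1)
    bits <- unique(g(258, 8))
    if (length(bits) != 1) stopf("heterogeneous bits per sample unsupported")
    fmt <- unique(g(339, 1))
    planar <- g(284, 1)
    if (planar != 1) stopf("planar (non-interleaved) TIFF unsupported")
    offs <- g(273); cnts <- g(279)
    if (is.null(offs) || is.null(cnts)) stopf("TIFF page missing strip layout")
    data <- raw(0)
    for (k in seq_along(offs))
      data <- c(data, raw[(offs[k] + 1):(offs[k] + cnts[k])])
    npx <- nx * ny * nc
    if (fmt == 3 && bits == 32) {
      v <- readBin(data, "double", n = npx, size = 4, endian = endian)
    } else if (fmt == 1 && bits %in% c(8, 16)) {
      v <- readBin(data, "integer", n = npx, size = bits / 8,
                   signed = FALSE, endian = endian)
    } else stopf("unsupported TIFF sample type: %d-bit format %d", bits, fmt)
    a <- array(v, dim = c(nc, nx, ny))
    pages[[length(pages) + 1]] <- aperm(a, c(3, 2, 1))  # (y, x, c)
    if (is.null(description) && !is.null(g(270))) description <- g(270)
    ifd_off <- rd_uint(raw, ifd_off + 1 + 2 + n * 12, 4, endian)
  }
  list(pages = pages, description = description)
}
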