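# Minimal single-band GeoTIFF codec.
#
# Scope: uncompressed strip-organized rasters, one sample per pixel, IEEE
# float (32/64 bit) or integer samples, square pixels, north-up (no rotation).
# Georeferencing via ModelPixelScale (33550) + ModelTiepoint (33922); nodata
# via the GDAL_NODATA ASCII tag (42113). Files with a ModelTransformation tag
# (34264) carrying rotation terms are rejected as unsupported geometry.

TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

tiff_read_values <- function(raw, type, count, endian) {
  con <- rawConnection(raw)
  on.exit(close(con))
  switch(as.character(type),
    "1" = readBin(con, "integer", count, size = 1L, signed = FALSE),
    "2" = {
      s <- readBin(con, "raw", count)
      rawToChar(s[s != as.raw(0L)])
    },
    "3" = readBin(con, "integer", count, size = 2L, signed = FALSE,
                  endian = endian),
    "4" = readBin(con, "integer", count, size = 4L, endian = endian),
    "11" = readBin(con, "double", count, size = 4L, endian = endian),
    "12" = readBin(con, "double", count, size = 8L, endian = endian),
    stop("unsupported TIFF field type: ", type, call. = FALSE))
}

tiff_read_ifd <- function(con, endian) {
  n <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    tag <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    raw4 <- readBin(con, "raw", 4L)
    entries[[i]] <- list(tag = tag, type = type, count = count, raw = raw4)
  }
  entries
}

tiff_entry_values <- function(entry, con, endian) {
  if (entry$type > length(TIFF_TYPE_SIZE)) return(NULL)
  total <- TIFF_TYPE_SIZE[entry$type] * entry$count
  if (total <= 4L) {
    tiff_read_values(entry$raw, entry$type, entry$count, endian)
  } else {
    off <- readBin(entry$raw, "integer", 1L, size = 4L, endian = endian)
    seek(con, off)
    tiff_read_values(readBin(con, "raw", total), entry$type, entry$count, endian)
  }
}

#' Read a single-band GeoTIFF
#'
#' Supports uncompressed single-band files with square, unrotated pixels —
#' the format [write_raster()] produces. Values, nodata sentinel, origin and
#' cell size survive a write/read round trip exactly.
#'
#' @param path path to a GeoTIFF file.
#' @param name layer name for the result; defaults to the file base name.
#' @return a [grid_layer()].
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- rawToChar(readBin(con, "raw", 2L))
  endian <- switch(order_bytes, II = "little", MM = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  if (readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian) != 42L)
    stop("not a TIFF file: ", path, call. = FALSE)
  seek(con, readBin(con, "integer", 1L, size = 4L, endian = endian))
  entries <- tiff_read_ifd(con, endian)
  tags <- new.env(parent = emptyenv())
  for (e in entries)
    assign(as.character(e$tag), tiff_entry_values(e, con, endian), envir = tags)
  tg <- function(id, default = NULL) {
    v <- mget(as.character(id), envir = tags, ifnotfound = list(NULL))[[1L]]
    if (is.null(v)) default else v
  }

  width <- tg(256); height <- tg(257)
  if (is.null(width) || is.null(height))
    stop("TIFF missing image dimensions", call. = FALSE)
  if (tg(259, 1L) != 1L)
    stop("compressed TIFFs are not supported", call. = FALSE)
  if (tg(277, 1L) != 1L)
    stop("multi-band TIFFs are not supported", call. = FALSE)
  bits <- tg(258, 1L); fmt <- tg(339, 1L)

  xform <- tg(34264)
  if (!is.null(xform)) {
    # 4x4 row-major model transform; b/d are the rotation terms
    if (abs(xform[2L]) > 0 || abs(xform[5L]) > 0)
      stop("rotated affine transforms are not supported", call. = FALSE)
    scale_x <- xform[1L]; scale_y <- -xform[6L]
    origin_x <- xform[4L]; origin_y <- xform[8L]
  } else {
    scale <- tg(33550)
    tie <- tg(33922)
    if (is.null(scale) || is.null(tie))
      stop("file carries no GeoTIFF georeferencing tags", call. = FALSE)
    scale_x <- scale[1L]; scale_y <- scale[2L]
    origin_x <- tie[4L] - tie[1L] * scale_x
    origin_y <- tie[5L] + tie[2L] * scale_y
  }
  if (abs(scale_x - scale_y) > 1e-9 * max(abs(scale_x), abs(scale_y)))
    stop("non-square pixels are not supported", call. = FALSE)

  strip_offsets <- tg(273); strip_bytes <- tg(279)
  if (is.null(strip_offsets)) stop("TIFF missing strip offsets", call. = FALSE)
  sample_size <- bits %/% 8L
  vals <- numeric(0)
  for (i in seq_along(strip_offsets)) {
    seek(con, strip_offsets[i])
    n_samp <- strip_bytes[i] %/% sample_size
    v <- if (fmt == 3L)
      readBin(con, "double", n_samp, size = sample_size, endian = endian)
    else
      readBin(con, "integer", n_samp, size = sample_size,
              signed = fmt == 2L || sample_size == 4L, endian = endian)
    vals <- c(vals, as.numeric(v))
  }
  if (length(vals) != width * height)
    stop("TIFF pixel data truncated", call. = FALSE)
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)

  nodata <- suppressWarnings(as.numeric(tg(42113, NA_character_)))
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  grid_layer(name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
             values = m, origin_x = origin_x, origin_y = origin_y,
             cell_size = scale_x,
             nodata = if (is.na(nodata)) -9999 else nodata)
}

tiff_pack <- function(what, size, endian = "little") {
  writeBin(what, raw(), size = size, endian = endian)
}

tiff_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4L)
  c(tiff_pack(as.integer(tag), 2L), tiff_pack(as.integer(type), 2L),
    tiff_pack(as.integer(count), 4L),
    c(value_raw, raw(4L - length(value_raw))))
}

#' Write a grid as a single-band GeoTIFF
#'
#' Writes an uncompressed little-endian float64 GeoTIFF with
#' ModelPixelScale/ModelTiepoint georeferencing and a GDAL-style nodata tag;
#' `NA` cells are stored as the grid's `nodata` sentinel. [read_raster()]
#' inverts the file exactly.
#'
#' @param grid a [grid_layer()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "grid_layer"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  h <- nrow(m); w <- ncol(m)
  nodata_str <- c(charToRaw(format(grid$nodata, scientific = FALSE,
                                   trim = TRUE)), as.raw(0L))

  n_entries <- 13L
  ifd_offset <- 8L
  ifd_size <- 2L + 12L * n_entries + 4L
  scale_off <- ifd_offset + ifd_size
  tie_off <- scale_off + 24L
  nodata_off <- tie_off + 48L
  data_off <- nodata_off + length(nodata_str)
  data_off <- data_off + (-data_off %% 4L)          # word-align pixel data

  short_val <- function(x) tiff_pack(as.integer(x), 2L)
  long_val <- function(x) tiff_pack(as.integer(x), 4L)
  entries <- c(
    tiff_entry(256L, 4L, 1L, long_val(w)),
    tiff_entry(257L, 4L, 1L, long_val(h)),
    tiff_entry(258L, 3L, 1L, short_val(64L)),
    tiff_entry(259L, 3L, 1L, short_val(1L)),
    tiff_entry(262L, 3L, 1L, short_val(1L)),
    tiff_entry(273L, 4L, 1L, long_val(data_off)),
    tiff_entry(277L, 3L, 1L, short_val(1L)),
    tiff_entry(278L, 4L, 1L, long_val(h)),
    tiff_entry(279L, 4L, 1L, long_val(h * w * 8L)),
    tiff_entry(339L, 3L, 1L, short_val(3L)),
    tiff_entry(33550L, 12L, 3L, long_val(scale_off)),
    tiff_entry(33922L, 12L, 6L, long_val(tie_off)),
    tiff_entry(42113L, 2L, length(nodata_str), long_val(nodata_off)))

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write raster: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_offset, con, size = 4L, endian = "little")
  writeBin(as.integer(n_entries), con, size = 2L, endian = "little")
  writeBin(entries, con)
  writeBin(0L, con, size = 4L, endian = "little")                # no next IFD
  writeBin(c(grid$cell_size, grid$cell_size, 0), con, size = 8L,
           endian = "little")
  writeBin(c(0, 0, 0, grid$origin_x, grid$origin_y, 0), con, size = 8L,
           endian = "little")
  writeBin(nodata_str, con)
  pad <- seek(con)
  if (pad < data_off) writeBin(raw(data_off - pad), con)
  writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
  invisible(path)
}

# Test fixture helper: write a float64 TIFF whose georeferencing is a full
# model transform with rotation terms; read_raster must refuse it.
tiff_write_rotated <- function(values, path, rotation = 0.1, cell_size = 250) {
  m <- as.matrix(values)
  h <- nrow(m); w <- ncol(m)
  n_entries <- 11L
  ifd_size <- 2L + 12L * n_entries + 4L
  xform_off <- 8L + ifd_size
  data_off <- xform_off + 16L * 8L
  short_val <- function(x) tiff_pack(as.integer(x), 2L)
  long_val <- function(x) tiff_pack(as.integer(x), 4L)
  entries <- c(
    tiff_entry(256L, 4L, 1L, long_val(w)),
    tiff_entry(257L, 4L, 1L, long_val(h)),
    tiff_entry(258L, 3L, 1L, short_val(64L)),
    tiff_entry(259L, 3L, 1L, short_val(1L)),
    tiff_entry(262L, 3L, 1L, short_val(1L)),
    tiff_entry(273L, 4L, 1L, long_val(data_off)),
    tiff_entry(277L, 3L, 1L, short_val(1L)),
    tiff_entry(278L, 4L, 1L, long_val(h)),
    tiff_entry(279L, 4L, 1L, long_val(h * w * 8L)),
    tiff_entry(339L, 3L, 1L, short_val(3L)),
    tiff_entry(34264L, 12L, 16L, long_val(xform_off)))
  xform <- c(cell_size, rotation, 0, 0,
             rotation, -cell_size, 0, h * cell_size,
             0, 0, 0, 0, 0, 0, 0, 1)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(8L, con, size = 4L, endian = "little")
  writeBin(as.integer(n_entries), con, size = 2L, endian = "little")
  writeBin(entries, con)
  writeBin(0L, con, size = 4L, endian = "little")
  writeBin(xform, con, size = 8L, endian = "little")
  writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
  invisible(path)
}
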