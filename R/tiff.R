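# Minimal baseline TIFF codec.
#
# Scope: grayscale, single sample per pixel, uncompressed, strip-based,
# multi-page; uint8/16/32 and float32 sample formats. Written little-endian;
# both byte orders are accepted on read. This covers every raster this
# package produces or consumes (acquisitions, FRET maps, label masks).

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L,
                 SBYTE = 6L, UNDEF = 7L, SSHORT = 8L, SLONG = 9L,
                 SRATIONAL = 10L, FLOAT = 11L, DOUBLE = 12L)
.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

.u16 <- function(raw, off, endian) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2L, signed = FALSE,
          endian = endian)
}

.u32 <- function(raw, off, endian) {
  v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4L, endian = endian)
  if (v < 0) v <- v + 4294967296
  v
}

.read_entry_values <- function(raw, off, endian) {
  tag   <- .u16(raw, off, endian)
  type  <- .u16(raw, off + 2, endian)
  count <- .u32(raw, off + 4, endian)
  if (type < 1L || type > 12L) return(list(tag = tag, values = NULL))
  nbytes <- .tiff_type_size[type] * count
  voff <- if (nbytes <= 4) off + 8 else .u32(raw, off + 8, endian)
  bytes <- raw[(voff + 1):(voff + nbytes)]
  values <- switch(as.character(type),
    `1` = as.integer(bytes),
    `3` = readBin(bytes, "integer", n = count, size = 2L, signed = FALSE,
                  endian = endian),
    `4` = {
      v <- readBin(bytes, "integer", n = count, size = 4L, endian = endian)
      v <- as.double(v); v[v < 0] <- v[v < 0] + 4294967296; v
    },
    `8` = readBin(bytes, "integer", n = count, size = 2L, endian = endian),
    `9` = readBin(bytes, "integer", n = count, size = 4L, endian = endian),
    `11` = readBin(bytes, "numeric", n = count, size = 4L, endian = endian),
    `12` = readBin(bytes, "numeric", n = count, size = 8L, endian = endian),
    as.integer(bytes))
  list(tag = tag, values = values)
}

#' Read a multi-page grayscale TIFF
#'
#' Internal reader for uncompressed single-sample TIFFs of any common bit
#' depth. Returns a list of numeric matrices (row, column order), each with
#' attributes `sample_format` (`"uint"` or `"float"`) and `bits`.
#'
#' @param path path to a TIFF file.
#' @return list of matrices, one per page/plane.
#' @noRd
read_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file (truncated): ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("not a TIFF file (bad byte order mark): ", path)
  if (.u16(raw, 2, endian) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- .u32(raw, 4, endian)
  planes <- list()
  while (ifd_off != 0) {
    n_entries <- .u16(raw, ifd_off, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- .read_entry_values(raw, ifd_off + 2 + (i - 1) * 12, endian)
      tags[[as.character(e$tag)]] <- e$values
    }
    width  <- tags[["256"]]; height <- tags[["257"]]
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]][1]
    if (comp != 1L) stop("unsupported TIFF compression scheme: ", comp)
    spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]][1]
    if (spp != 1L) stop("only single-sample (grayscale) TIFFs are supported")
    fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
    if (!fmt %in% c(1L, 3L)) stop("unsupported TIFF sample format: ", fmt)
    offs <- tags[["273"]]; counts <- tags[["279"]]
    if (is.null(offs)) stop("TIFF page missing strip offsets")
    if (is.null(counts)) counts <- width * height * bits / 8
    data_bytes <- raw[unlist(mapply(function(o, n) (o + 1):(o + n),
                                    offs, counts, SIMPLIFY = FALSE))]
    npix <- width * height
    vals <- if (fmt == 3L) {
      if (bits != 32L) stop("only 32-bit float TIFFs are supported")
      readBin(data_bytes, "numeric", n = npix, size = 4L, endian = endian)
    } else if (bits == 8L) {
      as.double(as.integer(data_bytes))
    } else if (bits == 16L) {
      as.double(readBin(data_bytes, "integer", n = npix, size = 2L,
                        signed = FALSE, endian = endian))
    } else if (bits == 32L) {
      v <- as.double(readBin(data_bytes, "integer", n = npix, size = 4L,
                             endian = endian))
      v[v < 0] <- v[v < 0] + 4294967296
      v
    } else stop("unsupported TIFF bit depth: ", bits)
    m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    attr(m, "sample_format") <- if (fmt == 3L) "float" else "uint"
    attr(m, "bits") <- as.integer(bits)
    planes[[length(planes) + 1L]] <- m
    ifd_off <- .u32(raw, ifd_off + 2 + n_entries * 12, endian)
  }
  planes
}

.tiff_entry <- function(tag, type, count, value_or_offset) {
  con <- raw()
  c(writeBin(as.integer(tag), con, size = 2L, endian = "little"),
    writeBin(as.integer(type), con, size = 2L, endian = "little"),
    writeBin(as.integer(count), con, size = 4L, endian = "little"),
    writeBin(as.integer(value_or_offset), con, size = 4L, endian = "little"))
}

#' Write matrices as a multi-page grayscale TIFF
#'
#' @param planes a matrix or list of matrices (row, column order).
#' @param path output path.
#' @param dtype one of "float32", "uint8", "uint16", "uint32".
#' @return `path`, invisibly.
#' @noRd
write_tiff <- function(planes, path,
                       dtype = c("float32", "uint16", "uint8", "uint32")) {
  dtype <- match.arg(dtype)
  if (is.matrix(planes)) planes <- list(planes)
  bits <- switch(dtype, float32 = 32L, uint32 = 32L, uint16 = 16L, uint8 = 8L)
  fmt  <- if (dtype == "float32") 3L else 1L
  dmax <- switch(dtype, uint8 = 255, uint16 = 65535, uint32 = 4294967295,
                 float32 = Inf)
  n_tags <- 10L
  ifd_len <- 2L + n_tags * 12L + 4L
  body <- writeBin(charToRaw("II"), raw())
  body <- c(body, writeBin(42L, raw(), size = 2L, endian = "little"))
  # first IFD sits right after the 8-byte header; pixel data follow each IFD
  offset <- 8L
  chunks <- list()
  for (p in seq_along(planes)) {
    m <- planes[[p]]
    stopifnot(is.matrix(m))
    h <- nrow(m); w <- ncol(m)
    nbytes <- h * w * bits / 8L
    ifd_off <- offset
    data_off <- ifd_off + ifd_len
    v <- as.vector(t(m))                       # row-major
    if (fmt == 1L) {
      if (any(v < 0 | v > dmax, na.rm = TRUE) || anyNA(v))
        stop("pixel values out of range for ", dtype)
      if (any(v != round(v))) stop("non-integer pixel values for ", dtype)
    }
    pix <- if (dtype == "float32") {
      writeBin(as.numeric(v), raw(), size = 4L, endian = "little")
    } else if (dtype == "uint8") {
      as.raw(as.integer(v))
    } else if (dtype == "uint16") {
      writeBin(as.integer(v), raw(), size = 2L, endian = "little")
    } else {                                   # uint32, reject > 2^31 - 1
      if (any(v > 2147483647)) stop("uint32 write limited to values < 2^31")
      writeBin(as.integer(v), raw(), size = 4L, endian = "little")
    }
    next_ifd <- if (p < length(planes)) data_off + nbytes else 0L
    ifd <- writeBin(n_tags, raw(), size = 2L, endian = "little")
    ifd <- c(ifd,
             .tiff_entry(256L, 4L, 1L, w),
             .tiff_entry(257L, 4L, 1L, h),
             .tiff_entry(258L, 3L, 1L, bits),
             .tiff_entry(259L, 3L, 1L, 1L),    # no compression
             .tiff_entry(262L, 3L, 1L, 1L),    # BlackIsZero
             .tiff_entry(273L, 4L, 1L, data_off),
             .tiff_entry(277L, 3L, 1L, 1L),
             .tiff_entry(278L, 4L, 1L, h),
             .tiff_entry(279L, 4L, 1L, nbytes),
             .tiff_entry(339L, 3L, 1L, fmt),
             writeBin(as.integer(next_ifd), raw(), size = 4L,
                      endian = "little"))
    chunks[[p]] <- c(ifd, pix)
    offset <- data_off + nbytes
  }
  body <- c(body, writeBin(8L, raw(), size = 4L, endian = "little"))
  writeBin(c(body, unlist(chunks)), path)
  invisible(path)
}
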