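# Minimal baseline TIFF codec: uncompressed, single-sample (grayscale),
# 8- or 16-bit unsigned, single- or multi-page, both byte orders on read,
# little-endian on write. Intensities are never rescaled.

.u16raw <- function(v) {
  v <- as.integer(v)
  as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
}

.u32raw <- function(v) {
  v <- as.numeric(v)
  b0 <- v %% 256
  b1 <- (v %/% 256) %% 256
  b2 <- (v %/% 65536) %% 256
  b3 <- (v %/% 16777216) %% 256
  as.raw(as.vector(rbind(b0, b1, b2, b3)))
}

.ifd_entry <- function(tag, type, count, value) {
  c(.u16raw(tag), .u16raw(type), .u32raw(count), .u32raw(value))
}

#' Write a grayscale TIFF
#'
#' Writes one or more 2-D integer matrices as an uncompressed grayscale
#' baseline TIFF (little-endian), one page per matrix. Values must lie in
#' the unsigned range of the chosen bit depth; no rescaling is applied.
#'
#' @param pages a matrix or a list of matrices (all the same bit range)
#' @param path output file path
#' @param bits bits per sample, 8 or 16
#' @return `path`, invisibly
#' @export
write_tiff <- function(pages, path, bits = 16L) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, bits %in% c(8L, 16L))
  maxval <- if (bits == 16L) 65535 else 255
  for (m in pages) {
    if (!is.matrix(m)) stop("each page must be a 2-D matrix")
    v <- as.vector(m)
    if (anyNA(v) || any(v < 0) || any(v > maxval) || any(v != floor(v)))
      stop("pixel values must be integers in [0, ", maxval, "]")
  }
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  out <- c(charToRaw("II"), .u16raw(42L), .u32raw(8L))
  offset <- 8L
  n <- length(pages)
  for (i in seq_len(n)) {
    m <- pages[[i]]
    h <- nrow(m); w <- ncol(m)
    nbytes <- h * w * (bits / 8L)
    data_off <- offset + ifd_size
    pad <- nbytes %% 2L                      # keep IFDs word-aligned
    next_ifd <- if (i < n) data_off + nbytes + pad else 0L
    ifd <- c(
      .u16raw(n_entries),
      .ifd_entry(256L, 4L, 1L, w),           # ImageWidth
      .ifd_entry(257L, 4L, 1L, h),           # ImageLength
      .ifd_entry(258L, 3L, 1L, bits),        # BitsPerSample
      .ifd_entry(259L, 3L, 1L, 1L),          # Compression: none
      .ifd_entry(262L, 3L, 1L, 1L),          # Photometric: BlackIsZero
      .ifd_entry(273L, 4L, 1L, data_off),    # StripOffsets
      .ifd_entry(277L, 3L, 1L, 1L),          # SamplesPerPixel
      .ifd_entry(278L, 4L, 1L, h),           # RowsPerStrip
      .ifd_entry(279L, 4L, 1L, nbytes),      # StripByteCounts
      .u32raw(next_ifd)
    )
    v <- as.integer(t(m))                    # TIFF is row-major
    data <- if (bits == 16L) .u16raw(v) else as.raw(v)
    if (pad) data <- c(data, as.raw(0L))
    out <- c(out, ifd, data)
    offset <- offset + ifd_size + nbytes + pad
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

.rd_u16 <- function(raw, off, le) {
  a <- as.integer(raw[off + 1L]); b <- as.integer(raw[off + 2L])
  if (le) a + 256L * b else 256L * a + b
}

.rd_u32 <- function(raw, off, le) {
  b <- as.numeric(raw[off + 1:4])
  if (le) sum(b * c(1, 256, 65536, 16777216)) else
    sum(b * c(16777216, 65536, 256, 1))
}

.rd_values <- function(raw, type, count, value_off, le) {
  # type 3 = SHORT (2 bytes), type 4 = LONG (4 bytes)
  size <- if (type == 3L) 2L else 4L
  total <- size * count
  base <- if (total <= 4L) value_off else .rd_u32(raw, value_off, le)
  vapply(seq_len(count) - 1L, function(k) {
    if (type == 3L) as.numeric(.rd_u16(raw, base + 2L * k, le))
    else .rd_u32(raw, base + 4L * k, le)
  }, numeric(1))
}

#' Read a grayscale TIFF
#'
#' Reads an uncompressed grayscale baseline TIFF (8- or 16-bit unsigned,
#' either byte order) and returns its pages bit-exactly.
#'
#' @param path file path
#' @return list of integer matrices, one per page, with attribute `bits`
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("unreadable TIFF: no such file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("unreadable TIFF: file too short")
  magic <- rawToChar(raw[1:2])
  if (magic == "II") le <- TRUE
  else if (magic == "MM") le <- FALSE
  else stop("unreadable TIFF: bad byte-order mark")
  if (.rd_u16(raw, 2L, le) != 42L) stop("unreadable TIFF: bad magic number")
  ifd_off <- .rd_u32(raw, 4L, le)
  pages <- list()
  bits_seen <- NA_integer_
  while (ifd_off != 0) {
    n_entries <- .rd_u16(raw, ifd_off, le)
    tags <- list()
    for (j in seq_len(n_entries) - 1L) {
      eo <- ifd_off + 2L + 12L * j
      tag <- .rd_u16(raw, eo, le)
      type <- .rd_u16(raw, eo + 2L, le)
      count <- .rd_u32(raw, eo + 4L, le)
      if (type %in% c(3L, 4L))
        tags[[as.character(tag)]] <- .rd_values(raw, type, count, eo + 8L, le)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("unreadable TIFF: missing tag ", tag)
        default
      } else v
    }
    w <- need(256L); h <- need(257L)
    bits <- as.integer(need(258L, 8))
    if (!bits %in% c(8L, 16L))
      stop("unsupported TIFF: ", bits, "-bit samples")
    if (need(259L, 1) != 1) stop("unsupported TIFF: compressed data")
    if (need(277L, 1) != 1) stop("unsupported TIFF: multi-sample pixels")
    if (need(339L, 1) != 1) stop("unsupported TIFF: non-integer sample type")
    offs <- need(273L); cnts <- need(279L)
    bytes <- unlist(lapply(seq_along(offs), function(k) {
      raw[(offs[k] + 1):(offs[k] + cnts[k])]
    }), use.names = FALSE)
    npx <- w * h
    px <- if (bits == 8L) {
      as.integer(bytes[seq_len(npx)])
    } else {
      a <- as.integer(bytes[seq(1L, 2L * npx, by = 2L)])
      b <- as.integer(bytes[seq(2L, 2L * npx, by = 2L)])
      if (le) a + 256L * b else 256L * a + b
    }
    pages[[length(pages) + 1L]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    bits_seen <- bits
    ifd_off <- .rd_u32(raw, ifd_off + 2L + 12L * n_entries, le)
  }
  if (length(pages) == 0L) stop("unreadable TIFF: no pages")
  attr(pages, "bits") <- bits_seen
  pages
}
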