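# Minimal PNG codec for 8-bit RGB images.
#
# The environment this package targets has no binding to libpng, but
# base R's memCompress()/memDecompress(type = "gzip") speak the RFC 1950
# zlib format that PNG IDAT chunks use, so a self-contained reader and
# writer are implemented here.  Scope: 8-bit depth, colour types 0
# (greyscale), 2 (RGB) and 6 (RGBA), no interlacing, no palette.  That
# covers the 24-bit colour segmentations and atlas plates this package
# consumes and everything it writes.

PNG_SIGNATURE <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))

.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) # 0xEDB88320
      } else {
        bitwShiftR(bitwAnd(c, -2L), 1)
      }
    }
    tab[n + 1L] <- c
  }
  .crc_env$tab <- tab
  tab
}

# CRC-32 (ISO 3309) of a raw vector, returned as 4 big-endian raw bytes.
crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8), tab[idx + 1L])
  }
  crc <- bitwNot(crc)
  as.raw(c(
    bitwAnd(bitwShiftR(crc, 24), 255L), bitwAnd(bitwShiftR(crc, 16), 255L),
    bitwAnd(bitwShiftR(crc, 8), 255L), bitwAnd(crc, 255L)
  ))
}

u32_to_raw <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

raw_to_u32 <- function(r) {
  sum(as.double(as.integer(r)) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_to_raw(length(data)), body, crc32(body))
}

#' Write an RGB image to a PNG file
#'
#' @param img integer array of dimension `c(height, width, 3)` with values
#'   in 0--255 (row 1 is the top image row).  A `height x width` matrix is
#'   accepted and written as greyscale replicated to RGB.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  storage.mode(img) <- "integer"
  if (anyNA(img) || min(img) < 0L || max(img) > 255L)
    stop("write_png: pixel values must be integers in 0..255")
  h <- dim(img)[1]; w <- dim(img)[2]
  # interleave channels row-major: aperm to (channel, x, y) then flatten
  px <- as.vector(aperm(img, c(3L, 2L, 1L)))
  rows <- matrix(px, nrow = 3L * w, ncol = h)          # one column per row
  scan <- rbind(0L, rows)                              # filter byte 0 (None)
  stream <- memCompress(as.raw(as.vector(scan)), type = "gzip")
  ihdr <- c(u32_to_raw(w), u32_to_raw(h), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  out <- c(
    PNG_SIGNATURE,
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", stream),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}

paeth_predict <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  if (pa <= pb && pa <= pc) a else if (pb <= pc) b else c
}

# Undo one scanline filter in place; all vectors are integer 0..255.
png_unfilter_row <- function(type, cur, prev, bpp) {
  n <- length(cur)
  if (type == 0L) return(cur)
  if (type == 2L) return((cur + prev) %% 256L)
  if (type == 1L) {                       # Sub: cumsum per byte lane
    for (off in seq_len(bpp)) {
      idx <- seq.int(off, n, by = bpp)
      cur[idx] <- cumsum(cur[idx]) %% 256L
    }
    return(cur)
  }
  if (type == 3L) {                       # Average
    for (i in seq_len(n)) {
      left <- if (i > bpp) cur[i - bpp] else 0L
      cur[i] <- (cur[i] + (left + prev[i]) %/% 2L) %% 256L
    }
    return(cur)
  }
  if (type == 4L) {                       # Paeth
    for (i in seq_len(n)) {
      left <- if (i > bpp) cur[i - bpp] else 0L
      ul <- if (i > bpp) prev[i - bpp] else 0L
      cur[i] <- (cur[i] + paeth_predict(left, prev[i], ul)) %% 256L
    }
    return(cur)
  }
  stop("read_png: unsupported filter type ", type)
}

#' Read a PNG file as an RGB array
#'
#' Supports 8-bit greyscale, RGB and RGBA PNGs without interlacing.
#' Greyscale is replicated to three channels; an alpha channel, if
#' present, is dropped (with a warning when it is not fully opaque).
#'
#' @param path PNG file path.
#' @return integer array `c(height, width, 3)`, values 0--255.
#' @export
read_png <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8L || !identical(bytes[1:8], PNG_SIGNATURE))
    stop("read_png: ", path, " is not a PNG file")
  pos <- 9L
  idat <- list(); ihdr <- NULL
  while (pos + 8L <= length(bytes)) {
    len <- raw_to_u32(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) bytes[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") ihdr <- data
    else if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(ihdr)) stop("read_png: missing IHDR chunk")
  w <- raw_to_u32(ihdr[1:4]); h <- raw_to_u32(ihdr[5:8])
  bitdepth <- as.integer(ihdr[9]); colourtype <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (bitdepth != 8L)
    stop("read_png: only 8-bit depth supported (got ", bitdepth, ")")
  if (interlace != 0L) stop("read_png: interlaced PNG not supported")
  nch <- switch(as.character(colourtype), "0" = 1L, "2" = 3L, "6" = 4L,
                stop("read_png: unsupported colour type ", colourtype))
  stream <- memDecompress(do.call(c, idat), type = "gzip")
  stride <- nch * w
  stopifnot(length(stream) == h * (stride + 1L))
  mat <- matrix(as.integer(stream), nrow = stride + 1L, ncol = h)
  filters <- mat[1L, ]
  out <- matrix(0L, nrow = stride, ncol = h)
  prev <- integer(stride)
  for (r in seq_len(h)) {
    prev <- png_unfilter_row(filters[r], mat[-1L, r], prev, nch)
    out[, r] <- prev
  }
  arr <- aperm(array(out, dim = c(nch, w, h)), c(3L, 2L, 1L))
  if (nch == 1L) {
    arr <- array(rep(arr, 3L), dim = c(h, w, 3L))
  } else if (nch == 4L) {
    if (any(arr[, , 4L] != 255L))
      warning("read_png: dropping non-opaque alpha channel of ", path)
    arr <- arr[, , 1:3, drop = FALSE]
  }
  storage.mode(arr) <- "integer"
  arr
}
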