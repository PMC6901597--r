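# Image-series pre-processing and pixel <-> physical-unit arithmetic.
#
# Segmentations are produced from scans that were downscaled by a resize
# factor before classification, so one segmentation pixel represents
# (base_pixel_size / resize_factor) micrometres of tissue on a side.
# All area conversions in the package flow through scale_spec().

#' Physical scale of a segmentation series
#'
#' @param base_pixel_size micrometres per pixel of the original scanned
#'   image (e.g. 0.284 um/px for a 20x slide scan).
#' @param resize_factor dimensionless downscaling factor in (0, 1]
#'   applied before segmentation (e.g. 0.05).
#' @return a `scale_spec` object.
#' @export
scale_spec <- function(base_pixel_size, resize_factor = 1) {
  stopifnot(is.numeric(base_pixel_size), length(base_pixel_size) == 1L,
            base_pixel_size > 0,
            is.numeric(resize_factor), length(resize_factor) == 1L,
            resize_factor > 0, resize_factor <= 1)
  structure(list(base_pixel_size = as.numeric(base_pixel_size),
                 resize_factor = as.numeric(resize_factor)),
            class = "scale_spec")
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("<scale_spec> %g um/px at resize factor %g -> %g um2/px\n",
              x$base_pixel_size, x$resize_factor, pixel_area_um2(x)))
  invisible(x)
}

#' Area represented by one segmentation pixel
#'
#' One pixel of the downscaled segmentation covers
#' `(base_pixel_size / resize_factor)^2` square micrometres of tissue.
#'
#' @param scale a [scale_spec()].
#' @return area in um^2 per pixel.
#' @export
pixel_area_um2 <- function(scale) {
  stopifnot(inherits(scale, "scale_spec"))
  (scale$base_pixel_size / scale$resize_factor)^2
}

#' Physical area of a pixel count
#'
#' Converts object sizes in segmentation pixels to um^2; used, for
#' example, to express minimum object-size cut-offs (8 px at
#' 0.284 um/px, factor 0.05, is 258.0992 um^2).
#'
#' @param n_pixels non-negative pixel count(s).
#' @param scale a [scale_spec()].
#' @return area(s) in um^2.
#' @export
object_area_um2 <- function(n_pixels, scale) {
  stopifnot(all(n_pixels >= 0))
  n_pixels * pixel_area_um2(scale)
}

round_half_up <- function(x) floor(x + 0.5)

#' Resize an RGB image
#'
#' Output dimensions are `round(factor * dim)` (round half up).  Use
#' `method = "nearest"` for label-like content (no new colours are
#' invented) and `method = "area"` (box average) for photographs.
#'
#' @param img integer array `c(h, w, 3)`.
#' @param factor scale factor in (0, 1].
#' @param method `"nearest"` or `"area"`.
#' @return resized integer array.
#' @export
resize_image <- function(img, factor, method = c("nearest", "area")) {
  method <- match.arg(method)
  stopifnot(factor > 0, factor <= 1)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (factor * h < 1 || factor * w < 1)
    stop("resize_image: factor ", factor, " gives degenerate size for a ",
         w, "x", h, " image (need factor*dimension >= 1)")
  nh <- as.integer(round_half_up(factor * h))
  nw <- as.integer(round_half_up(factor * w))
  if (nh == h && nw == w) return(img)
  if (method == "nearest") {
    sy <- pmin(floor((seq_len(nh) - 0.5) * h / nh), h - 1L) + 1L
    sx <- pmin(floor((seq_len(nw) - 0.5) * w / nw), w - 1L) + 1L
    out <- img[sy, sx, , drop = FALSE]
  } else {
    # box average over the source interval covered by each output pixel
    out <- array(0L, dim = c(nh, nw, 3L))
    ylo <- floor((seq_len(nh) - 1L) * h / nh); yhi <- ceiling(seq_len(nh) * h / nh)
    xlo <- floor((seq_len(nw) - 1L) * w / nw); xhi <- ceiling(seq_len(nw) * w / nw)
    for (c in 1:3) {
      ch <- img[, , c]
      for (j in seq_len(nw)) {
        cols <- ch[, (xlo[j] + 1L):xhi[j], drop = FALSE]
        rs <- rowMeans(cols)
        out[, j, c] <- vapply(seq_len(nh), function(i)
          as.integer(round_half_up(mean(rs[(ylo[i] + 1L):yhi[i]]))), 0L)
      }
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Rotate an image by quarter turns
#'
#' A lossless pixel permutation; four quarter turns compose to the
#' identity.  Positive turns rotate clockwise.
#'
#' @param img integer array `c(h, w, 3)` or matrix.
#' @param quarter_turns integer in 0..3.
#' @return rotated array.
#' @export
rotate_image <- function(img, quarter_turns) {
  stopifnot(quarter_turns %in% 0:3)
  k <- as.integer(quarter_turns)
  if (k == 0L) return(img)
  rot1 <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])  # 90 cw
  app <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (is.matrix(img)) return(app(img))
  d <- dim(img)
  nd <- if (k %% 2L == 1L) c(d[2], d[1], d[3]) else d
  out <- array(img[1], dim = nd)
  for (c in seq_len(d[3])) out[, , c] <- app(image_channel(img, c))
  storage.mode(out) <- storage.mode(img)
  out
}

image_channel <- function(img, c) {
  m <- img[, , c, drop = FALSE]
  dim(m) <- dim(img)[1:2]
  m
}

#' Mirror an image
#'
#' `axis = "horizontal"` flips left-right, `"vertical"` flips
#' top-bottom.  Applying the same mirror twice is the identity.
#'
#' @param img integer array `c(h, w, 3)` or matrix.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return mirrored array.
#' @export
mirror_image <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  flip <- function(m) if (axis == "horizontal")
    m[, rev(seq_len(ncol(m))), drop = FALSE]
  else m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (is.matrix(img)) return(flip(img))
  out <- img
  for (c in seq_len(dim(img)[3])) out[, , c] <- flip(image_channel(img, c))
  out
}

#' Plan a series renaming
#'
#' Computes an injective old -> new filename mapping from a template
#' with one counter placeholder, validating for collisions before any
#' file is touched (rename with `apply = TRUE` only after the whole
#' mapping checks out).
#'
#' @param filenames input filenames, in series order.
#' @param template filename template containing exactly one `{N}` or
#'   zero-padded `{N:03}` placeholder.
#' @param start,step counter start value and increment (e.g. start 1,
#'   step 4 for every-4th-section sampling).
#' @param apply if TRUE, perform the renames on disk (paths must exist).
#' @return named character vector: `names()` are the old names, values
#'   the new names.
#' @export
rename_series <- function(filenames, template, start = 1L, step = 1L,
                          apply = FALSE) {
  m <- gregexpr("\\{N(:0?(\\d+))?\\}", template)[[1]]
  if (length(m) != 1L || m[1] == -1L)
    stop("rename_series: template must contain exactly one {N} placeholder")
  ph <- regmatches(template, m)[[1]]
  width <- sub("^\\{N(:0?(\\d+))?\\}$", "\\2", ph)
  fmt <- if (nzchar(width)) paste0("%0", width, "d") else "%d"
  if (length(filenames) == 0L) return(stats::setNames(character(0), character(0)))
  counters <- start + step * (seq_along(filenames) - 1L)
  new <- vapply(counters, function(n)
    sub("\\{N(:0?(\\d+))?\\}", sprintf(fmt, n), template), "")
  if (anyDuplicated(new))
    stop("rename_series: collision, two inputs map to ",
         new[duplicated(new)][1])
  mapping <- stats::setNames(new, filenames)
  if (apply) {
    ok <- file.rename(filenames, file.path(dirname(filenames), new))
    if (!all(ok)) stop("rename_series: rename failed for ",
                       paste(filenames[!ok], collapse = ", "))
  }
  mapping
}
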