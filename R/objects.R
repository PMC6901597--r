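# Object extraction from colour segmentations.
#
# A segmentation encodes each object class as one exact RGB colour code.
# A mask is taken per target colour, maximal connected components are
# collected by iterative flood fill (compiled; explicit stack, so a
# million-pixel blob cannot overflow the call stack), and per-object
# statistics are computed.  All pixel coordinates are 0-based, x
# rightward, y downward, origin at the top-left pixel.

#' Binarize a segmentation image by exact colour match
#'
#' @param img integer RGB array `c(h, w, 3)` as returned by [read_png()].
#' @param colour length-3 integer RGB triple in 0..255.
#' @return a `seg_mask`: logical matrix (h x w) with attributes
#'   `colour`.  If the colour is absent the mask is valid but empty and
#'   a warning is emitted (exact matching surfaces off-by-one colour
#'   codes).
#' @export
binarize_by_colour <- function(img, colour) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L, length(colour) == 3L)
  colour <- as.integer(colour)
  m <- img[, , 1] == colour[1] & img[, , 2] == colour[2] &
    img[, , 3] == colour[3]
  if (!any(m))
    warning("binarize_by_colour: colour (", paste(colour, collapse = ","),
            ") not present in image")
  structure(m, colour = colour, class = c("seg_mask", "matrix"))
}

#' Construct a segmentation mask directly from a logical matrix
#'
#' @param member logical matrix (rows = image rows): TRUE where the
#'   pixel carries the target colour.
#' @param colour the RGB colour code the mask represents.
#' @return a `seg_mask`.
#' @export
seg_mask <- function(member, colour = c(255L, 0L, 255L)) {
  stopifnot(is.matrix(member), is.logical(member))
  structure(member, colour = as.integer(colour),
            class = c("seg_mask", "matrix"))
}

#' Extract connected objects from a segmentation mask
#'
#' Every member pixel is assigned to exactly one maximal connected
#' component under the chosen connectivity.  Objects are numbered in
#' raster order of their anchor pixel (smallest y, ties broken by
#' smallest x), which makes extraction deterministic and repeatable.
#'
#' @param mask a `seg_mask` (logical matrix) from [binarize_by_colour()].
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal,
#'   default: diagonally touching plaque pixels form one plaque).
#' @param scale optional [scale_spec()] used to fill `area_um2`.
#' @return an `object_set`: data.frame with one row per object and
#'   columns `object_id`, `x_anchor`, `y_anchor`, `x_centroid`,
#'   `y_centroid`, `x_min`, `y_min`, `x_max`, `y_max`, `width_px`,
#'   `height_px`, `area_px`, `area_um2` (NA without `scale`),
#'   `region_id` (NA until assigned) and a list column `pixels` of
#'   n x 2 integer matrices (columns x, y; 0-based).
#' @export
extract_objects <- function(mask, connectivity = 8L, scale = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask),
            connectivity %in% c(4L, 8L))
  lab <- .label_components(unclass(mask), as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) return(empty_object_set())
  idx <- which(lab > 0L)
  h <- nrow(mask)
  x <- (idx - 1L) %/% h       # 0-based column
  y <- (idx - 1L) %% h        # 0-based row
  comp <- lab[idx]
  # raster order within each component: order by component, then y, then x
  o <- order(comp, y, x)
  x <- x[o]; y <- y[o]; comp <- comp[o]
  pix <- split.data.frame(cbind(x = x, y = y), comp)
  rows <- lapply(seq_len(n), function(i) object_stats(pix[[i]], scale = scale))
  out <- do.call(rbind, rows)
  out$object_id <- seq_len(n)
  out <- out[c("object_id", setdiff(names(out), "object_id"))]
  class(out) <- c("object_set", "data.frame")
  out
}

empty_object_set <- function() {
  out <- data.frame(object_id = integer(0), x_anchor = integer(0),
                    y_anchor = integer(0), x_centroid = numeric(0),
                    y_centroid = numeric(0), x_min = integer(0),
                    y_min = integer(0), x_max = integer(0),
                    y_max = integer(0), width_px = integer(0),
                    height_px = integer(0), area_px = integer(0),
                    area_um2 = numeric(0), region_id = integer(0))
  out$pixels <- list()
  class(out) <- c("object_set", "data.frame")
  out
}

#' Statistics of one pixel cluster
#'
#' The anchor pixel is the raster-first member (minimum y, ties broken
#' by minimum x): it is the position used for the atlas-region lookup.
#' The centroid is the arithmetic mean of member coordinates; the
#' bounding box is tight and inclusive.
#'
#' @param pixels n x 2 matrix or data.frame of 0-based (x, y) pixel
#'   coordinates; must be non-empty.
#' @param scale optional [scale_spec()] for `area_um2`.
#' @return one-row data.frame with the columns of [extract_objects()]
#'   (minus `object_id`).
#' @export
object_stats <- function(pixels, scale = NULL) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("object_stats: empty pixel list")
  storage.mode(pixels) <- "integer"
  colnames(pixels) <- c("x", "y")
  x <- pixels[, 1]; y <- pixels[, 2]
  a <- which(y == min(y))
  a <- a[which.min(x[a])]
  data.frame(
    x_anchor = x[a], y_anchor = y[a],
    x_centroid = mean(x), y_centroid = mean(y),
    x_min = min(x), y_min = min(y), x_max = max(x), y_max = max(y),
    width_px = max(x) - min(x) + 1L, height_px = max(y) - min(y) + 1L,
    area_px = nrow(pixels),
    area_um2 = if (is.null(scale)) NA_real_
               else object_area_um2(nrow(pixels), scale),
    region_id = NA_integer_,
    pixels = I(list(pixels))
  )
}

#' @export
print.object_set <- function(x, ...) {
  cat("<object_set> ", nrow(x), " objects, ", sum(x$area_px),
      " member pixels\n", sep = "")
  print(as.data.frame(x)[setdiff(names(x), "pixels")], ...)
  invisible(x)
}

#' Partition objects by size
#'
#' Keeps objects whose pixel count lies in `[min_px, max_px]` (both
#' ends inclusive); rejected objects are retained for audit so that
#' kept and rejected always partition the input.
#'
#' @param objects an `object_set`.
#' @param min_px,max_px inclusive size bounds in pixels,
#'   `1 <= min_px <= max_px` (use `Inf` for no upper bound).
#' @return list with `kept` and `rejected` object sets.
#' @export
filter_by_size <- function(objects, min_px = 1L, max_px = Inf) {
  if (min_px < 1 || min_px > max_px)
    stop("filter_by_size: need 1 <= min_px <= max_px (got [",
         min_px, ", ", max_px, "])")
  keep <- objects$area_px >= min_px & objects$area_px <= max_px
  list(kept = objects[keep, , drop = FALSE],
       rejected = objects[!keep, , drop = FALSE])
}

#' Write the per-object table
#'
#' One CSV row per object, with its anchor, centroid, extents, areas
#' and assigned region.
#'
#' @param objects an `object_set` (region-assigned).
#' @param table a [label_table()] for acronyms (optional).
#' @param path output CSV path.
#' @export
write_object_table <- function(objects, path, table = NULL) {
  df <- as.data.frame(objects)[c("object_id", "x_anchor", "y_anchor",
                                 "x_centroid", "y_centroid", "width_px",
                                 "height_px", "area_px", "area_um2",
                                 "region_id")]
  df$region_acronym <-
    if (!is.null(table) && !anyNA(objects$region_id))
      region_info(table, objects$region_id)$acronym
    else NA_character_
  df$x_centroid <- signif(df$x_centroid, 6)
  df$y_centroid <- signif(df$y_centroid, 6)
  df$area_um2 <- signif(df$area_um2, 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
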