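# Mapping segmented pixels into 3D reference-atlas space.
#
# A section image is anchored in the atlas by three vectors: o points
# from the atlas origin to the image's top-left corner, u spans the
# image's width axis and v its height axis, all in atlas voxel units.
# A pixel (x, y) of a W x H image therefore maps to
#   o + u * ((x + 0.5) / W) + v * ((y + 0.5) / H)
# under the default pixel-centre convention (unbiased for areas); the
# corner convention x/W, y/H is selectable for byte-compatibility with
# tools that use it, and maps (0,0), (W,0), (0,H) to o, o+u, o+v
# exactly.

anchor_vectors <- function(anchor) {
  list(o = c(anchor$ox, anchor$oy, anchor$oz),
       u = c(anchor$ux, anchor$uy, anchor$uz),
       v = c(anchor$vx, anchor$vy, anchor$vz))
}

#' Transform section pixels to 3D atlas coordinates
#'
#' @param px n x 2 matrix (or length-2 vector) of 0-based pixel
#'   coordinates (x, y).
#' @param anchor one row of an `anchoring` data.frame (fields `width`,
#'   `height`, `ox..vz`).
#' @param convention `"centre"` (default; pixel centres, offset 0.5) or
#'   `"corner"` (pixel corners; (0,0) maps exactly to `o`).
#' @return n x 3 numeric matrix of atlas coordinates (columns x, y, z).
#' @export
pixel_to_atlas <- function(px, anchor, convention = c("centre", "corner")) {
  convention <- match.arg(convention)
  if (is.null(dim(px))) px <- matrix(px, ncol = 2L, byrow = TRUE)
  px <- as.matrix(px)
  w <- anchor$width; h <- anchor$height
  if (any(px[, 1] < 0 | px[, 1] > w | px[, 2] < 0 | px[, 2] > h) ||
      (convention == "centre" && any(px[, 1] >= w | px[, 2] >= h)))
    stop("pixel_to_atlas: pixel outside the ", w, "x", h, " anchored image")
  off <- if (convention == "centre") 0.5 else 0
  s <- (px[, 1] + off) / w
  t <- (px[, 2] + off) / h
  a <- anchor_vectors(anchor)
  out <- cbind(x = a$o[1] + a$u[1] * s + a$v[1] * t,
               y = a$o[2] + a$u[2] * s + a$v[2] * t,
               z = a$o[3] + a$u[3] * s + a$v[3] * t)
  rownames(out) <- NULL
  out
}

#' Atlas-space points of extracted objects
#'
#' With `granularity = "pixel"` one point is emitted per member pixel
#' (the full point cloud of the labelling); `"centroid"` emits a single
#' point per object at its transformed centroid.
#'
#' @param objects a region-assigned `object_set`.
#' @param anchor one row of an `anchoring` data.frame.
#' @param granularity `"pixel"` or `"centroid"`.
#' @param convention passed to [pixel_to_atlas()].
#' @return data.frame `x`, `y`, `z`, `region_id`, `section_key` in
#'   deterministic order (object id, then raster order of pixels).
#' @export
object_points <- function(objects, anchor,
                          granularity = c("pixel", "centroid"),
                          convention = c("centre", "corner")) {
  granularity <- match.arg(granularity)
  convention <- match.arg(convention)
  key <- if ("section_key" %in% names(anchor)) anchor$section_key else ""
  if (nrow(objects) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      region_id = integer(0), section_key = character(0)))
  if (granularity == "pixel") {
    px <- do.call(rbind, objects$pixels)
    # pixelwise points carry the region under each pixel when available,
    # falling back to the object's anchor region
    rid <- rep(objects$region_id, times = objects$area_px)
    xyz <- pixel_to_atlas(px, anchor, convention)
  } else {
    cen <- cbind(objects$x_centroid, objects$y_centroid)
    rid <- objects$region_id
    xyz <- pixel_to_atlas(cen, anchor, convention)
  }
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             region_id = rid, section_key = key,
             stringsAsFactors = FALSE)
}

#' Pixelwise atlas points with per-pixel region lookup
#'
#' Like [object_points()] at pixel granularity, but each point carries
#' the region under its own pixel (pixelwise attribution) rather than
#' the whole object's anchor region.
#'
#' @inheritParams object_points
#' @param map the section's `atlas_map` at segmentation dimensions.
#' @return data.frame as in [object_points()].
#' @export
pixel_points <- function(objects, anchor, map,
                         convention = c("centre", "corner")) {
  convention <- match.arg(convention)
  key <- if ("section_key" %in% names(anchor)) anchor$section_key else ""
  if (nrow(objects) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      region_id = integer(0), section_key = character(0)))
  px <- do.call(rbind, objects$pixels)
  rid <- unclass(map)[cbind(px[, 2] + 1L, px[, 1] + 1L)]
  xyz <- pixel_to_atlas(px, anchor, convention)
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             region_id = rid, section_key = key,
             stringsAsFactors = FALSE)
}

#' Export an atlas-space point cloud
#'
#' TSV: columns `x,y,z,region_id,section_key`.  JSON: one object per
#' region with the region's name, colour from the label table and a
#' flat `[x1,y1,z1,x2,...]` coordinate array, ready for atlas point
#' viewers.  Subsampling keeps every k-th point (deterministic, so
#' exports are reproducible).
#'
#' @param points data.frame from [object_points()] (rows in
#'   deterministic order).
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @param table a [label_table()]; required for JSON colours.
#' @param subsample keep every `subsample`-th point (>= 1).
#' @param unit coordinate unit recorded in the file metadata
#'   (`"voxel"` or `"um"`); coordinates are written as given.
#' @export
export_point_cloud <- function(points, path, format = c("tsv", "json"),
                               table = NULL, subsample = 1L,
                               unit = "voxel") {
  format <- match.arg(format)
  stopifnot(subsample >= 1L)
  if (subsample > 1L && nrow(points) > 0L)
    points <- points[seq(1L, nrow(points), by = subsample), , drop = FALSE]
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# unit=", unit), con)
    writeLines("x\ty\tz\tregion_id\tsection_key", con)
    if (nrow(points) > 0L)
      writeLines(sprintf("%.9g\t%.9g\t%.9g\t%d\t%s", points$x, points$y,
                         points$z, points$region_id, points$section_key),
                 con)
  } else {
    stopifnot(!is.null(table))
    ids <- sort(unique(points$region_id))
    groups <- lapply(ids, function(id) {
      info <- region_info(table, id)
      p <- points[points$region_id == id, , drop = FALSE]
      list(region_id = id, name = info$name,
           colour = c(info$red, info$green, info$blue),
           unit = unit,
           points = as.vector(t(as.matrix(p[c("x", "y", "z")]))))
    })
    jsonlite::write_json(groups, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a TSV point cloud
#' @param path TSV written by [export_point_cloud()].
#' @return data.frame `x,y,z,region_id,section_key`.
#' @export
read_point_cloud <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(x = "numeric", y = "numeric",
                                   z = "numeric", region_id = "integer",
                                   section_key = "character"))
}
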