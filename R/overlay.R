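# Overlay rendering: atlas regions in their table colours with the
# segmented objects painted on top, colour-coded by assigned region.

#' Overlay rendering style
#'
#' @param atlas_alpha opacity of the atlas colours over white, in
#'   [0, 1] (1 = solid atlas colours).
#' @param object_colour_mode `"by-region"` (objects take their assigned
#'   region's colour) or `"fixed"`.
#' @param object_colour RGB triple used in `"fixed"` mode.
#' @param boundary_colour RGB triple for region boundary pixels, or
#'   NULL to skip boundary drawing.
#' @return an `overlay_style` list.
#' @export
overlay_style <- function(atlas_alpha = 0.5,
                          object_colour_mode = c("by-region", "fixed"),
                          object_colour = c(255L, 0L, 0L),
                          boundary_colour = c(0L, 0L, 0L)) {
  object_colour_mode <- match.arg(object_colour_mode)
  stopifnot(atlas_alpha >= 0, atlas_alpha <= 1)
  structure(list(atlas_alpha = atlas_alpha,
                 object_colour_mode = object_colour_mode,
                 object_colour = as.integer(object_colour),
                 boundary_colour = if (is.null(boundary_colour)) NULL
                                   else as.integer(boundary_colour)),
            class = "overlay_style")
}

#' Boundary pixels of an atlas map
#'
#' A pixel is a boundary pixel when its label differs from its right or
#' lower 4-neighbour (one-sided comparison, so boundaries are one pixel
#' wide).
#'
#' @param map an `atlas_map`.
#' @return logical matrix of boundary membership.
#' @export
region_boundaries <- function(map) {
  m <- unclass(map)
  h <- nrow(m); w <- ncol(m)
  b <- matrix(FALSE, h, w)
  if (w > 1L) b[, -w] <- b[, -w] | (m[, -w] != m[, -1L])
  if (h > 1L) b[-h, ] <- b[-h, ] | (m[-h, ] != m[-1L, ])
  b
}

#' Render a section overlay image
#'
#' Background: atlas regions in their label-table colours, blended at
#' `atlas_alpha` over white.  Object pixels are painted in the colour
#' of their assigned region (or a fixed colour), and region boundaries
#' are drawn on top.  Rendering is deterministic: identical inputs give
#' bit-identical images.
#'
#' @param map an `atlas_map` at segmentation dimensions.
#' @param objects a region-assigned `object_set` (may be empty).
#' @param table a [label_table()] supplying region colours.
#' @param style an [overlay_style()].
#' @return integer RGB array `c(h, w, 3)`.
#' @export
render_overlay <- function(map, objects, table, style = overlay_style()) {
  h <- nrow(map); w <- ncol(map)
  j <- match(as.vector(unclass(map)), table$id)
  if (anyNA(j))
    stop("render_overlay: map holds ids absent from the label table")
  a <- style$atlas_alpha
  blend <- function(ch) as.integer(round(a * ch + (1 - a) * 255))
  img <- array(0L, dim = c(h, w, 3L))
  img[, , 1] <- blend(table$red[j])
  img[, , 2] <- blend(table$green[j])
  img[, , 3] <- blend(table$blue[j])
  if (nrow(objects) > 0L) {
    if (style$object_colour_mode == "by-region" && anyNA(objects$region_id))
      stop("render_overlay: objects lack region assignment")
    for (i in seq_len(nrow(objects))) {
      col <- if (style$object_colour_mode == "by-region") {
        info <- region_info(table, objects$region_id[i])
        c(info$red, info$green, info$blue)
      } else style$object_colour
      px <- objects$pixels[[i]]
      for (c in 1:3)
        img[cbind(px[, 2] + 1L, px[, 1] + 1L, c)] <- col[c]
    }
  }
  if (!is.null(style$boundary_colour)) {
    b <- which(region_boundaries(map))
    if (length(b)) {
      yy <- (b - 1L) %% h + 1L
      xx <- (b - 1L) %/% h + 1L
      for (c in 1:3) img[cbind(yy, xx, c)] <- style$boundary_colour[c]
    }
  }
  img
}

#' Render and write one section overlay PNG
#'
#' @inheritParams render_overlay
#' @param dir output directory.
#' @param section_key section identifier used in the filename
#'   `<section_key>_overlay.png`.
#' @return the written path, invisibly.
#' @export
write_overlay <- function(map, objects, table, section_key, dir,
                          style = overlay_style()) {
  img <- render_overlay(map, objects, table, style)
  path <- file.path(dir, paste0(section_key, "_overlay.png"))
  write_png(img, path)
  invisible(path)
}
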