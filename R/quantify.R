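# Regional quantification: combine extracted objects with the section's
# atlas map to produce per-region and whole-section reports.
#
# Two attribution rules coexist.  The anchor rule assigns a whole object
# to the region under its raster-first (top-left) pixel and is the rule
# used for object COUNTS.  The pixelwise rule credits every member pixel
# to the region under that pixel and is the default for object AREAS and
# loads, since load is defined as labelled area within the region
# divided by region area.  The two agree exactly whenever no object
# straddles a region boundary; reports can be switched to either rule.

#' Pixel area of every region in an atlas map
#'
#' @param map an `atlas_map`.
#' @return named integer vector: region id -> pixel count; sums to
#'   `width * height`.
#' @export
region_pixel_areas <- function(map) {
  v <- as.vector(unclass(map))
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))
}

#' Assign objects to atlas regions by the top-left-pixel rule
#'
#' Each object's region is the atlas label under its anchor pixel.  The
#' map must already be at segmentation dimensions; an anchor outside
#' the map signals unmatched dimensions and is an error.
#'
#' @param objects an `object_set`.
#' @param map an `atlas_map` at segmentation dimensions.
#' @return the object set with `region_id` filled in.
#' @export
assign_object_region <- function(objects, map) {
  if (nrow(objects) == 0L) return(objects)
  h <- nrow(map); w <- ncol(map)
  bad <- objects$x_anchor < 0L | objects$x_anchor >= w |
    objects$y_anchor < 0L | objects$y_anchor >= h
  if (any(bad))
    stop("assign_object_region: anchor (", objects$x_anchor[which(bad)[1]],
         ",", objects$y_anchor[which(bad)[1]], ") outside the ", w, "x", h,
         " atlas map; are segmentation and map dimensions matched?")
  objects$region_id <-
    unclass(map)[cbind(objects$y_anchor + 1L, objects$x_anchor + 1L)]
  objects
}

#' Labelled pixel area per region, pixelwise attribution
#'
#' Credits each member pixel of each object to the region under that
#' pixel, independent of the object's anchor.
#'
#' @param objects an `object_set`.
#' @param map an `atlas_map` at segmentation dimensions.
#' @return named integer vector: region id -> labelled pixel count;
#'   sums to the total member pixels of `objects`.
#' @export
pixelwise_region_areas <- function(objects, map) {
  if (nrow(objects) == 0L)
    return(stats::setNames(integer(0), character(0)))
  px <- do.call(rbind, objects$pixels)
  h <- nrow(map); w <- ncol(map)
  if (any(px[, 1] < 0L | px[, 1] >= w | px[, 2] < 0L | px[, 2] >= h))
    stop("pixelwise_region_areas: object pixel outside the atlas map")
  ids <- unclass(map)[cbind(px[, 2] + 1L, px[, 1] + 1L)]
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build per-region reports for one section
#'
#' @param objects a filtered, region-assigned `object_set`.
#' @param map the section's `atlas_map` at segmentation dimensions.
#' @param table a [label_table()].
#' @param scale a [scale_spec()] converting pixels to um^2.
#' @param attribution `"pixel"` (default: areas credited to the region
#'   under each pixel) or `"anchor"` (whole-object areas credited to
#'   the anchor region).  Object counts always follow the anchor rule.
#' @param include_zero if TRUE, emit a row for every table region even
#'   with zero pixel area (load flagged NA).
#' @return a `region_report` data.frame with columns `region_id`,
#'   `name`, `acronym`, `region_area_px`, `region_area_um2`,
#'   `object_count`, `object_area_px`, `object_area_um2`, `load`.
#'   `load = object_area_px / region_area_px`; regions with zero area
#'   get `load = NA` (flagged, never silently dropped into the maths).
#' @export
build_region_reports <- function(objects, map, table, scale,
                                 attribution = c("pixel", "anchor"),
                                 include_zero = FALSE) {
  attribution <- match.arg(attribution)
  areas <- region_pixel_areas(map)
  ids <- as.integer(names(areas))
  if (include_zero) {
    extra <- setdiff(table$id, ids)
    ids <- c(ids, extra)
    areas <- c(areas, stats::setNames(integer(length(extra)), extra))
  }
  ord <- order(ids)
  ids <- ids[ord]; areas <- as.integer(areas[ord])
  counts <- integer(length(ids))
  obj_px <- integer(length(ids))
  if (nrow(objects) > 0L) {
    if (anyNA(objects$region_id))
      stop("build_region_reports: objects have no region assignment; ",
           "run assign_object_region() first")
    ct <- table(objects$region_id)
    j <- match(as.integer(names(ct)), ids)
    if (anyNA(j))
      stop("build_region_reports: object assigned to region absent from map")
    counts[j] <- as.integer(ct)
    if (attribution == "pixel") {
      pw <- pixelwise_region_areas(objects, map)
      k <- match(as.integer(names(pw)), ids)
      obj_px[k] <- as.integer(pw)
    } else {
      ar <- tapply(objects$area_px, objects$region_id, sum)
      k <- match(as.integer(names(ar)), ids)
      obj_px[k] <- as.integer(ar)
    }
  }
  info <- region_info(table, ids)
  ppx <- pixel_area_um2(scale)
  rep <- data.frame(
    region_id = ids, name = info$name, acronym = info$acronym,
    region_area_px = areas, region_area_um2 = areas * ppx,
    object_count = counts, object_area_px = obj_px,
    object_area_um2 = obj_px * ppx,
    load = ifelse(areas > 0L, obj_px / areas, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(rep, "attribution") <- attribution
  class(rep) <- c("region_report", "data.frame")
  rep
}

#' Whole-section summary row
#'
#' Pools all regions of a report (optionally excluding some, e.g. the
#' outside-brain background) into one row with `region_id = -1`; the
#' summary load is total labelled area over total pooled region area.
#'
#' @param report a `region_report`.
#' @param exclude region ids removed from both numerator and
#'   denominator (default none).
#' @return one-row data.frame in report schema.
#' @export
summarize_report <- function(report, exclude = integer(0)) {
  r <- report[!(report$region_id %in% exclude), , drop = FALSE]
  data.frame(
    region_id = -1L, name = "WHOLE SECTION", acronym = "ALL",
    region_area_px = sum(r$region_area_px),
    region_area_um2 = sum(r$region_area_um2),
    object_count = sum(r$object_count),
    object_area_px = sum(r$object_area_px),
    object_area_um2 = sum(r$object_area_um2),
    load = if (sum(r$region_area_px) > 0)
      sum(r$object_area_px) / sum(r$region_area_px) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Custom region grouping specification
#'
#' @param groups named list: group name -> integer vector of member
#'   region ids.  Groups must be pairwise disjoint.
#' @param excluded region ids removed from whole-brain summaries;
#'   disjoint from all groups.
#' @return a `custom_regions` object.
#' @export
custom_regions <- function(groups = list(), excluded = integer(0)) {
  groups <- lapply(groups, function(g) as.integer(g))
  excluded <- as.integer(excluded)
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("custom_regions: groups must be pairwise disjoint (id ",
         all_members[duplicated(all_members)][1], " repeated)")
  if (length(intersect(all_members, excluded)))
    stop("custom_regions: excluded ids overlap group members")
  structure(list(groups = groups, excluded = excluded),
            class = "custom_regions")
}

#' Read a custom-region grouping CSV
#'
#' Schema: `group_name,member_ids` with member ids separated by
#' semicolons.  A member written `+ID` expands to ID and all its
#' descendants in the label-table hierarchy.  The pseudo-group
#' `EXCLUDE` lists regions removed from whole-brain summaries.
#'
#' @param path CSV path.
#' @param table a [label_table()] used to validate ids and expand
#'   `+ID` descendant members.
#' @return a [custom_regions()] object.
#' @export
read_custom_regions <- function(path, table) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("group_name", "member_ids") %in% names(df)))
    stop("custom region file must have columns group_name,member_ids")
  parse_members <- function(s) {
    toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    unlist(lapply(toks, function(t) {
      if (startsWith(t, "+")) {
        id <- as.integer(substring(t, 2))
        check_known(id)
        region_descendants(table, id)
      } else {
        id <- as.integer(t)
        check_known(id)
        id
      }
    }))
  }
  check_known <- function(id) {
    if (is.na(id) || !(id %in% table$id))
      stop("custom region file: unknown region id '", id, "'")
  }
  groups <- list(); excluded <- integer(0)
  for (i in seq_len(nrow(df))) {
    ids <- parse_members(df$member_ids[i])
    if (identical(df$group_name[i], "EXCLUDE")) excluded <- c(excluded, ids)
    else groups[[df$group_name[i]]] <- c(groups[[df$group_name[i]]], ids)
  }
  custom_regions(groups, excluded)
}

#' All descendants of a region in the hierarchy (including itself)
#' @param table a [label_table()].
#' @param id root region id.
#' @return integer vector of ids.
#' @export
region_descendants <- function(table, id) {
  out <- as.integer(id)
  repeat {
    kids <- table$id[!is.na(table$parent_id) & table$parent_id %in% out &
                       !(table$id %in% out)]
    if (!length(kids)) break
    out <- c(out, kids)
  }
  out
}

#' Merge and exclude regions in a report
#'
#' Group rows are pooled area-weighted: the group load is the summed
#' labelled area over the summed region area, NOT the mean of member
#' loads.  Excluded regions are dropped from the report (and hence
#' from any whole-brain summary built from it).  Regions in no group
#' pass through unchanged.
#'
#' @param report a `region_report`.
#' @param spec a [custom_regions()] object.
#' @param table a [label_table()] used to validate spec ids.
#' @return merged `region_report`; grouped rows carry negative
#'   synthetic ids (-101, -102, ...) and the group name.
#' @export
apply_custom_regions <- function(report, spec, table) {
  stopifnot(inherits(spec, "custom_regions"))
  unknown <- setdiff(c(unlist(spec$groups), spec$excluded), table$id)
  if (length(unknown))
    stop("apply_custom_regions: spec references unknown id(s): ",
         paste(unknown, collapse = ", "))
  out <- report[!(report$region_id %in% spec$excluded), , drop = FALSE]
  grouped <- integer(0)
  rows <- list()
  for (i in seq_along(spec$groups)) {
    ids <- spec$groups[[i]]
    sel <- out[out$region_id %in% ids, , drop = FALSE]
    grouped <- c(grouped, ids)
    if (nrow(sel) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = -100L - i, name = names(spec$groups)[i],
      acronym = names(spec$groups)[i],
      region_area_px = sum(sel$region_area_px),
      region_area_um2 = sum(sel$region_area_um2),
      object_count = sum(sel$object_count),
      object_area_px = sum(sel$object_area_px),
      object_area_um2 = sum(sel$object_area_um2),
      load = if (sum(sel$region_area_px) > 0)
        sum(sel$object_area_px) / sum(sel$region_area_px) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- out[!(out$region_id %in% grouped), , drop = FALSE]
  out <- rbind(out, do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "attribution") <- attr(report, "attribution")
  class(out) <- c("region_report", "data.frame")
  out
}

#' Aggregate per-section reports into a series report
#'
#' Per-region pixel areas, object counts and labelled areas are summed
#' across sections; the series load of a region is its pooled labelled
#' area over its pooled region area (sections in which a region is
#' absent contribute nothing to its denominator).
#'
#' @param reports list of `region_report`s sharing one label table.
#' @return a `region_report` for the pooled series.
#' @export
aggregate_series <- function(reports) {
  stopifnot(length(reports) >= 1L)
  all <- do.call(rbind, lapply(reports, as.data.frame))
  nm <- unique(all[c("region_id", "name", "acronym")])
  if (anyDuplicated(nm$region_id))
    stop("aggregate_series: inconsistent label tables across sections ",
         "(one region id maps to several names)")
  agg <- function(col) tapply(all[[col]], all$region_id, sum)
  a <- agg("region_area_px")
  ids <- as.integer(names(a))
  out <- data.frame(
    region_id = ids,
    name = nm$name[match(ids, nm$region_id)],
    acronym = nm$acronym[match(ids, nm$region_id)],
    region_area_px = as.integer(a),
    region_area_um2 = as.numeric(agg("region_area_um2")),
    object_count = as.integer(agg("object_count")),
    object_area_px = as.integer(agg("object_area_px")),
    object_area_um2 = as.numeric(agg("object_area_um2")),
    stringsAsFactors = FALSE
  )
  out$load <- ifelse(out$region_area_px > 0,
                     out$object_area_px / out$region_area_px, NA_real_)
  out <- out[order(out$region_id), ]
  rownames(out) <- NULL
  class(out) <- c("region_report", "data.frame")
  out
}

#' Write a region report CSV
#'
#' Floats with 6 significant digits, pixel counts exact; a whole-
#' section summary row (`region_id = -1`) is appended.
#'
#' @param report a `region_report`.
#' @param path output CSV path.
#' @param exclude region ids left out of the summary row (e.g. the
#'   outside-brain background).
#' @export
write_region_report <- function(report, path, exclude = integer(0)) {
  out <- rbind(as.data.frame(report), summarize_report(report, exclude))
  for (col in c("region_area_um2", "object_area_um2", "load"))
    out[[col]] <- signif(out[[col]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stereological point-grid area-fraction estimate
#'
#' Reimplements the area-fraction fractionator probe used to validate
#' segmentation-based loads: counting frames are laid out at a fixed
#' grid period across the section, test points are placed at a fixed
#' spacing inside each frame, and the area fraction is estimated as
#' the fraction of points that hit labelled material.  Defaults follow
#' common practice for plaque-load estimation: 300 x 300 um grid,
#' 200 x 200 um frame, 20 um point spacing.
#'
#' @param mask a `seg_mask` at segmentation resolution.
#' @param scale a [scale_spec()] giving um per segmentation pixel.
#' @param grid_um sampling-grid period (x, y) in um.
#' @param frame_um counting-frame extent (x, y) in um; must not exceed
#'   the grid period.
#' @param point_um test-point spacing in um within each frame.
#' @return list with `fraction` (NA-flagged when no point falls on the
#'   section), `n_points`, `n_positive`, and the binomial `se`.
#' @export
point_grid_area_fraction <- function(mask, scale,
                                     grid_um = c(300, 300),
                                     frame_um = c(200, 200),
                                     point_um = 20) {
  stopifnot(all(grid_um > 0), all(frame_um > 0), point_um > 0,
            all(frame_um <= grid_um))
  um_per_px <- scale$base_pixel_size / scale$resize_factor
  w_um <- ncol(mask) * um_per_px
  h_um <- nrow(mask) * um_per_px
  if (w_um < frame_um[1] || h_um < frame_um[2])
    return(list(fraction = NA_real_, n_points = 0L, n_positive = 0L,
                se = NA_real_))
  fx <- seq(0, w_um - frame_um[1], by = grid_um[1])
  fy <- seq(0, h_um - frame_um[2], by = grid_um[2])
  px_off <- seq(point_um / 2, frame_um[1], by = point_um)
  py_off <- seq(point_um / 2, frame_um[2], by = point_um)
  px_off <- px_off[px_off < frame_um[1]]
  py_off <- py_off[py_off < frame_um[2]]
  if (!length(fx) || !length(fy) || !length(px_off) || !length(py_off))
    return(list(fraction = NA_real_, n_points = 0L, n_positive = 0L,
                se = NA_real_))
  xs <- as.vector(outer(fx, px_off, `+`))
  ys <- as.vector(outer(fy, py_off, `+`))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  cx <- pmin(floor(gx / um_per_px), ncol(mask) - 1L) + 1L
  cy <- pmin(floor(gy / um_per_px), nrow(mask) - 1L) + 1L
  hit <- unclass(mask)[cbind(cy, cx)]
  n <- length(hit)
  p <- mean(hit)
  list(fraction = p, n_points = n, n_positive = sum(hit),
       se = sqrt(p * (1 - p) / n))
}
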