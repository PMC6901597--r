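# Synthetic test scenes with exactly known ground truth.
#
# A scene is a test double for one registered, segmented brain section:
# a small label table (two-level hierarchy), an atlas map tiled into
# vertical region bands with one concave region (a notch of one band
# carved into its neighbour, so boundary rendering and pixelwise
# attribution are exercised), planted objects grown as irregular random
# blobs (region growing, not discs, so connected-component code faces
# plaque-like shapes), and a randomized planar anchoring.  Objects are
# planted with a one-pixel Chebyshev clearance from each other, and are
# grown by 4-neighbour steps, so extraction recovers them identically
# under both 4- and 8-connectivity.  Everything is derived from one
# seed and regenerates bit-identically.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

fixture_label_table <- function(n_regions) {
  stopifnot(n_regions >= 2L, n_regions <= 200L)
  i <- seq_len(n_regions)
  kids <- data.frame(
    id = i,
    name = paste0("Region ", i),
    acronym = paste0("R", i),
    red = i, green = (i * 7L) %% 256L, blue = (i * 13L) %% 256L,
    parent_id = ifelse(i <= ceiling(n_regions / 2), 1001L, 1002L)
  )
  parents <- data.frame(
    id = c(1001L, 1002L), name = c("Anterior group", "Posterior group"),
    acronym = c("ANT", "POST"), red = c(255L, 255L),
    green = c(250L, 245L), blue = c(250L, 245L),
    parent_id = c(NA_integer_, NA_integer_)
  )
  bg <- data.frame(id = 0L, name = "background", acronym = "bg",
                   red = 0L, green = 0L, blue = 0L,
                   parent_id = NA_integer_)
  label_table(rbind(bg, parents, kids))
}

fixture_atlas_map <- function(width, height, n_regions) {
  # vertical bands; band 1 made concave by carving a notch of region 2
  # into its middle
  band <- pmin(floor((seq_len(width) - 1L) * n_regions / width) + 1L,
               n_regions)
  m <- matrix(rep(band, each = height), nrow = height)
  bw <- max(ceiling(width / n_regions), 2L)
  nx <- max(1L, bw %/% 3L):max(2L, (2L * bw) %/% 3L)
  ny <- (height %/% 3L):(2L * height %/% 3L)
  m[ny + 1L, nx + 1L] <- 2L
  new_atlas_map(m)
}

blob_neighbours <- function(idx, h, n) {
  # in-bounds 4-neighbours of a set of matrix indices
  y <- (idx - 1L) %% h
  cand <- c(idx[y > 0L] - 1L, idx[y < h - 1L] + 1L, idx - h, idx + h)
  unique(cand[cand >= 1L & cand <= n])
}

grow_blob <- function(free, target, seed_idx, region = NULL, map = NULL) {
  # 4-neighbour stochastic region growing from seed_idx over the `free`
  # matrix; optionally confined to one atlas region.  Returns a vector
  # of matrix indices or NULL if growth stalls below target.
  h <- nrow(free)
  n <- length(free)
  ok <- function(idx) {
    k <- free[idx]
    if (!is.null(region)) k <- k & map[idx] == region
    k
  }
  if (!ok(seed_idx)) return(NULL)
  pix <- seed_idx
  inblob <- rep(FALSE, n)
  inblob[seed_idx] <- TRUE
  while (length(pix) < target) {
    cand <- blob_neighbours(pix, h, n)
    cand <- cand[!inblob[cand]]
    cand <- cand[ok(cand)]
    if (!length(cand)) return(NULL)
    add <- cand[sample.int(length(cand), 1L)]
    pix <- c(pix, add)
    inblob[add] <- TRUE
  }
  pix
}

chebyshev_block <- function(free, idx, h) {
  # mark idx and its 8-neighbourhood as unavailable
  y <- (idx - 1L) %% h
  n <- length(free)
  nb <- c(idx,
          idx[y > 0L] - 1L, idx[y < h - 1L] + 1L,
          idx - h, idx + h,
          idx[y > 0L] - h - 1L, idx[y > 0L] + h - 1L,
          idx[y < h - 1L] - h + 1L, idx[y < h - 1L] + h + 1L)
  nb <- nb[nb >= 1L & nb <= n]
  free[nb] <- FALSE
  free
}

#' Generate one synthetic section scene
#'
#' @param seed RNG seed; the whole scene is a pure function of it.
#' @param width,height scene dimensions in pixels.
#' @param n_regions number of atlas regions tiled across the map.
#' @param n_objects number of planted objects.
#' @param object_size_range inclusive pixel-size range objects are
#'   drawn from.
#' @param straddle_fraction fraction of objects deliberately planted
#'   across a region boundary (exercises the divergence between
#'   anchor-rule and pixelwise attribution).
#' @param table optional shared [label_table()] (for series).
#' @param section_index 0-based position within a series; shifts the
#'   anchoring origin along the sectioning axis.
#' @param section_spacing anchoring advance per section, voxel units.
#' @param drift s.d. of the jitter applied to the anchoring vectors.
#' @return a `synthetic_scene` list: `table`, `map`, `seg` (RGB array),
#'   `mask`, `object_pixels` (list of n x 2 matrices), `object_colour`,
#'   `anchor` (one-row `anchoring`), `truth` (per-region ground truth
#'   under both attribution rules), `section_key`, `params`.
#' @export
make_scene <- function(seed, width = 128L, height = 128L, n_regions = 4L,
                       n_objects = 10L, object_size_range = c(8L, 60L),
                       straddle_fraction = 0, table = NULL,
                       section_index = 0L, section_spacing = 2.5,
                       drift = 0) {
  stopifnot(width >= 16L, height >= 16L, n_objects >= 0L,
            straddle_fraction >= 0, straddle_fraction <= 1,
            object_size_range[1] >= 1L,
            object_size_range[1] <= object_size_range[2])
  if (is.null(table)) table <- fixture_label_table(n_regions)
  map <- fixture_atlas_map(width, height, n_regions)
  m <- unclass(map)
  with_local_seed(seed, {
    n_straddle <- round(straddle_fraction * n_objects)
    boundary <- which(region_boundaries(map) & m > 0L)
    free <- matrix(TRUE, height, width)
    # keep a 1-px image margin clear so bounding boxes are interior
    free[c(1L, height), ] <- FALSE
    free[, c(1L, width)] <- FALSE
    pixels <- vector("list", n_objects)
    for (i in seq_len(n_objects)) {
      want_straddle <- i <= n_straddle
      target <- sample(object_size_range[1]:object_size_range[2], 1L)
      blob <- NULL
      for (try in 1:200) {
        seed_idx <- if (want_straddle) {
          cand <- boundary[free[boundary]]
          if (!length(cand)) break
          cand[sample.int(length(cand), 1L)]
        } else {
          cand <- which(free)
          cand[sample.int(length(cand), 1L)]
        }
        blob <- grow_blob(free, target, seed_idx,
                          region = if (want_straddle) NULL else m[seed_idx],
                          map = if (want_straddle) NULL else m)
        if (!is.null(blob) && want_straddle &&
            length(unique(m[blob])) < 2L) blob <- NULL
        if (!is.null(blob)) break
      }
      if (is.null(blob))
        stop("make_scene: could not place object ", i, " of ", n_objects,
             " (scene too crowded for size ", target, ")")
      pixels[[i]] <- blob
      free <- chebyshev_block(free, blob, height)
    }
    # anchoring: serial sectioning advances o along the atlas y axis
    jit <- function(n) if (drift > 0) stats::rnorm(n, 0, drift) else
      stats::runif(n, -0.05, 0.05)
    key <- sprintf("%d", section_index * 4L + 2L)  # every-4th sampling
    anchor <- data.frame(
      section_key = key,
      filename = sprintf("seg_s%03d.png", section_index * 4L + 2L),
      width = as.numeric(width), height = as.numeric(height),
      ox = 39 + jit(1), oy = 3 + section_index * section_spacing + jit(1),
      oz = 62 + jit(1),
      ux = -34 + jit(1), uy = jit(1), uz = jit(1),
      vx = jit(1), vy = jit(1), vz = -28 + jit(1),
      stringsAsFactors = FALSE
    )
    class(anchor) <- c("anchoring", "data.frame")
    object_colour <- c(255L, 0L, 255L)
    seg <- array(255L, dim = c(height, width, 3L))
    mask <- matrix(FALSE, height, width)
    for (blob in pixels) {
      mask[blob] <- TRUE
      seg[blob] <- object_colour[1]                     # channel 1 plane
      seg[blob + height * width] <- object_colour[2]
      seg[blob + 2L * height * width] <- object_colour[3]
    }
    obj_xy <- lapply(pixels, function(idx) {
      xy <- cbind(x = (idx - 1L) %/% height, y = (idx - 1L) %% height)
      xy[order(xy[, "y"], xy[, "x"]), , drop = FALSE]
    })
    # object list in raster order of anchor pixels, as extraction numbers
    anc <- t(vapply(obj_xy, function(p) p[1L, ], c(x = 0L, y = 0L)))
    obj_xy <- obj_xy[order(anc[, "y"], anc[, "x"])]
    truth <- scene_truth(obj_xy, m)
    structure(list(table = table, map = map, seg = seg,
                   mask = seg_mask(mask, object_colour),
                   object_pixels = obj_xy, object_colour = object_colour,
                   anchor = anchor, truth = truth, section_key = key,
                   params = list(seed = seed, width = width, height = height,
                                 n_regions = n_regions,
                                 n_objects = n_objects,
                                 object_size_range = object_size_range,
                                 straddle_fraction = straddle_fraction,
                                 drift = drift)),
              class = "synthetic_scene")
  })
}

scene_truth <- function(obj_xy, m) {
  region_area <- table(as.vector(m))
  ids <- sort(as.integer(names(region_area)))
  area <- as.integer(region_area[as.character(ids)])
  count <- stats::setNames(integer(length(ids)), ids)
  a_anchor <- count
  a_pixel <- count
  for (p in obj_xy) {
    rid_anchor <- as.character(m[cbind(p[1L, "y"] + 1L, p[1L, "x"] + 1L)])
    count[rid_anchor] <- count[rid_anchor] + 1L
    a_anchor[rid_anchor] <- a_anchor[rid_anchor] + nrow(p)
    split <- table(m[cbind(p[, "y"] + 1L, p[, "x"] + 1L)])
    a_pixel[names(split)] <- a_pixel[names(split)] + as.integer(split)
  }
  data.frame(region_id = ids, region_area_px = area,
             object_count = as.integer(count),
             object_area_px_anchor = as.integer(a_anchor),
             object_area_px_pixel = as.integer(a_pixel),
             load_anchor = ifelse(area > 0, a_anchor / area, NA_real_),
             load_pixel = ifelse(area > 0, a_pixel / area, NA_real_))
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene> ", x$params$width, "x", x$params$height, " px, ",
      nrow(x$truth), " regions, ", length(x$object_pixels),
      " planted objects (seed ", x$params$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate a synthetic serial-section series
#'
#' Sections share one label table; anchoring origins advance along the
#' sectioning axis at `section_spacing` (emulating serial coronal
#' sampling), with optional per-section jitter (`drift`).  A pooled
#' per-region ground truth over all sections is included.
#'
#' @param seed series seed; per-section seeds are derived from it.
#' @param n_sections number of sections (>= 1).
#' @param ... passed to [make_scene()] (dimensions, object counts, ...).
#' @param drift s.d. of anchoring jitter across sections.
#' @return a `synthetic_series` list: `scenes` (list of scenes),
#'   `table`, `anchors` (combined `anchoring`), `truth` (pooled
#'   per-region ground truth), `per_section_truth`.
#' @export
make_series <- function(seed, n_sections = 5L, ..., drift = 0) {
  stopifnot(n_sections >= 1L)
  sub <- with_local_seed(seed, sample.int(2^20, n_sections))
  args <- list(...)
  n_regions <- if (is.null(args$n_regions)) 4L else args$n_regions
  table <- fixture_label_table(n_regions)
  scenes <- lapply(seq_len(n_sections), function(i) {
    do.call(make_scene, c(list(seed = sub[i], table = table,
                               section_index = i - 1L, drift = drift),
                          args))
  })
  anchors <- do.call(rbind, lapply(scenes, function(s) s$anchor))
  class(anchors) <- c("anchoring", "data.frame")
  per <- lapply(scenes, function(s) s$truth)
  pooled <- do.call(rbind, per)
  agg <- function(col) tapply(pooled[[col]], pooled$region_id, sum)
  ids <- sort(unique(pooled$region_id))
  truth <- data.frame(
    region_id = ids,
    region_area_px = as.integer(agg("region_area_px")[as.character(ids)]),
    object_count = as.integer(agg("object_count")[as.character(ids)]),
    object_area_px_anchor =
      as.integer(agg("object_area_px_anchor")[as.character(ids)]),
    object_area_px_pixel =
      as.integer(agg("object_area_px_pixel")[as.character(ids)])
  )
  truth$load_anchor <- truth$object_area_px_anchor / truth$region_area_px
  truth$load_pixel <- truth$object_area_px_pixel / truth$region_area_px
  structure(list(scenes = scenes, table = table, anchors = anchors,
                 truth = truth, per_section_truth = per, seed = seed),
            class = "synthetic_series")
}

#' Write a synthetic series as a ready-to-run input tree
#'
#' Creates `segmentations/`, `atlas/`, `label_table.csv`,
#' `anchoring.xml` and `ground_truth.csv` under `dir`, in the formats
#' the quantification pipeline consumes.
#'
#' @param series a `synthetic_series` (a single `synthetic_scene` is
#'   also accepted).
#' @param dir output directory (created if needed).
#' @param atlas_format `"colour"` (PNG) or `"raw"` (QMAP).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir, atlas_format = c("colour", "raw")) {
  atlas_format <- match.arg(atlas_format)
  if (inherits(series, "synthetic_scene"))
    series <- structure(list(scenes = list(series), table = series$table,
                             anchors = series$anchor, truth = series$truth,
                             per_section_truth = list(series$truth)),
                        class = "synthetic_series")
  dir.create(file.path(dir, "segmentations"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "atlas"), showWarnings = FALSE)
  write_label_table(series$table, file.path(dir, "label_table.csv"))
  write_anchoring(series$anchors, file.path(dir, "anchoring.xml"))
  ext <- if (atlas_format == "colour") "png" else "qmap"
  for (s in series$scenes) {
    write_png(s$seg, file.path(dir, "segmentations",
                               sprintf("seg_s%s.png", s$section_key)))
    write_atlas_map(s$map,
                    file.path(dir, "atlas",
                              sprintf("atlas_s%s.%s", s$section_key, ext)),
                    table = series$table, mode = atlas_format)
  }
  gt <- do.call(rbind, lapply(seq_along(series$scenes), function(i) {
    cbind(section_key = series$scenes[[i]]$section_key,
          series$per_section_truth[[i]])
  }))
  gt <- rbind(gt, cbind(section_key = "SERIES", series$truth))
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
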