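sc1 <- scale_spec(1, 1)

test_that("region_pixel_areas counts every pixel once", {
  m <- atlasquant:::new_atlas_map(matrix(0L, 4, 4))
  expect_equal(region_pixel_areas(m), c("0" = 16L))
  m2 <- atlasquant:::new_atlas_map(matrix(c(1L, 2L, 1L, 0L), 2))
  expect_equal(region_pixel_areas(m2), c("0" = 1L, "1" = 2L, "2" = 1L))
  set.seed(11)
  r <- matrix(sample(0:6, 256, TRUE), 16)
  got <- region_pixel_areas(atlasquant:::new_atlas_map(r))
  # independent per-pixel tally
  want <- vapply(sort(unique(as.vector(r))),
                 function(id) sum(r == id), 0L)
  expect_equal(unname(got), want)
  expect_equal(sum(got), 256L)
})

test_that("anchor rule assigns the whole object to the top-left pixel's region", {
  map <- half_map(8L, 8L)                 # left 4 cols region 1, right region 2
  # object anchored in region 1 at (3,1) but 90% of pixels in region 2
  px <- cbind(x = c(3L, 4L, 5L, 6L, 7L, 4L, 5L, 6L, 7L, 4L),
              y = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L))
  obs <- assign_object_region(
    structure(object_stats(px), class = c("object_set", "data.frame")), map)
  expect_equal(obs$region_id, 1L)
  # fully inside region 2
  obs2 <- assign_object_region(
    structure(object_stats(cbind(x = 5:6, y = c(4L, 4L))),
              class = c("object_set", "data.frame")), map)
  expect_equal(obs2$region_id, 2L)
  # anchor outside the map signals a geometry error
  obs3 <- structure(object_stats(cbind(10L, 0L)),
                    class = c("object_set", "data.frame"))
  expect_error(assign_object_region(obs3, half_map(8L, 8L)),
               "outside the 8x8 atlas map")
})

test_that("pixelwise attribution splits straddling objects by pixel", {
  map <- half_map(4L, 4L)
  px <- cbind(x = 0:3, y = rep(1L, 4L))   # 2 px region 1, 2 px region 2
  obs <- structure(object_stats(px), class = c("object_set", "data.frame"))
  expect_equal(pixelwise_region_areas(obs, map), c("1" = 2L, "2" = 2L))
  expect_length(pixelwise_region_areas(atlasquant:::empty_object_set(), map),
                0L)
})

test_that("pixelwise attribution equals a brute-force per-pixel lookup", {
  set.seed(12)
  s <- make_scene(5, width = 64L, height = 64L, n_objects = 6L,
                  straddle_fraction = 0.5)
  obs <- extract_objects(s$mask)
  got <- pixelwise_region_areas(obs, s$map)
  m <- unclass(s$map)
  want <- table(m[which(unclass(s$mask))])
  expect_equal(unname(got), as.integer(want))
  expect_equal(names(got), names(want))
  expect_equal(sum(got), sum(s$mask))     # conservation
})

test_that("region reports carry counts, areas and loads", {
  tab <- tiny_table()
  map <- atlasquant:::new_atlas_map(matrix(1L, 10, 10))
  px <- cbind(x = c(2:5, 2:4), y = c(rep(2L, 4L), rep(3L, 3L)))  # 7 px
  obs <- assign_object_region(
    structure(object_stats(px), class = c("object_set", "data.frame")), map)
  rep <- build_region_reports(obs, map, tab, sc1)
  expect_equal(rep$region_id, 1L)
  expect_equal(rep$object_count, 1L)
  expect_equal(rep$object_area_px, 7L)
  expect_equal(rep$load, 0.07)
  # no objects -> all loads zero
  rep0 <- build_region_reports(atlasquant:::empty_object_set(), map, tab, sc1)
  expect_true(all(rep0$load == 0))
})

test_that("anchor and pixel attributions agree for interior objects", {
  s <- make_scene(21, straddle_fraction = 0)
  obs <- assign_object_region(extract_objects(s$mask), s$map)
  ra <- build_region_reports(obs, s$map, s$table, sc1, attribution = "anchor")
  rp <- build_region_reports(obs, s$map, s$table, sc1, attribution = "pixel")
  expect_identical(ra$object_area_px, rp$object_area_px)
  expect_identical(ra$load, rp$load)
})

test_that("whole-section summary equals the overall labelled fraction", {
  s <- make_scene(22, straddle_fraction = 0.4)
  obs <- assign_object_region(extract_objects(s$mask), s$map)
  rep <- build_region_reports(obs, s$map, s$table, sc1)
  tot <- summarize_report(rep)
  expect_equal(tot$region_id, -1L)
  expect_equal(tot$load, sum(s$mask) / prod(dim(s$map)))
})

test_that("custom region merges are area-weighted, not load-averaged", {
  tab <- tiny_table()
  rep <- data.frame(
    region_id = c(1L, 2L), name = c("A", "B"), acronym = c("A", "B"),
    region_area_px = c(100L, 300L), region_area_um2 = c(100, 300),
    object_count = c(2L, 1L), object_area_px = c(10L, 3L),
    object_area_um2 = c(10, 3), load = c(0.10, 0.01))
  class(rep) <- c("region_report", "data.frame")
  merged <- apply_custom_regions(rep, custom_regions(list(AB = c(1, 2))), tab)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$load, 13 / 400)     # not mean(0.10, 0.01)
  expect_equal(merged$object_count, 3L)
  # empty spec leaves reports unchanged
  same <- apply_custom_regions(rep, custom_regions(), tab)
  expect_equal(as.data.frame(same), as.data.frame(rep))
  expect_error(
    apply_custom_regions(rep, custom_regions(list(G = 999)), tab),
    "unknown id")
})

test_that("merged-group load equals recomputation from raw pixels", {
  s <- make_scene(23, straddle_fraction = 0.5)
  obs <- assign_object_region(extract_objects(s$mask), s$map)
  rep <- build_region_reports(obs, s$map, s$table, sc1)
  ids <- setdiff(unique(as.vector(unclass(s$map))), 0L)
  merged <- apply_custom_regions(rep, custom_regions(list(ALL = ids)),
                                 s$table)
  grp <- merged[merged$name == "ALL", ]
  m <- unclass(s$map)
  in_group <- matrix(m %in% ids, nrow(m))
  expect_equal(grp$region_area_px, sum(in_group))
  expect_equal(grp$object_area_px, sum(unclass(s$mask) & in_group))
  expect_equal(grp$load, sum(unclass(s$mask) & in_group) / sum(in_group))
})

test_that("custom region CSV parses groups, descendants and excludes", {
  tab <- tiny_table()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("group_name,member_ids",
               "Cortical,+1",            # 1 and its descendant 3
               "Diencephalon,+5",        # 5 and its descendant 6
               "EXCLUDE,0"), path)
  spec <- read_custom_regions(path, tab)
  expect_setequal(spec$groups$Cortical, c(1L, 3L))
  expect_setequal(spec$groups$Diencephalon, c(5L, 6L))
  expect_equal(spec$excluded, 0L)
  writeLines(c("group_name,member_ids", "G,999"), path)
  expect_error(read_custom_regions(path, tab), "unknown region id")
})

test_that("series aggregation pools areas, not loads", {
  tab <- tiny_table()
  mk <- function(area, obj) {
    r <- data.frame(region_id = 1L, name = "A", acronym = "A",
                    region_area_px = area, region_area_um2 = area,
                    object_count = 1L, object_area_px = obj,
                    object_area_um2 = obj, load = obj / area)
    class(r) <- c("region_report", "data.frame")
    r
  }
  agg <- aggregate_series(list(mk(100L, 10L), mk(100L, 10L)))
  expect_equal(agg$load, 0.1)             # equal areas, equal loads
  agg2 <- aggregate_series(list(mk(100L, 10L), mk(300L, 3L)))
  expect_equal(agg2$load, 13 / 400)       # pooled, not mean
})

test_that("series aggregation matches brute-force pooled recomputation", {
  series <- make_series(31, n_sections = 5L, n_objects = 6L,
                        straddle_fraction = 0.3)
  reports <- lapply(series$scenes, function(s) {
    obs <- assign_object_region(extract_objects(s$mask), s$map)
    build_region_reports(obs, s$map, series$table, sc1)
  })
  agg <- aggregate_series(reports)
  pooled_area <- Reduce(`+`, lapply(series$scenes, function(s)
    region_pixel_areas(s$map)))
  expect_equal(agg$region_area_px,
               as.integer(pooled_area[as.character(agg$region_id)]))
  m <- merge(agg, series$truth, by = "region_id")
  expect_equal(m$object_area_px, m$object_area_px_pixel)
  expect_equal(m$load, m$load_pixel)
  # a region present in one section only keeps that section's denominator
  one <- reports[[1]]
  extra <- one[1, ]; extra$region_id <- 6L; extra$name <- "Hypothalamus"
  extra$acronym <- "HY"
  one2 <- rbind(one, extra)
  class(one2) <- c("region_report", "data.frame")
  agg3 <- aggregate_series(list(one2, reports[[2]]))
  expect_equal(agg3$region_area_px[agg3$region_id == 6L],
               extra$region_area_px)
})

test_that("point-grid estimator hits the exact fractions at the extremes", {
  sc <- scale_spec(10, 1)                 # 10 um per pixel
  full <- seg_mask(matrix(TRUE, 100, 100))
  est <- point_grid_area_fraction(full, sc)
  expect_equal(est$fraction, 1)
  expect_gt(est$n_points, 0)
  empty <- seg_mask(matrix(FALSE, 100, 100))
  expect_equal(point_grid_area_fraction(empty, sc)$fraction, 0)
})

test_that("point-grid estimator is within 3 binomial SEs on a 50% stripe mask", {
  sc <- scale_spec(10, 1)
  m <- matrix(FALSE, 120, 120)            # 1200x1200 um
  m[, rep(c(TRUE, FALSE), each = 12, times = 5)] <- TRUE  # 120-um stripes
  est <- point_grid_area_fraction(seg_mask(m), sc, grid_um = c(300, 300),
                                  frame_um = c(200, 200), point_um = 20)
  expect_lt(abs(est$fraction - 0.5), 3 * est$se + 1e-12)
})

test_that("zero points on the section flags the estimate undefined", {
  sc <- scale_spec(1, 1)                  # 5x5 um section, 300 um grid
  est <- point_grid_area_fraction(seg_mask(matrix(TRUE, 5, 5)), sc)
  expect_true(is.na(est$fraction))
  expect_equal(est$n_points, 0L)
})
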