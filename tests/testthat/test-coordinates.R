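test_that("corner convention maps image corners to o, o+u, o+v exactly", {
  anc <- one_anchor(o = c(3, -2, 7), u = c(10, 1, 0), v = c(0.5, 0, 10),
                    width = 40, height = 25)
  expect_identical(pixel_to_atlas(c(0, 0), anc, "corner")[1, ],
                   c(x = 3, y = -2, z = 7))
  expect_equal(unname(pixel_to_atlas(c(40, 0), anc, "corner")[1, ]),
               c(3 + 10, -2 + 1, 7 + 0))
  expect_equal(unname(pixel_to_atlas(c(0, 25), anc, "corner")[1, ]),
               c(3.5, -2, 17))
})

test_that("degenerate u = v = 0 maps every pixel to o", {
  anc <- one_anchor(o = c(1, 2, 3), u = c(0, 0, 0), v = c(0, 0, 0),
                    width = 10, height = 10)
  px <- cbind(x = c(0L, 4L, 9L), y = c(0L, 7L, 9L))
  xyz <- pixel_to_atlas(px, anc)
  expect_true(all(xyz[, 1] == 1 & xyz[, 2] == 2 & xyz[, 3] == 3))
})

test_that("pixel-centre convention evaluates the affine form", {
  anc <- one_anchor(o = c(0, 0, 0), u = c(10, 0, 0), v = c(0, 0, 10),
                    width = 10, height = 10)
  got <- pixel_to_atlas(c(4, 9), anc, "centre")
  expect_equal(unname(got[1, ]), c(4.5, 0, 9.5))
  expect_error(pixel_to_atlas(c(10, 0), anc, "centre"), "outside")
})

test_that("the pixel map is affine: midpoints map to midpoints", {
  set.seed(13)
  anc <- one_anchor(o = stats::rnorm(3), u = stats::rnorm(3),
                    v = stats::rnorm(3), width = 50, height = 40)
  a <- c(3, 5); b <- c(21, 33)
  mid <- (a + b) / 2
  img <- pixel_to_atlas(rbind(a, b, mid), anc, "corner")
  expect_equal(img[3, ], (img[1, ] + img[2, ]) / 2, tolerance = 1e-9)
})

test_that("all points of one section are coplanar", {
  set.seed(14)
  for (i in 1:5) {
    anc <- one_anchor(o = stats::rnorm(3, 0, 20), u = stats::rnorm(3, 0, 30),
                      v = stats::rnorm(3, 0, 30), width = 64, height = 64)
    px <- cbind(x = sample(0:63, 50, TRUE), y = sample(0:63, 50, TRUE))
    xyz <- pixel_to_atlas(px, anc)
    u <- c(anc$ux, anc$uy, anc$uz); v <- c(anc$vx, anc$vy, anc$vz)
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    n <- n / sqrt(sum(n^2))
    res <- (xyz - matrix(c(anc$ox, anc$oy, anc$oz), 50, 3,
                         byrow = TRUE)) %*% n
    expect_lt(max(abs(res)), 1e-6)
  }
})

test_that("object_points emits per-pixel or per-centroid points", {
  anc <- one_anchor(width = 10, height = 10)
  obs <- assign_object_region(
    extract_objects(seg_mask(rbind(matrix(FALSE, 2, 10),
                                   c(TRUE, TRUE, TRUE, rep(FALSE, 7)),
                                   matrix(FALSE, 7, 10)))),
    atlasquant:::new_atlas_map(matrix(1L, 10, 10)))
  pp <- object_points(obs, anc, granularity = "pixel")
  expect_equal(nrow(pp), 3L)
  expect_true(all(pp$region_id == 1L))
  cp <- object_points(obs, anc, granularity = "centroid")
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$x, unname(pixel_to_atlas(cbind(1, 2), anc)[1, 1]))
})

test_that("pixelwise points partition by region like pixelwise attribution", {
  s <- make_scene(17, straddle_fraction = 0.6)
  obs <- assign_object_region(extract_objects(s$mask), s$map)
  pts <- pixel_points(obs, s$anchor, s$map)
  got <- table(pts$region_id)
  want <- pixelwise_region_areas(obs, s$map)
  expect_equal(as.integer(got), unname(want))
  expect_equal(names(got), names(want))
})

test_that("TSV export round-trips coordinates and subsamples every k-th", {
  pts <- data.frame(x = stats::runif(10), y = stats::runif(10),
                    z = stats::runif(10), region_id = rep(1:2, 5),
                    section_key = "14")
  path <- withr::local_tempfile(fileext = ".tsv")
  export_point_cloud(pts, path, format = "tsv")
  back <- read_point_cloud(path)
  expect_equal(back$x, pts$x, tolerance = 1e-6)
  expect_equal(back$z, pts$z, tolerance = 1e-6)
  export_point_cloud(pts, path, format = "tsv", subsample = 3L)
  expect_equal(read_point_cloud(path)$x, pts$x[c(1, 4, 7, 10)],
               tolerance = 1e-6)
  # empty cloud: header only
  export_point_cloud(pts[0, ], path, format = "tsv")
  expect_equal(nrow(read_point_cloud(path)), 0L)
})

test_that("JSON export groups points by region with table colours", {
  tab <- tiny_table()
  pts <- data.frame(x = c(1, 2, 3), y = 0, z = 0,
                    region_id = c(1L, 2L, 1L), section_key = "14")
  path <- withr::local_tempfile(fileext = ".json")
  export_point_cloud(pts, path, format = "json", table = tab)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  expect_length(j, 2L)
  expect_equal(j[[1]]$region_id, 1)
  expect_equal(unlist(j[[1]]$colour), c(31, 120, 180))
  expect_equal(unlist(j[[1]]$points), c(1, 0, 0, 3, 0, 0))
})
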