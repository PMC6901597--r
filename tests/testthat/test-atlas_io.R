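test_that("label table CSV loads, validates and auto-adds background", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,acronym,red,green,blue,parent_id",
               "1,Isocortex,CTX,255,0,0,",
               "2,HPF,HPF,0,255,0,"), path)
  tab <- read_label_table(path)
  expect_s3_class(tab, "label_table")
  expect_equal(nrow(tab), 3L)          # background row added
  expect_true(0L %in% tab$id)
  expect_equal(attr(tab, "background_id"), 0L)
})

test_that("duplicate ids and duplicate colours are format errors", {
  df <- data.frame(id = c(1L, 1L), name = c("a", "b"), acronym = c("a", "b"),
                   red = c(1L, 2L), green = 0L, blue = 0L,
                   parent_id = NA_integer_)
  expect_error(label_table(df), "duplicate region id 1")
  df2 <- data.frame(id = 1:2, name = c("a", "b"), acronym = c("a", "b"),
                    red = 255L, green = 0L, blue = 0L,
                    parent_id = NA_integer_)
  expect_error(label_table(df2), "duplicate colour \\(255,0,0\\)")
})

test_that("cyclic parent chains are a hierarchy error", {
  df <- data.frame(id = c(5L, 6L), name = c("a", "b"), acronym = c("a", "b"),
                   red = c(10L, 20L), green = 0L, blue = 0L,
                   parent_id = c(6L, 5L))
  expect_error(label_table(df), "cyclic parent chain")
})

test_that("colour atlas maps decode exactly and re-encode bit-exactly", {
  tab <- tiny_table()
  # 2x2 pixels coloured as regions 1, 1, 2, 0 (raster order)
  ids <- matrix(c(1L, 2L, 1L, 0L), nrow = 2)  # column-major: rows y, cols x
  path <- withr::local_tempfile(fileext = ".png")
  write_atlas_map(atlasquant:::new_atlas_map(ids), path, tab)
  map <- read_atlas_map(path, tab)
  expect_identical(unclass(map), ids)
  # re-encode: byte-identical PNG
  path2 <- withr::local_tempfile(fileext = ".png")
  write_atlas_map(map, path2, tab)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("all-background map decodes to background labels", {
  tab <- tiny_table()
  img <- array(0L, dim = c(4L, 4L, 3L))  # background colour is (0,0,0)
  path <- withr::local_tempfile(fileext = ".png")
  write_png(img, path)
  map <- read_atlas_map(path, tab)
  expect_identical(as.vector(unclass(map)), rep(0L, 16L))
})

test_that("off-palette colours are a decode error naming the pixel", {
  tab <- tiny_table()
  img <- array(0L, dim = c(2L, 3L, 3L))
  img[2, 3, ] <- 7L                       # colour (7,7,7), pixel (2,1)
  path <- withr::local_tempfile(fileext = ".png")
  write_png(img, path)
  expect_error(read_atlas_map(path, tab), "\\(7,7,7\\).*\\(2,1\\)")
})

test_that("raw QMAP maps round-trip and validate the size header", {
  tab <- tiny_table()
  m <- matrix(sample(tab$id, 12L, replace = TRUE), nrow = 3)
  path <- withr::local_tempfile(fileext = ".qmap")
  write_atlas_map(atlasquant:::new_atlas_map(m), path, mode = "raw")
  expect_identical(unclass(read_atlas_map(path, tab)), m)
  # truncate: size header promises more labels than the file holds
  bytes <- readBin(path, "raw", file.size(path))
  writeBin(bytes[1:(length(bytes) - 8L)], path)
  expect_error(read_atlas_map(path, tab, mode = "raw"), "size header")
})

test_that("nearest-neighbour rescale replicates labels on integer upscale", {
  m <- atlasquant:::new_atlas_map(matrix(c(1L, 3L, 2L, 4L), 2))
  up <- rescale_atlas_map(m, 4L, 4L)
  expect_identical(unclass(up),
                   unclass(m)[rep(1:2, each = 2), rep(1:2, each = 2)])
  expect_identical(rescale_atlas_map(m, 2L, 2L), m)
})

test_that("rescale matches the brute-force centre-mapping oracle", {
  set.seed(42)
  for (i in 1:10) {
    sh <- sample(2:9, 1); sw <- sample(2:9, 1)
    th <- sample(2:11, 1); tw <- sample(2:11, 1)
    m <- matrix(sample(0:5, sh * sw, replace = TRUE), sh, sw)
    got <- rescale_atlas_map(atlasquant:::new_atlas_map(m), tw, th)
    expect_identical(unclass(got), oracle_rescale(m, tw, th))
    expect_true(all(unique(as.vector(unclass(got))) %in% m))
  }
})

test_that("anchoring XML and JSON round-trip to 1e-9", {
  anc <- rbind(one_anchor(o = c(0.123456789, -4, 7.5), key = "14"),
               one_anchor(o = c(1, 2, 3), u = c(-33.25, 0.5, 0),
                          v = c(0, 1e-3, -28.125), key = "15"))
  anc$filename <- c("img_s014.png", "img_s015.png")
  class(anc) <- c("anchoring", "data.frame")
  for (ext in c(".xml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_anchoring(anc, path)
    back <- read_anchoring(path)
    for (k in c("width", "height", "ox", "oy", "oz", "ux", "uy", "uz",
                "vx", "vy", "vz"))
      expect_equal(back[[k]], anc[[k]], tolerance = 1e-9)
    expect_identical(back$section_key, c("14", "15"))
  }
})

test_that("anchoring parse errors: missing component, duplicate key", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    '<series><slice filename="a_s1.png" width="10" height="10" ',
    'ox="0" oy="0" oz="0" ux="1" uy="0" uz="0" vx="0" vy="0"/></series>'),
    path)
  expect_error(read_anchoring(path), "missing attribute.*vz")
  writeLines(c(
    '<series>',
    '<slice filename="a_s1.png" width="10" height="10" ox="0" oy="0" oz="0" ux="1" uy="0" uz="0" vx="0" vy="0" vz="1"/>',
    '<slice filename="b_s01.png" width="10" height="10" ox="0" oy="0" oz="0" ux="1" uy="0" uz="0" vx="0" vy="0" vz="1"/>',
    '</series>'), path)
  expect_error(read_anchoring(path), "duplicate section key 1")
})

test_that("empty anchoring series parses to an empty collection", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<series></series>", path)
  expect_equal(nrow(read_anchoring(path)), 0L)
})

test_that("match_sections joins on section key and reports leftovers", {
  anc <- one_anchor(key = "14")
  m <- match_sections("img_s014.png", anc, "atlas_s014.png")
  expect_equal(nrow(m$triples), 1L)
  expect_equal(m$triples$section_key, "14")
  expect_length(m$unmatched$images, 0L)

  m2 <- match_sections("img_s099.png", anc, "atlas_s014.png")
  expect_equal(nrow(m2$triples), 0L)
  expect_equal(m2$unmatched$images, "img_s099.png")
  expect_equal(m2$unmatched$anchors, "14")

  expect_error(
    match_sections(c("a_s014.png", "b_s14.png"), anc, "atlas_s014.png"),
    "ambiguous image naming: key 14")
})
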