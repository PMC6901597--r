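series_config <- function(dir, ...) {
  run_config(
    input = list(segmentation_dir = file.path(dir, "segmentations"),
                 atlas_dir = file.path(dir, "atlas"),
                 anchoring = file.path(dir, "anchoring.xml"),
                 label_table = file.path(dir, "label_table.csv")),
    output = list(dir = file.path(dir, "out")),
    scale = list(pixel_size = 0.284, resize_factor = 0.05), ...)
}

test_that("a 3-section run writes the full artifact inventory", {
  dir <- withr::local_tempdir()
  write_series(make_series(55, n_sections = 3L), dir)
  res <- run_quantifier(series_config(dir))
  expect_equal(res$status, 0L)
  out <- file.path(dir, "out")
  expect_length(list.files(out, pattern = "^report_s\\d+\\.csv$"), 3L)
  expect_length(list.files(out, pattern = "_overlay\\.png$"), 3L)
  expect_true(file.exists(file.path(out, "report_series.csv")))
  expect_true(file.exists(file.path(out, "points.tsv")))
  expect_true(file.exists(file.path(out, "points.json")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  # manifest totals equal the object-table sums
  man <- jsonlite::fromJSON(file.path(out, "manifest.json"))
  for (key in names(man$sections)) {
    objs <- utils::read.csv(file.path(out, sprintf("objects_s%s.csv", key)))
    expect_equal(man$sections[[key]]$n_objects, nrow(objs))
    expect_equal(man$sections[[key]]$labelled_px, sum(objs$area_px))
  }
})

test_that("a section with a missing atlas map is flagged, others complete", {
  dir <- withr::local_tempdir()
  write_series(make_series(56, n_sections = 3L), dir)
  maps <- list.files(file.path(dir, "atlas"), full.names = TRUE)
  file.remove(maps[1])
  res <- run_quantifier(series_config(dir))
  expect_equal(res$status, 1L)
  expect_length(res$sections, 2L)
  man <- jsonlite::fromJSON(file.path(dir, "out", "manifest.json"))
  expect_equal(man$status, 1L)
  expect_length(man$unmatched$images, 1L)
})

test_that("reruns are bit-identical for CSV, TSV and JSON outputs", {
  dir <- withr::local_tempdir()
  write_series(make_series(57, n_sections = 2L, straddle_fraction = 0.3),
               dir)
  cfg1 <- series_config(dir)
  run_quantifier(cfg1)
  first <- file.path(dir, "out")
  cfg2 <- cfg1
  cfg2$output$dir <- file.path(dir, "out2")
  run_quantifier(cfg2)
  for (f in c("report_series.csv", "points.tsv", "points.json")) {
    expect_identical(
      readBin(file.path(first, f), "raw", file.size(file.path(first, f))),
      readBin(file.path(dir, "out2", f), "raw",
              file.size(file.path(dir, "out2", f))),
      label = f)
  }
})

test_that("pipeline handles the raw QMAP atlas dialect end to end", {
  dir <- withr::local_tempdir()
  ser <- make_series(58, n_sections = 1L)
  write_series(ser, dir, atlas_format = "raw")
  res <- run_quantifier(series_config(dir))
  expect_equal(res$status, 0L)
  rep <- res$sections[[1]]$report
  m <- merge(rep, ser$truth, by = "region_id")
  expect_equal(m$object_area_px, m$object_area_px_pixel)
})

test_that("anchor attribution mode flows through the run configuration", {
  dir <- withr::local_tempdir()
  ser <- make_series(59, n_sections = 1L, straddle_fraction = 0.5)
  write_series(ser, dir)
  res <- run_quantifier(series_config(
    dir, report = list(attribution = "anchor")))
  m <- merge(res$sections[[1]]$report, ser$truth, by = "region_id")
  expect_equal(m$object_area_px, m$object_area_px_anchor)
  expect_equal(m$load, m$load_anchor)
})

test_that("the CLI generates fixtures and quantifies them", {
  dir <- withr::local_tempdir()
  expect_equal(suppressMessages(
    aq_main(c("fixtures", "--out", dir, "--seed", "4",
              "--sections", "2"))), 0L)
  toml <- file.path(dir, "run.toml")
  writeLines(c("[input]",
               sprintf('segmentation_dir = "%s/segmentations"', dir),
               sprintf('atlas_dir = "%s/atlas"', dir),
               sprintf('anchoring = "%s/anchoring.xml"', dir),
               sprintf('label_table = "%s/label_table.csv"', dir),
               "[output]", sprintf('dir = "%s/out"', dir),
               "[scale]", "pixel_size = 0.284", "resize_factor = 0.05"),
             toml)
  status <- suppressMessages(aq_main(c("quantify", "--config", toml)))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(dir, "out", "report_series.csv")))
  # transform dry-run makes no changes
  n_before <- length(list.files(file.path(dir, "segmentations")))
  suppressMessages(aq_main(c("transform", "--in",
                             file.path(dir, "segmentations"),
                             "--out", file.path(dir, "tx"),
                             "--rename-template", "img_s{N:03}.png",
                             "--dry-run")))
  expect_false(dir.exists(file.path(dir, "tx")))
  expect_length(list.files(file.path(dir, "segmentations")), n_before)
})
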