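# End-to-end pipeline: for each matched section, load the segmentation
# and its atlas map, rescale the map to segmentation dimensions,
# binarize per target colour, extract and filter objects, assign
# regions, and emit per-section reports, object tables, overlays and
# atlas-space points; then aggregate the series.  One bad section never
# kills a 60-section run: failures are recorded in the manifest and the
# exit status is nonzero if any occurred.

quantify_section <- function(seg_path, map_path, anchor, config, table,
                             out_dir) {
  cfg <- config
  img <- read_png(seg_path)
  map <- read_atlas_map(map_path, table)
  map <- rescale_atlas_map(map, width = dim(img)[2], height = dim(img)[1])
  objects <- empty_object_set()
  rejected <- 0L
  for (i in seq_len(nrow(cfg$objects$colours))) {
    mask <- suppressWarnings(
      binarize_by_colour(img, cfg$objects$colours[i, ]))
    obs <- extract_objects(mask, connectivity = cfg$objects$connectivity,
                           scale = cfg$scale)
    flt <- filter_by_size(obs, cfg$objects$min_px, cfg$objects$max_px)
    rejected <- rejected + nrow(flt$rejected)
    objects <- rbind(objects, flt$kept)
  }
  if (nrow(objects) > 0L) {
    objects$object_id <- seq_len(nrow(objects))
    class(objects) <- c("object_set", "data.frame")
  }
  objects <- assign_object_region(objects, map)
  report <- build_region_reports(objects, map, table, cfg$scale,
                                 attribution = cfg$report$attribution)
  key <- anchor$section_key
  bg <- if (isTRUE(cfg$report$exclude_background))
    attr(table, "background_id") else integer(0)
  write_region_report(report,
                      file.path(out_dir, sprintf("report_s%s.csv", key)),
                      exclude = bg)
  write_object_table(objects,
                     file.path(out_dir, sprintf("objects_s%s.csv", key)),
                     table = table)
  write_overlay(map, objects, table, key, out_dir)
  points <- if (cfg$report$point_granularity == "pixel")
    pixel_points(objects, anchor, map,
                 convention = cfg$report$convention)
  else object_points(objects, anchor, granularity = "centroid",
                     convention = cfg$report$convention)
  list(report = report, points = points, n_objects = nrow(objects),
       n_rejected = rejected,
       labelled_px = sum(objects$area_px))
}

#' Run the full quantification pipeline
#'
#' Matches segmentations, atlas maps and anchors by section key, then
#' quantifies every section (see the package vignette for the stage
#' order), aggregates the series, exports the pooled atlas-space point
#' cloud (TSV and JSON) and writes a machine-readable run manifest.
#' Outputs are deterministic: rerunning an identical configuration
#' yields bit-identical files.
#'
#' @param config a `run_config` from [load_config()] or [run_config()].
#' @return invisibly, a list with `status` (0 ok, 1 partial failure),
#'   `sections` (per-section outcome), `series_report`, `manifest_path`.
#' @export
run_quantifier <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- read_label_table(config$input$label_table)
  anchors <- read_anchoring(config$input$anchoring,
                            pattern = config$report$section_pattern)
  segs <- sort(list.files(config$input$segmentation_dir,
                          pattern = "\\.(png|PNG)$", full.names = TRUE))
  maps <- sort(list.files(config$input$atlas_dir,
                          pattern = "\\.(png|PNG|qmap)$", full.names = TRUE))
  matched <- match_sections(segs, anchors, maps,
                            pattern = config$report$section_pattern)
  spec <- if (!is.null(config$input$custom_regions))
    read_custom_regions(config$input$custom_regions, table) else NULL
  tri <- matched$triples
  results <- list(); failures <- list()
  for (i in seq_len(nrow(tri))) {
    key <- tri$section_key[i]
    res <- tryCatch(
      quantify_section(tri$image[i], tri$map[i], tri[i, ], config, table,
                       out_dir),
      error = function(e) e)
    if (inherits(res, "error")) failures[[key]] <- conditionMessage(res)
    else results[[key]] <- res
  }
  status <- 0L
  series_report <- NULL
  points_tsv <- points_json <- NULL
  if (length(results)) {
    reports <- lapply(results, function(r) {
      rep <- r$report
      if (!is.null(spec)) rep <- apply_custom_regions(rep, spec, table)
      rep
    })
    series_report <- aggregate_series(reports)
    bg <- if (isTRUE(config$report$exclude_background))
      attr(table, "background_id") else integer(0)
    write_region_report(series_report,
                        file.path(out_dir, "report_series.csv"),
                        exclude = bg)
    all_points <- do.call(rbind, lapply(results, function(r) r$points))
    rownames(all_points) <- NULL
    points_tsv <- file.path(out_dir, "points.tsv")
    points_json <- file.path(out_dir, "points.json")
    export_point_cloud(all_points, points_tsv, format = "tsv")
    export_point_cloud(all_points, points_json, format = "json",
                       table = table)
  }
  if (length(failures) || length(matched$unmatched$images)) status <- 1L
  manifest <- list(
    tool = "atlasquant",
    version = as.character(utils::packageVersion("atlasquant")),
    parameters = list(
      pixel_size = config$scale$base_pixel_size,
      resize_factor = config$scale$resize_factor,
      min_px = config$objects$min_px, max_px = config$objects$max_px,
      connectivity = config$objects$connectivity,
      attribution = config$report$attribution,
      convention = config$report$convention,
      colours = apply(config$objects$colours, 1L, paste, collapse = ",")
    ),
    inputs = config$input,
    sections = lapply(results, function(r)
      list(n_objects = r$n_objects, n_rejected = r$n_rejected,
           labelled_px = r$labelled_px)),
    failed_sections = failures,
    unmatched = matched$unmatched,
    status = status
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(status = status, sections = results,
                 failures = failures, series_report = series_report,
                 manifest_path = manifest_path))
}

#' Command-line entry point
#'
#' Subcommands: `quantify --config run.toml [--strict]`, `transform`
#' (resize/rotate/mirror/rename a directory of images), `points`
#' (re-export a point cloud from a finished run) and `fixtures` (write
#' a synthetic input tree).  Exit codes: 0 ok, 1 partial failure,
#' 2 usage or configuration error.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return integer exit status, invisibly.
#' @export
aq_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: atlasquant <command> [options]",
    "  quantify  --config <run.toml|run.csv> [--strict true|false]",
    "  transform --in <dir> --out <dir> [--resize f] [--rotate 0..3]",
    "            [--mirror horizontal|vertical] [--method nearest|area]",
    "            [--rename-template tpl] [--start n] [--step n] [--dry-run]",
    "  points    --run <outdir> --out <file> [--format tsv|json]",
    "            [--subsample k] [--label-table csv]",
    "  fixtures  --out <dir> [--seed n] [--sections n] [--straddle f]",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  status <- tryCatch(
    switch(cmd,
           quantify = cli_quantify(opts),
           transform = cli_transform(opts),
           points = cli_points(opts),
           fixtures = cli_fixtures(opts),
           { message("unknown command: ", cmd, "\n", usage); 2L }),
    error = function(e) { message("error: ", conditionMessage(e)); 2L })
  invisible(as.integer(status))
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opts
}

cli_quantify <- function(opts) {
  if (is.null(opts$config)) stop("quantify: --config is required")
  strict <- !identical(opts$strict, "false")
  cfg <- load_config(opts$config, strict = strict)
  res <- run_quantifier(cfg)
  if (res$status != 0L)
    message("quantify: ", length(res$failures), " section(s) failed, ",
            length(res$sections), " completed")
  res$status
}

cli_transform <- function(opts) {
  if (is.null(opts[["in"]]) || is.null(opts$out))
    stop("transform: --in and --out are required")
  files <- sort(list.files(opts[["in"]], pattern = "\\.(png|PNG)$"))
  dry <- isTRUE(opts[["dry-run"]])
  new_names <- if (!is.null(opts[["rename-template"]])) {
    rename_series(files, opts[["rename-template"]],
                  start = as.integer(if (is.null(opts$start)) 1L else
                    opts$start),
                  step = as.integer(if (is.null(opts$step)) 1L else
                    opts$step))
  } else stats::setNames(files, files)
  if (dry) {
    for (i in seq_along(new_names))
      message(names(new_names)[i], " -> ", new_names[i])
    return(0L)
  }
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  method <- if (is.null(opts$method)) "nearest" else opts$method
  for (i in seq_along(files)) {
    img <- read_png(file.path(opts[["in"]], files[i]))
    if (!is.null(opts$resize))
      img <- resize_image(img, as.numeric(opts$resize), method = method)
    if (!is.null(opts$rotate))
      img <- rotate_image(img, as.integer(opts$rotate))
    if (!is.null(opts$mirror))
      img <- mirror_image(img, opts$mirror)
    write_png(img, file.path(opts$out, new_names[i]))
    message("transform: wrote ", new_names[i],
            " (", paste(dim(img)[1:2], collapse = "x"), " px, ", method,
            " resampling)")
  }
  0L
}

cli_points <- function(opts) {
  if (is.null(opts$run) || is.null(opts$out))
    stop("points: --run and --out are required")
  pts <- read_point_cloud(file.path(opts$run, "points.tsv"))
  fmt <- if (is.null(opts$format)) "tsv" else opts$format
  table <- if (!is.null(opts[["label-table"]]))
    read_label_table(opts[["label-table"]]) else NULL
  export_point_cloud(pts, opts$out, format = fmt, table = table,
                     subsample = as.integer(
                       if (is.null(opts$subsample)) 1L else opts$subsample))
  0L
}

cli_fixtures <- function(opts) {
  if (is.null(opts$out)) stop("fixtures: --out is required")
  seed <- as.integer(if (is.null(opts$seed)) 1L else opts$seed)
  n <- as.integer(if (is.null(opts$sections)) 3L else opts$sections)
  straddle <- as.numeric(if (is.null(opts$straddle)) 0.3 else opts$straddle)
  series <- make_series(seed, n_sections = n,
                        straddle_fraction = straddle)
  write_series(series, opts$out)
  message("fixtures: wrote ", n, " section(s) to ", opts$out)
  0L
}
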