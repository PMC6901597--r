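# Run configuration: a plain-text TOML file (diffable, scriptable)
# replaces spreadsheet-style parameter templates; a CSV rendering
# (key,value rows) of such a template can be imported to the identical
# configuration.

assign_nested <- function(lst, keys, value) {
  if (length(keys) == 1L) {
    lst[[keys]] <- value
    return(lst)
  }
  if (is.null(lst[[keys[1]]])) lst[[keys[1]]] <- list()
  lst[[keys[1]]] <- assign_nested(lst[[keys[1]]], keys[-1L], value)
  lst
}

# Minimal TOML subset parser: [section] headers, key = value with
# strings, numbers, booleans and flat arrays, # comments.  Deliberately
# small -- the configuration schema below needs nothing more.
parse_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- character(0)
  parse_scalar <- function(tok) {
    tok <- trimws(tok)
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    if (grepl("^'.*'$", tok)) return(gsub("^'|'$", "", tok))
    if (tok %in% c("true", "false")) return(tok == "true")
    num <- suppressWarnings(as.numeric(tok))
    if (!is.na(num)) return(num)
    stop("TOML parse error: cannot interpret value '", tok, "'")
  }
  for (raw in lines) {
    line <- sub('#(?=(?:[^"]*"[^"]*")*[^"]*$).*', "", raw, perl = TRUE)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- strsplit(gsub("^\\[|\\]$", "", line), ".", fixed = TRUE)[[1]]
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq == -1L) stop("TOML parse error: expected key = value in '",
                        raw, "'")
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    value <- if (grepl("^\\[.*\\]$", val)) {
      toks <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
      toks <- trimws(toks)
      toks <- toks[nzchar(toks)]
      vals <- lapply(toks, parse_scalar)
      if (length(vals)) simplify2array(vals) else numeric(0)
    } else parse_scalar(val)
    out <- assign_nested(out, c(section, key), value)
  }
  out
}

config_defaults <- function() list(
  scale = list(pixel_size = 1, resize_factor = 1),
  objects = list(min_px = 1, max_px = Inf, connectivity = 8,
                 colours = c(255, 0, 255)),
  report = list(attribution = "pixel", convention = "centre",
                section_pattern = "_s(\\d+)", point_granularity = "pixel",
                exclude_background = TRUE)
)

config_known_keys <- function() list(
  input = c("segmentation_dir", "atlas_dir", "anchoring", "label_table",
            "custom_regions"),
  output = "dir",
  scale = c("pixel_size", "resize_factor"),
  objects = c("min_px", "max_px", "connectivity", "colours"),
  report = c("attribution", "convention", "section_pattern",
             "point_granularity", "exclude_background")
)

#' Assemble and validate a run configuration
#'
#' @param input list with `segmentation_dir`, `atlas_dir`, `anchoring`,
#'   `label_table` and optionally `custom_regions` paths.
#' @param output list with `dir` (created on run if absent).
#' @param scale list `pixel_size` (um/px of the original scan) and
#'   `resize_factor`.
#' @param objects list `min_px`, `max_px`, `connectivity` (4/8),
#'   `colours` (flat RGB vector, length a multiple of 3; one mask is
#'   quantified per colour).
#' @param report list `attribution` ("pixel"/"anchor"), `convention`
#'   ("centre"/"corner"), `section_pattern`, `point_granularity`
#'   ("pixel"/"centroid"), `exclude_background` (drop the background
#'   region from whole-section summaries).
#' @param check_paths verify that input paths exist (default TRUE).
#' @return a validated `run_config`; applied defaults are recorded in
#'   `attr(, "defaults_applied")`.
#' @export
run_config <- function(input, output, scale = list(), objects = list(),
                       report = list(), check_paths = TRUE) {
  def <- config_defaults()
  applied <- character(0)
  fill <- function(user, section) {
    for (k in names(def[[section]])) {
      if (is.null(user[[k]])) {
        user[[k]] <- def[[section]][[k]]
        applied <<- c(applied, paste0(section, ".", k, " = ",
                                      paste(def[[section]][[k]],
                                            collapse = ",")))
      }
    }
    user
  }
  scale <- fill(scale, "scale")
  objects <- fill(objects, "objects")
  report <- fill(report, "report")
  for (k in c("segmentation_dir", "atlas_dir", "anchoring", "label_table"))
    if (is.null(input[[k]]))
      stop("config error: missing mandatory key input.", k)
  if (is.null(output$dir))
    stop("config error: missing mandatory key output.dir")
  if (check_paths)
    for (k in c("segmentation_dir", "atlas_dir", "anchoring", "label_table",
                "custom_regions")) {
      if (!is.null(input[[k]]) && !file.exists(input[[k]]))
        stop("config error: input.", k, " path does not exist: ", input[[k]])
    }
  if (objects$min_px < 1 || objects$min_px > objects$max_px)
    stop("config error: need 1 <= objects.min_px <= objects.max_px")
  if (!(objects$connectivity %in% c(4, 8)))
    stop("config error: objects.connectivity must be 4 or 8")
  if (length(objects$colours) %% 3L != 0L || length(objects$colours) == 0L)
    stop("config error: objects.colours must be a flat RGB list ",
         "(length a multiple of 3)")
  if (!(report$attribution %in% c("pixel", "anchor")))
    stop("config error: report.attribution must be 'pixel' or 'anchor'")
  if (!(report$convention %in% c("centre", "corner")))
    stop("config error: report.convention must be 'centre' or 'corner'")
  if (!(report$point_granularity %in% c("pixel", "centroid")))
    stop("config error: report.point_granularity must be 'pixel' or ",
         "'centroid'")
  cfg <- list(input = input, output = output,
              scale = scale_spec(scale$pixel_size, scale$resize_factor),
              objects = list(min_px = objects$min_px,
                             max_px = objects$max_px,
                             connectivity = as.integer(objects$connectivity),
                             colours = matrix(as.integer(objects$colours),
                                              ncol = 3L, byrow = TRUE)),
              report = report)
  structure(cfg, defaults_applied = applied, class = "run_config")
}

#' Load a run configuration from TOML or CSV
#'
#' The CSV template import mode (`key,value` rows with dotted keys like
#' `input.segmentation_dir`) produces the identical configuration as
#' the equivalent TOML.
#'
#' @param path `.toml` or `.csv` file.
#' @param strict if TRUE (default), unknown keys are a config error;
#'   otherwise they are warned about and ignored.
#' @param check_paths verify input paths exist.
#' @return a `run_config`.
#' @export
load_config <- function(path, strict = TRUE, check_paths = TRUE) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!all(c("key", "value") %in% names(df)))
      stop("config error: CSV template needs columns key,value")
    out <- list()
    for (i in seq_len(nrow(df))) {
      keys <- strsplit(df$key[i], ".", fixed = TRUE)[[1]]
      val <- df$value[i]
      num <- suppressWarnings(as.numeric(strsplit(val, ";")[[1]]))
      parsed <- if (!anyNA(num)) num
      else if (val %in% c("true", "false")) val == "true"
      else val
      out <- assign_nested(out, keys, parsed)
    }
    out
  } else parse_toml(path)
  known <- config_known_keys()
  for (section in names(raw)) {
    if (!(section %in% names(known))) {
      msg <- paste0("config error: unknown section [", section, "]")
      if (strict) stop(msg) else {
        warning(msg, " (ignored)"); raw[[section]] <- NULL; next
      }
    }
    bad <- setdiff(names(raw[[section]]), known[[section]])
    if (length(bad)) {
      msg <- paste0("config error: unknown key ", section, ".", bad[1])
      if (strict) stop(msg)
      warning(msg, " (ignored)")
      raw[[section]][bad] <- NULL
    }
  }
  cfg <- run_config(input = raw$input, output = raw$output,
                    scale = if (is.null(raw$scale)) list() else raw$scale,
                    objects = if (is.null(raw$objects)) list() else
                      raw$objects,
                    report = if (is.null(raw$report)) list() else raw$report,
                    check_paths = check_paths)
  for (d in attr(cfg, "defaults_applied"))
    message("config: default applied: ", d)
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  segmentations:", x$input$segmentation_dir, "\n")
  cat("  atlas maps:   ", x$input$atlas_dir, "\n")
  cat("  scale:        ", x$scale$base_pixel_size, "um/px, factor",
      x$scale$resize_factor, "\n")
  cat("  size bounds:  [", x$objects$min_px, ",", x$objects$max_px,
      "] px, connectivity", x$objects$connectivity, "\n")
  cat("  attribution:  ", x$report$attribution, "; convention:",
      x$report$convention, "\n")
  invisible(x)
}
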