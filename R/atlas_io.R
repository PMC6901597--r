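# Label tables, atlas maps and section anchoring.
#
# An atlas map is the per-section image in which every pixel carries the
# id of the reference-atlas region underneath it, exported by a
# registration tool customised to the section's cutting angle.  Two
# encodings are supported: a colour-coded PNG decoded through the label
# table, and a simple raw little-endian label matrix ("QMAP" dialect),
# because registration tools export either.

colour_key <- function(r, g, b) r * 65536 + g * 256 + b

#' Construct a validated region label table
#'
#' @param df data.frame with columns `id`, `name`, `acronym`, `red`,
#'   `green`, `blue`, `parent_id` (NA for roots).
#' @param background_id region id reserved for outside-brain pixels; a
#'   background row is appended if absent.
#' @return a `label_table`: the data.frame with a `background_id`
#'   attribute, ids and colours validated unique, parent links acyclic.
#' @export
label_table <- function(df, background_id = 0L) {
  need <- c("id", "name", "acronym", "red", "green", "blue", "parent_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("label table is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$id <- as.integer(df$id)
  df$parent_id <- suppressWarnings(as.integer(df$parent_id))
  for (ch in c("red", "green", "blue")) df[[ch]] <- as.integer(df[[ch]])
  if (anyNA(df$id) || any(df$id < 0L))
    stop("label table: region ids must be non-negative integers")
  rgb <- as.matrix(df[c("red", "green", "blue")])
  if (anyNA(rgb) || any(rgb < 0L) || any(rgb > 255L))
    stop("label table: colour components must be in 0..255")
  if (!(background_id %in% df$id)) {
    bg <- data.frame(id = as.integer(background_id), name = "background",
                     acronym = "bg", red = 0L, green = 0L, blue = 0L,
                     parent_id = NA_integer_)
    if (colour_key(0, 0, 0) %in% colour_key(df$red, df$green, df$blue))
      bg[c("red", "green", "blue")] <- list(255L, 255L, 255L)
    df <- rbind(bg, df)
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup))
    stop("label table: duplicate region id ", dup[1], " (row ",
         which(df$id == dup[1])[2], ")")
  key <- colour_key(df$red, df$green, df$blue)
  dupc <- which(duplicated(key))
  if (length(dupc))
    stop("label table: duplicate colour (", df$red[dupc[1]], ",",
         df$green[dupc[1]], ",", df$blue[dupc[1]], ") at row ", dupc[1])
  # parent links: must resolve and contain no cycles
  for (i in seq_len(nrow(df))) {
    seen <- integer(0)
    cur <- df$id[i]
    while (!is.na(cur)) {
      if (cur %in% seen)
        stop("label table: cyclic parent chain involving id ", cur)
      seen <- c(seen, cur)
      j <- match(cur, df$id)
      if (is.na(j))
        stop("label table: parent id ", cur, " not present in table")
      cur <- df$parent_id[j]
      if (!is.na(cur) && cur == df$id[j]) break  # self-parent = root marker
    }
  }
  rownames(df) <- NULL
  structure(df, background_id = as.integer(background_id),
            class = c("label_table", "data.frame"))
}

#' Read a region label table from CSV
#'
#' Expected header: `id,name,acronym,red,green,blue,parent_id`.
#' A background row (id 0, reserved for outside-brain pixels) is added
#' automatically when the file does not provide one.
#'
#' @param path CSV file path.
#' @inheritParams label_table
#' @return a [label_table()].
#' @export
read_label_table <- function(path, background_id = 0L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  label_table(df, background_id = background_id)
}

#' Write a label table to CSV
#' @param table a [label_table()].
#' @param path output path.
#' @export
write_label_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.label_table <- function(x, ...) {
  cat("<label_table> ", nrow(x), " regions (background id ",
      attr(x, "background_id"), ")\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

background_id <- function(table) attr(table, "background_id")

#' Look up region rows by id
#' @param table a [label_table()].
#' @param ids integer region ids.
#' @return data.frame rows of `table` aligned to `ids`.
#' @export
region_info <- function(table, ids) {
  j <- match(as.integer(ids), table$id)
  if (anyNA(j))
    stop("unknown region id(s): ",
         paste(unique(ids[is.na(j)]), collapse = ", "))
  as.data.frame(table)[j, , drop = FALSE]
}

new_atlas_map <- function(labels) {
  storage.mode(labels) <- "integer"
  structure(labels, class = "atlas_map")
}

#' @export
print.atlas_map <- function(x, ...) {
  cat("<atlas_map> ", ncol(x), " x ", nrow(x), " px, ",
      length(unique(as.vector(x))), " distinct labels\n", sep = "")
  invisible(x)
}

#' @export
dim.atlas_map <- function(x) dim(unclass(x))

QMAP_MAGIC <- charToRaw("QMAP")

#' Read a section atlas map
#'
#' In `"colour"` mode the file is a 24-bit PNG whose pixel colours are
#' decoded exactly (no nearest-colour snapping) through the label table;
#' any off-palette pixel is an error, surfacing anti-aliased (invalid)
#' atlas exports.  In `"raw"` mode the file is the QMAP dialect: magic
#' bytes `QMAP`, two little-endian uint32 (width, height), then
#' width*height little-endian uint32 region ids in row-major order.
#'
#' @param path file path.
#' @param table a [label_table()] supplying the colour palette and the
#'   set of valid region ids.
#' @param mode `"auto"` (by file extension), `"colour"` or `"raw"`.
#' @return an `atlas_map`: an integer matrix (rows = image rows, top
#'   first) of region ids.
#' @export
read_atlas_map <- function(path, table, mode = c("auto", "colour", "raw")) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (tolower(tools::file_ext(path)) == "qmap") "raw" else "colour"
  if (mode == "colour") {
    img <- read_png(path)
    key <- colour_key(img[, , 1], img[, , 2], img[, , 3])
    pal <- colour_key(table$red, table$green, table$blue)
    j <- match(key, pal)
    if (anyNA(j)) {
      bad <- which(is.na(j))[1]
      h <- dim(img)[1]
      y0 <- (bad - 1L) %% h       # 0-based row
      x0 <- (bad - 1L) %/% h      # 0-based column
      stop("atlas map ", path, ": colour (", img[y0 + 1, x0 + 1, 1], ",",
           img[y0 + 1, x0 + 1, 2], ",", img[y0 + 1, x0 + 1, 3],
           ") at pixel (", x0, ",", y0, ") not in label table")
    }
    lab <- matrix(table$id[j], nrow = dim(img)[1])
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 4L)
    if (!identical(magic, QMAP_MAGIC))
      stop("atlas map ", path, ": bad QMAP magic bytes")
    wh <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    if (any(wh <= 0L))
      stop("atlas map ", path, ": invalid size header")
    w <- wh[1]; h <- wh[2]
    vals <- readBin(con, "integer", w * h, size = 4L, endian = "little")
    if (length(vals) != w * h)
      stop("atlas map ", path, ": size header promises ", w * h,
           " labels but file holds ", length(vals))
    lab <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)  # row-major file
    unknown <- setdiff(unique(vals), table$id)
    if (length(unknown))
      stop("atlas map ", path, ": label(s) not in table: ",
           paste(unknown, collapse = ", "))
  }
  new_atlas_map(lab)
}

#' Write an atlas map
#' @param map an `atlas_map`.
#' @param path output path.
#' @param table a [label_table()] (required for colour mode).
#' @param mode `"colour"` (PNG) or `"raw"` (QMAP).
#' @export
write_atlas_map <- function(map, path, table = NULL,
                            mode = c("colour", "raw")) {
  mode <- match.arg(mode)
  if (mode == "colour") {
    stopifnot(!is.null(table))
    j <- match(as.vector(unclass(map)), table$id)
    if (anyNA(j))
      stop("write_atlas_map: map holds ids absent from the label table")
    h <- nrow(map); w <- ncol(map)
    img <- array(0L, dim = c(h, w, 3L))
    img[, , 1] <- table$red[j]
    img[, , 2] <- table$green[j]
    img[, , 3] <- table$blue[j]
    write_png(img, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(QMAP_MAGIC, con)
    writeBin(as.integer(c(ncol(map), nrow(map))), con, size = 4L,
             endian = "little")
    writeBin(as.integer(t(unclass(map))), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Rescale an atlas map by nearest-neighbour resampling
#'
#' Region labels are categorical, so no interpolation is performed: each
#' output pixel takes the label of the input pixel whose centre is
#' nearest to the output pixel centre.  Used to bring atlas maps to the
#' dimensions of the segmentation image they annotate.
#'
#' @param map an `atlas_map`.
#' @param width,height target dimensions in pixels (positive).
#' @return an `atlas_map` of the requested size.
#' @export
rescale_atlas_map <- function(map, width, height) {
  stopifnot(width >= 1, height >= 1)
  sh <- nrow(map); sw <- ncol(map)
  if (width == sw && height == sh) return(map)
  # output pixel centre (i+0.5)/dst maps to source coordinate; floor picks
  # the containing source pixel
  sx <- pmin(floor((seq_len(width) - 0.5) * sw / width), sw - 1L) + 1L
  sy <- pmin(floor((seq_len(height) - 0.5) * sh / height), sh - 1L) + 1L
  new_atlas_map(unclass(map)[sy, sx, drop = FALSE])
}

#' Parse a section anchoring file
#'
#' Each section image is placed in 3D atlas space by three vectors: `o`,
#' the atlas-space position of the image's top-left corner, and `u`, `v`,
#' the atlas-space extents of the image's width and height axes.  The XML
#' dialect is `<series><slice filename=".." width=".." height=".."
#' ox=".." ... vz=".."/></series>`; the JSON dialect is a list of objects
#' with the same keys.
#'
#' @param path XML (`.xml`) or JSON (`.json`) anchoring file.
#' @return an `anchoring` data.frame: one row per section with columns
#'   `section_key`, `filename`, `width`, `height`, `ox..oz`, `ux..uz`,
#'   `vx..vz`.
#' @param pattern regex with one capture group extracting the section
#'   key from `filename`.
#' @export
read_anchoring <- function(path, pattern = "_s(\\d+)") {
  vec_keys <- c("ox", "oy", "oz", "ux", "uy", "uz", "vx", "vy", "vz")
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    lst <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    rows <- lapply(lst, function(sl) {
      miss <- setdiff(c("filename", "width", "height", vec_keys), names(sl))
      if (length(miss))
        stop("anchoring ", path, ": slice '",
             if (is.null(sl$filename)) "?" else sl$filename,
             "' missing field(s): ", paste(miss, collapse = ", "))
      sl[c("filename", "width", "height", vec_keys)]
    })
  } else {
    doc <- xml2::read_xml(path)
    slices <- xml2::xml_find_all(doc, ".//slice")
    rows <- lapply(slices, function(sl) {
      at <- xml2::xml_attrs(sl)
      miss <- setdiff(c("filename", "width", "height", vec_keys), names(at))
      if (length(miss))
        stop("anchoring ", path, ": slice '",
             if ("filename" %in% names(at)) at[["filename"]] else "?",
             "' missing attribute(s): ", paste(miss, collapse = ", "))
      c(list(filename = at[["filename"]],
             width = as.numeric(at[["width"]]),
             height = as.numeric(at[["height"]])),
        as.list(as.numeric(at[vec_keys])))
    })
  }
  if (length(rows) == 0L) {
    df <- data.frame(section_key = character(0), filename = character(0),
                     width = numeric(0), height = numeric(0))
    for (k in vec_keys) df[[k]] <- numeric(0)
    return(structure(df, class = c("anchoring", "data.frame")))
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    names(r) <- c("filename", "width", "height", vec_keys)
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  num <- c("width", "height", vec_keys)
  for (k in num) {
    df[[k]] <- as.numeric(df[[k]])
    if (anyNA(df[[k]]))
      stop("anchoring ", path, ": non-numeric value in field ", k)
  }
  if (any(df$width <= 0) || any(df$height <= 0))
    stop("anchoring ", path, ": width and height must be positive")
  uv0 <- rowSums(abs(as.matrix(df[c("ux", "uy", "uz")]))) == 0 &
    rowSums(abs(as.matrix(df[c("vx", "vy", "vz")]))) == 0
  if (any(uv0))
    warning("anchoring ", path, ": u and v both zero for slice ",
            df$filename[which(uv0)[1]], " (degenerate plane)")
  df$section_key <- section_key(df$filename, pattern)
  dup <- df$section_key[duplicated(df$section_key)]
  if (length(dup))
    stop("anchoring ", path, ": duplicate section key ", dup[1])
  df <- df[c("section_key", "filename", "width", "height", vec_keys)]
  rownames(df) <- NULL
  structure(df, class = c("anchoring", "data.frame"))
}

#' Serialize anchoring to XML or JSON
#' @param anchors an `anchoring` data.frame (see [read_anchoring()]).
#' @param path output path; format chosen by extension unless given.
#' @param format `"auto"`, `"xml"` or `"json"`.
#' @export
write_anchoring <- function(anchors, path, format = c("auto", "xml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "xml"
  vec_keys <- c("ox", "oy", "oz", "ux", "uy", "uz", "vx", "vy", "vz")
  if (format == "json") {
    lst <- lapply(seq_len(nrow(anchors)), function(i) {
      c(list(filename = anchors$filename[i],
             width = anchors$width[i], height = anchors$height[i]),
        as.list(anchors[i, vec_keys]))
    })
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    doc <- xml2::xml_new_root("series")
    for (i in seq_len(nrow(anchors))) {
      at <- c(filename = anchors$filename[i],
              width = format(anchors$width[i], digits = 17),
              height = format(anchors$height[i], digits = 17),
              vapply(vec_keys, function(k)
                format(anchors[[k]][i], digits = 17), ""))
      do.call(xml2::xml_add_child, c(list(doc, "slice"), as.list(at)))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Extract section keys from filenames
#'
#' @param filenames character vector.
#' @param pattern regex with exactly one capture group; the default
#'   matches serial-section naming like `image_s014.png`.  Keys are
#'   normalised by stripping leading zeros so `s014` and `s14` match.
#' @return character keys; NA where the pattern does not match.
#' @export
section_key <- function(filenames, pattern = "_s(\\d+)") {
  m <- regmatches(filenames, regexec(pattern, filenames))
  vapply(m, function(g) {
    if (length(g) < 2L) return(NA_character_)
    sub("^0+(?=\\d)", "", g[2], perl = TRUE)
  }, character(1))
}

#' Match segmentation images, anchors and atlas maps by section
#'
#' Joins the three inputs on the section key embedded in their
#' filenames.  Unmatched items are reported in the result, never
#' silently dropped.
#'
#' @param images character vector of segmentation filenames.
#' @param anchors an `anchoring` data.frame.
#' @param maps character vector of atlas-map filenames.
#' @param pattern section-key regex (see [section_key()]).
#' @return list with `triples` (data.frame `section_key`, `image`,
#'   `map`, plus anchor columns) and `unmatched` (list of leftover
#'   `images`, `anchors`, `maps`).
#' @export
match_sections <- function(images, anchors, maps, pattern = "_s(\\d+)") {
  ik <- section_key(basename(images), pattern)
  mk <- section_key(basename(maps), pattern)
  if (anyNA(ik))
    stop("cannot extract a section key from image(s): ",
         paste(images[is.na(ik)], collapse = ", "))
  if (anyNA(mk))
    stop("cannot extract a section key from map(s): ",
         paste(maps[is.na(mk)], collapse = ", "))
  for (nm in list(c("image", "ik"), c("map", "mk"))) {
    k <- get(nm[2])
    dup <- k[duplicated(k)]
    if (length(dup))
      stop("ambiguous ", nm[1], " naming: key ", dup[1], " extracted from: ",
           paste(get(if (nm[1] == "image") "images" else "maps")[k == dup[1]],
                 collapse = ", "))
  }
  ak <- anchors$section_key
  common <- intersect(intersect(ik, ak), mk)
  ord <- order(suppressWarnings(as.numeric(common)), common)
  common <- common[ord]
  tri <- data.frame(section_key = common,
                    image = images[match(common, ik)],
                    map = maps[match(common, mk)],
                    stringsAsFactors = FALSE)
  tri <- cbind(tri, as.data.frame(anchors)[match(common, ak),
                                           setdiff(names(anchors),
                                                   c("section_key", "filename")),
                                           drop = FALSE])
  rownames(tri) <- NULL
  list(triples = tri,
       unmatched = list(images = images[!(ik %in% common)],
                        anchors = ak[!(ak %in% common)],
                        maps = maps[!(mk %in% common)]))
}
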