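# Small in-code fixtures shared by test files.

tiny_table <- function() {
  label_table(data.frame(
    id = c(1L, 2L, 3L, 5L, 6L),
    name = c("Isocortex", "Hippocampal formation", "Olfactory areas",
             "Thalamus", "Hypothalamus"),
    acronym = c("CTX", "HPF", "OLF", "TH", "HY"),
    red = c(31L, 126L, 154L, 255L, 230L),
    green = c(120L, 208L, 210L, 144L, 68L),
    blue = c(180L, 75L, 189L, 159L, 56L),
    parent_id = c(NA, NA, 1L, NA, 5L)
  ))
}

# map with a vertical half split: left = region 1, right = region 2
half_map <- function(h = 8L, w = 8L) {
  m <- matrix(1L, h, w)
  m[, (w %/% 2 + 1L):w] <- 2L
  atlasquant:::new_atlas_map(m)
}

# segmentation image (h x w x 3) with the given pixels (0-based x,y)
# set to `colour` over a white background
seg_image <- function(h, w, pixels, colour = c(255L, 0L, 255L)) {
  img <- array(255L, dim = c(h, w, 3L))
  for (c in 1:3)
    img[cbind(pixels[, 2] + 1L, pixels[, 1] + 1L, c)] <- colour[c]
  img
}

one_anchor <- function(o = c(0, 0, 0), u = c(10, 0, 0), v = c(0, 0, 10),
                       width = 100, height = 100, key = "14") {
  df <- data.frame(section_key = key,
                   filename = paste0("img_s", key, ".png"),
                   width = width, height = height,
                   ox = o[1], oy = o[2], oz = o[3],
                   ux = u[1], uy = u[2], uz = u[3],
                   vx = v[1], vy = v[2], vz = v[3],
                   stringsAsFactors = FALSE)
  class(df) <- c("anchoring", "data.frame")
  df
}
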