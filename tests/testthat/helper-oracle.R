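# Independent oracles used across test files.

# Brute-force frontier BFS connected-component labelling, written
# independently of the package's compiled flood fill.  Visits seeds in
# column-major order; use canonical_labels() before comparing
# partitions.
oracle_label <- function(mask, connectivity) {
  h <- nrow(mask); w <- ncol(mask)
  if (connectivity == 4L) {
    dx <- c(0L, 0L, -1L, 1L); dy <- c(-1L, 1L, 0L, 0L)
  } else {
    dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  }
  lab <- matrix(0L, h, w)
  id <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    id <- id + 1L
    lab[s] <- id
    frontier <- s
    while (length(frontier)) {
      y <- (frontier - 1L) %% h
      x <- (frontier - 1L) %/% h
      cx <- as.vector(outer(x, dx, `+`))
      cy <- as.vector(outer(y, dy, `+`))
      keep <- cx >= 0L & cx < w & cy >= 0L & cy < h
      idx <- unique(cx[keep] * h + cy[keep] + 1L)
      idx <- idx[mask[idx] & lab[idx] == 0L]
      lab[idx] <- id
      frontier <- idx
    }
  }
  lab
}

# Relabel components by order of first occurrence in column-major scan,
# so two labelings of the same partition compare equal.
canonical_labels <- function(lab) {
  v <- as.vector(lab)
  nz <- v != 0L
  first <- v[nz][!duplicated(v[nz])]
  v[nz] <- match(v[nz], first)
  matrix(v, nrow = nrow(lab))
}

random_mask <- function(h, w, density) {
  matrix(stats::runif(h * w) < density, h, w)
}

# Nearest-neighbour rescale oracle: independent per-output-pixel centre
# mapping.
oracle_rescale <- function(m, width, height) {
  out <- matrix(0L, height, width)
  for (j in seq_len(width)) {
    for (i in seq_len(height)) {
      sx <- min(floor((j - 0.5) * ncol(m) / width), ncol(m) - 1L) + 1L
      sy <- min(floor((i - 0.5) * nrow(m) / height), nrow(m) - 1L) + 1L
      out[i, j] <- m[sy, sx]
    }
  }
  out
}
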