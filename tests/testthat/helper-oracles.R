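# Independent brute-force oracles. These deliberately use slow elementwise
# loops and a separate code path from the package internals.

# per-pixel max over the three colour planes
oracle_v_plane <- function(pixels) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- max(pixels[i, j, 1], pixels[i, j, 2], pixels[i, j, 3])
  out
}

# occurrence counts of each brightness level 0..255
oracle_counts <- function(v) {
  out <- integer(256)
  for (p in as.integer(v)) out[p + 1L] <- out[p + 1L] + 1L
  out
}

# assign each nonzero level to its bin by linear search over the documented
# floor-based edges, accumulate, take the max
oracle_max_binned <- function(normalized, n_bins) {
  lo <- 1 + floor(255 * (0:(n_bins - 1)) / n_bins)
  hi <- 1 + floor(255 * (1:n_bins) / n_bins) - 1
  content <- numeric(n_bins)
  for (v in 1:255) {
    b <- which(lo <= v & v <= hi)
    stopifnot(length(b) == 1)  # the edges partition 1..255
    content[b] <- content[b] + normalized[v + 1]
  }
  max(content)
}

# random 8-bit RGB frame
random_frame <- function(h, w, sample_id = "RND", marker = "green") {
  px <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
  confocal_image(px, sample_id, 0, marker)
}

# mostly-dark frame with a few bright pixels at random levels
sparse_frame <- function(h = 16, w = 16, n_bright = 8) {
  px <- array(0L, c(h, w, 3))
  pos <- sample(h * w, n_bright)
  lv <- sample(1:255, n_bright, replace = TRUE)
  plane <- matrix(0L, h, w)
  plane[pos] <- lv
  px[, , 2] <- plane
  confocal_image(px, "SPARSE", 0, "green")
}

# simple 3x3 box blur with edge replication (independent of quality_score)
box_blur <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, 1:h, h), c(1, 1:w, w)]
  out <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2)
    out <- out + pad[(1 + di):(h + di), (1 + dj):(w + dj)]
  out / 9
}

# write a tiny manifest CSV for a set of frames
write_panel_manifest <- function(dir, entries) {
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(entries, path, row.names = FALSE)
  path
}
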