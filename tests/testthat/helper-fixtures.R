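# Small scene specs used across tests; full-size study scenes are built only
# where a test needs them.

small_scene_spec <- function(n_cells = 6L, seed = 1L, rates = c(KCC2 = 5),
                             ...) {
  scene_spec(image_height_px = 256L, image_width_px = 256L,
             n_cells = n_cells, channel_rates = rates, seed = seed, ...)
}

# A toy exon model matching the cassette-exon template worked examples:
# exon20 = [100, 200), exon21 = [300, 348), exon22 = [400, 500).
toy_model <- function() {
  exon_model("chr18",
             rbind(c(100, 200), c(300, 348), c(400, 500)),
             focal_exon = 2, expected_focal_length = 48)
}

# Paint a flat-topped disk of the given pixel value; used to build
# constructed calibration scenes with exactly known speckle areas.
paint_disk <- function(img, r, c, radius, value) {
  ri <- max(1, r - radius):min(nrow(img), r + radius)
  ci <- max(1, c - radius):min(ncol(img), c + radius)
  d2 <- outer((ri - r)^2, (ci - c)^2, "+")
  img[ri, ci][d2 <= radius^2] <- value
  img
}

# Label mask with n single-pixel objects on a grid (for cell counting).
grid_mask <- function(n, h = 120, w = 120) {
  m <- matrix(0L, h, w)
  k <- ceiling(sqrt(n))
  i <- 0L
  for (r in seq_len(k)) for (c in seq_len(k)) {
    if (i >= n) break
    i <- i + 1L
    m[r * floor(h / (k + 1)), c * floor(w / (k + 1))] <- i
  }
  label_mask(m)
}
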