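# Shared fixture builders: constructed binary/intensity images with known
# geometry, used across segmentation and compartment tests.

# blank [0,1] image matrix
blank_img <- function(w = 64, h = 64, value = 0) matrix(value, w, h)

# paint a disk; returns the modified matrix
paint_disk <- function(img, cx, cy, r, val = 1) {
  xs <- pmax(1, floor(cx - r)):pmin(nrow(img), ceiling(cx + r))
  ys <- pmax(1, floor(cy - r)):pmin(ncol(img), ceiling(cy + r))
  d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  sub <- img[xs, ys, drop = FALSE]
  sub[d2 <= r^2] <- val
  img[xs, ys] <- sub
  img
}

# paint a thick segment
paint_segment <- function(img, x0, y0, x1, y1, thickness, val = 1) {
  hw <- thickness / 2
  xs <- pmax(1, floor(min(x0, x1) - hw)):pmin(nrow(img), ceiling(max(x0, x1) + hw))
  ys <- pmax(1, floor(min(y0, y1) - hw)):pmin(ncol(img), ceiling(max(y0, y1) + hw))
  px <- matrix(xs, length(xs), length(ys))
  py <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx^2 + dy^2
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / L2))
  d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
  sub <- img[xs, ys, drop = FALSE]
  sub[d2 <= hw^2] <- val
  img[xs, ys] <- sub
  img
}

# a soma label image containing one labeled disk
soma_label <- function(w, h, cx, cy, r) {
  m <- paint_disk(blank_img(w, h), cx, cy, r, 1)
  matrix(as.integer(m > 0), w, h)
}

# default test scene: 9 cells, 2 extracellular nuclei, unit pixel size
test_scene <- function(seed, ...) {
  culture_scene(n_cells = 9, n_extra_nuclei = 2, seed = seed, ...)
}

# brute-force maximum-correlation threshold: same smoothing and quantization
# as the implementation, but the criterion is evaluated directly with cor()
mct_oracle_threshold <- function(img, mask, sigma = 1, bins = 256) {
  sm <- if (sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma)) else img
  v <- sm[mask]
  rng <- range(v)
  step <- diff(rng) / bins
  idx <- pmin(bins, pmax(1, ceiling((v - rng[1]) / step)))
  vq <- rng[1] + (idx - 0.5) * step
  lev <- sort(unique(vq))
  cand <- lev[-length(lev)]
  crit <- vapply(cand, function(t) stats::cor(vq, as.numeric(vq > t)), numeric(1))
  cand[which.max(crit)]
}
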