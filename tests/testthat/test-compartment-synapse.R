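test_that("background threshold is twice the histogram mode", {
  img <- blank_img(64, 64, 0.05)
  img <- paint_disk(img, 32, 32, 10, 0.9)
  mask <- background_threshold(img)
  thr <- attr(mask, "threshold")
  expect_lt(abs(thr - 0.10), 0.01)           # 2 x mode, mode ~ 0.05
  expect_true(all(img[mask] > thr))
  expect_equal(sum(mask), sum(img == 0.9))   # exactly the painted object

  const <- blank_img(32, 32, 0.4)
  expect_equal(sum(background_threshold(const)), 0)
})

test_that("background threshold recovers the painted MAP2 area on a render", {
  sc <- culture_scene(n_cells = 9, seed = 19)
  r <- gen_culture_image(sc, 0)
  map2 <- EBImage::imageData(EBImage::medianFilter(
    EBImage::Image(r$channels$map2), size = 1))
  mask <- background_threshold(map2)
  # the painted geometry is essentially fully covered ...
  expect_gt(mean(mask[r$truth$cell_mask]), 0.99)
  # ... while background away from the point-spread halo stays excluded
  halo <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(r$truth$cell_mask * 1), EBImage::makeBrush(9, "disc"))) > 0
  expect_lt(mean(mask[!halo]), 0.01)
})

test_that("compartment split separates soma from a thin tail", {
  img <- blank_img(96, 96)
  img <- paint_disk(img, 40, 48, 20, 1)
  img <- paint_segment(img, 60, 48, 90, 48, 1.5, 1)  # 1-px-wide tail
  masks <- split_compartments(img > 0)
  tail_px <- which(img > 0 & col(img) == 48 & row(img) > 70)
  expect_false(any(masks$soma[tail_px]))
  expect_true(any(masks$neurite[tail_px]))
  # invariants
  expect_true(all(masks$cell[masks$soma]))
  expect_true(all(masks$cell[masks$neurite]))
  expect_false(any(masks$soma & masks$neurite))
})

test_that("compartment masks stay disjoint on random blob masks", {
  set.seed(99)
  for (i in 1:200) {
    m <- blank_img(48, 48)
    for (j in 1:sample(1:4, 1))
      m <- paint_disk(m, runif(1, 5, 43), runif(1, 5, 43), runif(1, 2, 9), 1)
    if (runif(1) < 0.5)
      m <- paint_segment(m, runif(1, 1, 48), runif(1, 1, 48),
                         runif(1, 1, 48), runif(1, 1, 48), 2, 1)
    masks <- split_compartments(m > 0)
    expect_false(any(masks$soma & masks$neurite))
    expect_true(all(masks$cell[masks$soma]))
    expect_true(all(masks$cell[masks$neurite]))
  }
  e <- split_compartments(blank_img(16, 16) > 0)
  expect_equal(sum(e$cell) + sum(e$soma) + sum(e$neurite), 0)
})

test_that("maximum-correlation threshold separates two-level images", {
  set.seed(5)
  img <- blank_img(48, 48, 0.1)
  img <- paint_disk(img, 24, 24, 8, 0.9)
  mask <- matrix(TRUE, 48, 48)
  got <- mct_threshold(img, mask, sigma = 0)
  thr <- attr(got, "threshold")
  expect_gt(thr, 0.1); expect_lt(thr, 0.9)
  expect_equal(sum(got), sum(img == 0.9))
  expect_error(mct_threshold(blank_img(16, 16, 0.5)), "degenerate")
})

test_that("maximum-correlation threshold equals the brute-force criterion search", {
  set.seed(123)
  for (i in 1:30) {
    img <- matrix(sample(seq(0, 1, length.out = 16), 32 * 32, TRUE), 32, 32)
    mask <- matrix(TRUE, 32, 32)
    got <- mct_threshold(img, mask, sigma = 1)
    expect_equal(attr(got, "threshold"), mct_oracle_threshold(img, mask, sigma = 1))
  }
})

test_that("densities are ratios of thresholded to total compartment area", {
  w <- 96
  cell <- paint_disk(blank_img(w, w), 48, 48, 24, 1)
  masks <- split_compartments(cell > 0)
  # uniformly bright synaptophysin over the whole image -> every ratio 1
  syn_hi <- blank_img(w, w, 0.05)
  syn_hi[masks$cell] <- 0.9
  d1 <- synaptophysin_density(syn_hi, masks, sigma = 0, median_filter = FALSE)
  expect_equal(d1$ratio_soma, 1)
  # no in-domain signal -> ratio 0
  syn_lo <- blank_img(w, w, 0.05)
  syn_lo <- paint_disk(syn_lo, 90, 90, 4, 0.9)  # signal outside the cell
  d0 <- synaptophysin_density(syn_lo, masks, sigma = 0, median_filter = FALSE)
  expect_equal(d0$ratio_soma, 0)
  # empty compartment -> NA
  empty_masks <- split_compartments(blank_img(w, w) > 0)
  dna <- synaptophysin_density(syn_hi, empty_masks)
  expect_true(all(is.na(unlist(dna))))
})

test_that("puncta covering half the soma give a soma density near 0.5", {
  w <- 128
  cell <- paint_disk(blank_img(w, w), 64, 64, 30, 1)
  masks <- split_compartments(cell > 0)
  syn <- blank_img(w, w, 0.05)
  # paint the left half of the soma bright
  sel <- masks$soma & row(masks$soma) <= 64
  syn[sel] <- 0.9
  set.seed(3); syn <- syn + matrix(rnorm(w * w, 0, 0.01), w, w)
  d <- synaptophysin_density(syn, masks, sigma = 0, median_filter = FALSE)
  half <- sum(sel) / sum(masks$soma)
  expect_lt(abs(d$ratio_soma - half), 0.05)
})

test_that("densities are invariant to positive intensity rescaling", {
  sc <- culture_scene(n_cells = 4, width = 340, height = 340, seed = 23)
  r <- gen_culture_image(sc, 0)
  map2 <- EBImage::imageData(EBImage::medianFilter(
    EBImage::Image(r$channels$map2), size = 1))
  masks <- split_compartments(background_threshold(map2))
  d1 <- synaptophysin_density(r$channels$synaptophysin, masks,
                              median_filter = FALSE)
  d2 <- synaptophysin_density(0.5 * r$channels$synaptophysin, masks,
                              median_filter = FALSE)
  expect_equal(unlist(d1), unlist(d2), tolerance = 1e-8)
})

test_that("adding above-threshold puncta never lowers a compartment density", {
  w <- 96
  cell <- paint_disk(blank_img(w, w), 48, 48, 24, 1)
  masks <- split_compartments(cell > 0)
  set.seed(11)
  syn <- blank_img(w, w, 0.05) + matrix(rnorm(w * w, 0, 0.01), w, w)
  syn <- paint_disk(syn, 44, 44, 3, 0.9)
  d_before <- synaptophysin_density(syn, masks, sigma = 0, median_filter = FALSE)
  syn2 <- paint_disk(syn, 54, 50, 3, 0.9)
  d_after <- synaptophysin_density(syn2, masks, sigma = 0, median_filter = FALSE)
  expect_gte(d_after$ratio_soma, d_before$ratio_soma)
})

test_that("group comparison applies the Bonferroni-corrected criterion", {
  set.seed(61)
  same <- data.frame(ratio_cell = rep(0.3, 6) + rnorm(6, 0, 1e-6),
                     ratio_soma = rep(0.5, 6) + rnorm(6, 0, 1e-6),
                     ratio_neurite = rep(0.2, 6) + rnorm(6, 0, 1e-6))
  res <- compare_groups(same, same)
  expect_true(all(!res$significant))
  expect_equal(attr(res, "alpha_corrected"), 0.05 / 3)
  expect_error(compare_groups(same[1, , drop = FALSE], same), ">= 2")

  # groups separated by 5 pooled sd at n = 12 are detected essentially always
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    ctrl <- data.frame(ratio_cell = rnorm(12, 0.30, 0.02),
                       ratio_soma = rnorm(12, 0.50, 0.02),
                       ratio_neurite = rnorm(12, 0.20, 0.02))
    inj <- data.frame(ratio_cell = rnorm(12, 0.30, 0.02),
                      ratio_soma = rnorm(12, 0.60, 0.02),  # +5 sd shift
                      ratio_neurite = rnorm(12, 0.20, 0.02))
    r <- compare_groups(ctrl, inj)
    if (r$significant[r$domain == "soma"]) hits <- hits + 1
  }
  expect_gte(hits, 50 * 0.99)
})
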