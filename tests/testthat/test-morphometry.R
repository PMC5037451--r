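test_that("preprocessing removes impulses and flattens illumination gradients", {
  flat <- blank_img(64, 64, 0.2)
  expect_equal(preprocess_live(flat), flat)

  imp <- flat; imp[30, 30] <- 1
  expect_equal(preprocess_live(imp, correct_illumination = FALSE), flat)

  # linear illumination gradient of known amplitude (generator-style)
  grad <- matrix(rep(seq(0.05, 0.25, length.out = 64), 64), 64, 64)
  corr <- preprocess_live(grad)
  expect_lt(diff(range(corr)), 0.02)
  expect_error(preprocess_live(array(0, c(4, 4, 2))), "2D")
})

test_that("nucleus segmentation counts separated and clumped nuclei", {
  expect_equal(max(segment_nuclei(blank_img(64, 64, 0.05), pixel_size = 1)), 0)

  img <- blank_img(128, 128, 0.05)
  centers <- expand.grid(x = c(20, 60, 100), y = c(20, 60, 100))
  for (i in seq_len(9)) img <- paint_disk(img, centers$x[i], centers$y[i], 5, 0.9)
  img <- paint_disk(img, 20, 100, 5, 0.9)  # 10th, re-painting corner is idempotent
  lab <- segment_nuclei(img, pixel_size = 1)
  expect_equal(max(lab), 9)

  # two overlapping nuclei with distinct peaks are declumped by watershed
  two <- blank_img(64, 64, 0.05)
  two <- paint_disk(two, 28, 32, 6, 0.9)
  two <- paint_disk(two, 39, 32, 6, 0.9)
  expect_equal(max(segment_nuclei(two, pixel_size = 1)), 2)
})

test_that("cell segmentation applies the nucleus and size rejection rules", {
  w <- 128
  nuc <- blank_img(w, w, 0.05); via <- blank_img(w, w, 0.05)
  # viable cell: soma + nucleus
  via <- paint_disk(via, 30, 30, 9, 0.85); nuc <- paint_disk(nuc, 30, 30, 5, 0.9)
  # dead cell: nucleus without calcein
  nuc <- paint_disk(nuc, 90, 30, 5, 0.9)
  # bead: small bright viability blob with no nucleus
  via <- paint_disk(via, 60, 90, 4, 0.85)
  nuclei <- segment_nuclei(nuc, pixel_size = 1)
  seg <- segment_cells(via, nuclei, pixel_size = 1)
  expect_equal(seg$n_viable, 1)
  expect_equal(seg$n_dead, 1)
  expect_equal(nrow(seg$rejected), 1)
  expect_equal(seg$rejected$reason, "no_nucleus")
})

test_that("generator somata are all recovered as viable cells", {
  sc <- culture_scene(n_cells = 9, seed = 31)
  r <- gen_culture_image(sc, 0)
  res <- analyze_live_image(r$channels$nuclear, r$channels$viability,
                            pixel_size = sc$pixel_size)
  expect_equal(res$segmentation$n_viable, 9)
  expect_equal(res$segmentation$n_dead, 0)
})

test_that("a straight neurite is traced to within 5% of its true length", {
  w <- 128
  via <- blank_img(w, w, 0)
  via <- paint_disk(via, 30, 64, 9, 1)
  via <- paint_segment(via, 30, 64, 110, 64, 3, 1)  # length 80 - 9 = 71 beyond soma
  som <- soma_label(w, w, 30, 64, 9)
  tn <- trace_neurites(via > 0.5, som, pixel_size = 1, soma_margin_px = 0)
  expect_equal(tn$n_processes, 1L)
  expect_lt(abs(tn$total_length_um - 71) / 71, 0.05)
})

test_that("a Y-shaped neurite yields one process and one branch point", {
  w <- 128
  via <- blank_img(w, w, 0)
  via <- paint_disk(via, 20, 64, 9, 1)
  via <- paint_segment(via, 20, 64, 70, 64, 3, 1)
  via <- paint_segment(via, 70, 64, 100, 44, 3, 1)
  via <- paint_segment(via, 70, 64, 100, 84, 3, 1)
  som <- soma_label(w, w, 20, 64, 9)
  tn <- trace_neurites(via > 0.5, som, pixel_size = 1, soma_margin_px = 0)
  expect_equal(tn$n_processes, 1L)
  expect_equal(tn$n_branches, 1L)
  # path property: skeleton length of the main limb exceeds the endpoint gap
  expect_gt(tn$total_length_um, sqrt((100 - 29)^2))
  expect_equal(nrow(tn$components), 1)
  expect_true(all(tn$components$attached))
})

test_that("a soma with no neurites yields an empty skeleton graph", {
  w <- 64
  via <- paint_disk(blank_img(w, w, 0), 32, 32, 9, 1)
  som <- soma_label(w, w, 32, 32, 9)
  tn <- trace_neurites(via > 0.5, som, pixel_size = 1)
  expect_equal(tn$total_length_um, 0)
  expect_equal(tn$n_processes, 0L)
  expect_error(trace_neurites(via > 0.5, som, pixel_size = NULL), "pixel_size")
})

test_that("well metrics satisfy the definitional identities", {
  seg <- list(n_viable = 0L, n_dead = 0L)
  neur <- list(total_length_um = 0, n_processes = 0L, n_branches = 0L)
  m0 <- well_injury_metrics(seg, neur, reference_count = 100)
  expect_true(all(m0[, c("viable_cells_per_image", "dead_cells_per_image",
                         "neurite_length_per_cell", "total_neurite_length",
                         "cell_viability")] == 0))

  seg2 <- list(n_viable = 4L, n_dead = 3L)
  neur2 <- list(total_length_um = 210, n_processes = 9L, n_branches = 5L)
  m <- well_injury_metrics(seg2, neur2, reference_count = 10)
  expect_equal(m$total_neurite_length,
               m$neurite_length_per_cell * m$viable_cells_per_image)
  expect_equal(m$cell_viability, 40)
  expect_true(is.na(well_injury_metrics(seg2, neur2, reference_count = 0)$cell_viability))
})

test_that("an isolated calcein-negative nucleus adds exactly one dead cell", {
  sc <- culture_scene(n_cells = 4, width = 340, height = 340, seed = 41)
  r <- gen_culture_image(sc, 0)
  base <- analyze_live_image(r$channels$nuclear, r$channels$viability,
                             pixel_size = 1)
  nuc2 <- paint_disk(r$channels$nuclear, 170, 170, 5, 0.9)  # between cells
  plus <- analyze_live_image(nuc2, r$channels$viability, pixel_size = 1)
  expect_equal(plus$segmentation$n_dead, base$segmentation$n_dead + 1)
  expect_equal(plus$segmentation$n_viable, base$segmentation$n_viable)
  expect_equal(plus$metrics$total_neurite_length, base$metrics$total_neurite_length)
})

test_that("counts are stable under whole-pixel translation", {
  sc <- culture_scene(n_cells = 4, width = 340, height = 340, seed = 43)
  r <- gen_culture_image(sc, 0.3)
  shift <- function(m, d) {
    out <- matrix(0.05, nrow(m), ncol(m))
    out[(1 + d):nrow(m), ] <- m[1:(nrow(m) - d), ]
    out
  }
  a <- analyze_live_image(r$channels$nuclear, r$channels$viability, pixel_size = 1)
  b <- analyze_live_image(shift(r$channels$nuclear, 3),
                          shift(r$channels$viability, 3), pixel_size = 1)
  expect_equal(b$segmentation$n_viable, a$segmentation$n_viable)
  expect_equal(b$segmentation$n_dead, a$segmentation$n_dead)
})

test_that("measured per-cell neurite length declines with injury", {
  sc <- test_scene(47)
  lens <- vapply(c(0, 0.5, 1), function(lev) {
    r <- gen_culture_image(sc, lev)
    res <- analyze_live_image(r$channels$nuclear, r$channels$viability,
                              pixel_size = 1)
    res$metrics$neurite_length_per_cell
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})
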