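test_that("axial Green-Lagrange strain matches hand-computed values", {
  expect_equal(axial_lagrangian_strain(1.5, 1.5), 0)
  # u/X = 0.2 -> 0.2 + 0.5 * 0.04 = 0.22
  expect_equal(axial_lagrangian_strain(1.5, 1.8), 0.22)
  # closed-form inverse: lambda = sqrt(1 + 2 E)
  expect_equal(axial_lagrangian_strain(1.0, sqrt(1 + 2 * 0.45)), 0.45,
               tolerance = 1e-12)
  expect_equal(lagrangian_stretch(axial_lagrangian_strain(2, 2.6)), 2.6 / 2)
})

test_that("axial strain rejects invalid lengths and is monotone and unit-free", {
  expect_error(axial_lagrangian_strain(0, 1), "invalid")
  expect_error(axial_lagrangian_strain(1, -1), "invalid")
  finals <- seq(0.5, 3, by = 0.1)
  e <- axial_lagrangian_strain(1.2, finals)
  expect_true(all(diff(e) > 0))
  # scaling all lengths by a common factor leaves strain unchanged
  expect_equal(axial_lagrangian_strain(1.5, 1.8),
               axial_lagrangian_strain(1.5 * 25.4, 1.8 * 25.4))
})

test_that("well strain averages replicate strains and reports the spread", {
  one <- data.frame(pre_width = 1.5, pre_height = 1.5,
                    post_width = 1.8, post_height = 1.8)
  ws <- well_strain(one)
  expect_equal(ws$Exx, 0.22); expect_equal(ws$Eyy, 0.22); expect_equal(ws$E, 0.22)
  expect_equal(ws$se, 0)

  # anisotropic case: E is the arithmetic mean of the axial strains
  l04 <- lagrangian_stretch(0.4); l05 <- lagrangian_stretch(0.5)
  an <- data.frame(pre_width = 1.5, pre_height = 1.5,
                   post_width = 1.5 * l04, post_height = 1.5 * l05)
  wa <- well_strain(an)
  expect_equal(wa$Exx, 0.4); expect_equal(wa$Eyy, 0.5); expect_equal(wa$E, 0.45)

  reps <- one[rep(1, 5), ]
  expect_equal(well_strain(reps)$se, 0)
  expect_error(well_strain(one[0, ]), "at least one")
  mixed <- rbind(cbind(one, unit = "mm"), cbind(one, unit = "px"))
  expect_error(well_strain(mixed), "mixed units")
})

test_that("plate strain map round-trips the synthetic generator exactly", {
  lay <- plate_layout()
  spec <- strain_field_spec("aligned", 0.45, 0.051, replicate_sd = 0, seed = 11)
  g <- gen_dot_measurements(lay, spec)
  m <- plate_strain_map(g$measurements, lay)
  expect_equal(nrow(m), nrow(g$truth))
  err <- abs(m$E[match(g$truth$well, m$well)] - g$truth$strain)
  expect_lt(max(err), 1e-10)
  expect_true(all(m$is_control[m$well %in% lay$control_wells]))
})

test_that("measurements in excluded wells are dropped with a warning", {
  lay <- plate_layout()
  g <- gen_dot_measurements(lay, strain_field_spec(seed = 2))
  bad <- g$measurements[1, ]
  bad$well <- "A1"
  expect_warning(m <- plate_strain_map(rbind(g$measurements, bad), lay),
                 "excluded")
  expect_false("A1" %in% m$well)
})

test_that("misaligned plates show higher strain on the right side", {
  lay <- plate_layout()
  spec <- strain_field_spec("misaligned", 0.45, 0.02, gradient = 0.04, seed = 5)
  g <- gen_dot_measurements(lay, spec)
  m <- plate_strain_map(g$measurements, lay)
  cols <- as.integer(substring(m$well, 2))
  inj <- !m$is_control
  expect_gt(mean(m$E[inj & cols == 11]), mean(m$E[inj & cols == 2]))
})

test_that("strain distribution summary uses the sample (n-1) convention", {
  ws <- data.frame(well = c("B2", "B3"), E = c(0.4, 0.5))
  s <- summarize_strain_distribution(ws)
  expect_equal(s$mean, 0.45)
  expect_equal(s$sd, 0.07071068, tolerance = 1e-7)  # sd with n-1 denominator
  expect_error(summarize_strain_distribution(ws[1, , drop = FALSE]), "at least 2")
  const <- data.frame(well = c("B2", "B3", "B4"), E = rep(0.3, 3))
  expect_equal(summarize_strain_distribution(const)$sd, 0)
})

test_that("aligned 60-well plates recover the prescribed strain distribution", {
  lay60 <- plate_layout(control_wells = character(0))
  spec <- strain_field_spec("aligned", 0.45, 0.051, seed = 21)
  g <- gen_dot_measurements(lay60, spec)
  m <- plate_strain_map(g$measurements, lay60)
  expect_equal(nrow(m), 60)
  s <- summarize_strain_distribution(m)
  expect_lt(abs(s$mean - 0.45), 0.02)
})

test_that("displacement-strain line matches the closed-form least squares", {
  # exactly collinear points
  d <- c(1, 2, 3, 4); e <- 0.02 + 0.11 * d
  fit <- displacement_strain_curve(d, e, negligible_threshold = 0)
  expect_equal(fit$slope, 0.11)
  expect_equal(fit$intercept, 0.02)
  expect_lt(max(abs(fit$residuals)), 1e-12)

  # noisy 3-point fit vs the normal equations solved by hand
  d2 <- c(1, 2.9, 4.7); e2 <- c(0.01, 0.31, 0.46)
  f2 <- displacement_strain_curve(d2, e2)
  X <- cbind(1, d2)
  beta <- solve(t(X) %*% X, t(X) %*% e2)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-12)
  expect_equal(f2$slope, beta[2], tolerance = 1e-12)

  # the lowest level barely strains the membrane and gets flagged
  f3 <- displacement_strain_curve(c(1, 2, 3), c(0.005, 0.2, 0.4))
  expect_equal(f3$negligible, c(TRUE, FALSE, FALSE))
  expect_error(displacement_strain_curve(c(1, 1), c(0.1, 0.1)), "distinct")
})
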