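test_that("phase assignment follows the left-closed area intervals", {
  expect_equal(assign_phase(5000), 1L)
  expect_equal(assign_phase(6500), 2L)
  expect_equal(assign_phase(40000), 3L)
  ## total and monotone non-decreasing
  areas <- sort(exp(runif(200, log(100), log(1e5))))
  ph <- assign_phase(areas)
  expect_true(all(ph %in% 1:3))
  expect_true(all(diff(ph) >= 0))
  expect_error(assign_phase(0), "positive")
  expect_error(phase_thresholds(10, 5), "t12")
})

test_that("measure populates 24 deterministic parameters", {
  g <- generate_chamber(3000, "wt", seed = 3, config = quiet_cfg())
  r1 <- measure(g); r2 <- measure(g)
  expect_identical(r1, r2)
  expect_equal(ncol(r1) - 2L, 24L)   # 24 quantitative + genotype + phase
  expect_equal(r1$oocyte_fraction_of_germline, 1 / 16, tolerance = 1e-3)
  expect_true(r1$prop_fc_on_oocyte >= 0 && r1$prop_fc_on_oocyte <= 1)
  expect_true(r1$interface_angle > 0 && r1$interface_angle < 180)
  ## phase-3 chamber has 6 anterior rows on the nurse-cell side
  r3 <- measure(generate_chamber(40000, "wt", seed = 3, config = quiet_cfg()))
  expect_equal(r3$afc_row_count_on_nc, 6)
})

test_that("contact proportion matches a dense-polygon arc-length oracle", {
  cfg <- quiet_cfg()
  g <- generate_chamber(3000, "wt", seed = 1, config = cfg)
  ## oracle: fraction of finely sampled boundary arc posterior of the
  ## interface chord, converted to a count proportion over uniform cells
  a <- g$a; b <- g$b; x0 <- g$chord_x
  th <- seq(0, 2 * pi, length.out = 100001)
  xy <- cbind(a * cos(th), b * sin(th))
  ds <- sqrt(rowSums(diff(xy)^2))
  xm <- (xy[-1, 1] + xy[-nrow(xy), 1]) / 2
  arc_frac <- sum(ds[xm >= x0]) / sum(ds)
  n_half <- g$fc_count_section %/% 2L
  expected <- (n_half - round(n_half * (1 - arc_frac))) / n_half
  expect_equal(contact_proportion(g), expected, tolerance = 1e-8)
  ## proportions on the two germline compartments sum to one exactly
  d <- pmin(g$fc_s, g$perimeter - g$fc_s)
  s_if <- eggchamber:::interface_arc_position(g)
  expect_equal(mean(d > s_if) + mean(d <= s_if), 1, tolerance = 1e-12)
})

test_that("contact proportion degenerates correctly", {
  g <- generate_chamber(3000, "wt", seed = 1, config = quiet_cfg())
  g$oocyte_fraction <- 0
  expect_equal(contact_proportion(g), 0)
  g$oocyte_fraction <- 1
  expect_equal(contact_proportion(g), 1)
})

test_that("interface angle: symmetric circle with a diameter interface gives 90", {
  ## circle split into symmetric halves by a straight vertical diameter
  iface <- eggchamber:::build_interface(50, 50, 0.5, 90)
  g <- list(a = 50, b = 50, perimeter = 2 * pi * 50,
            outer_contour = eggchamber:::ellipse_contour(50, 50, 720L),
            nc_oocyte_interface = iface$interface,
            chord_x = iface$x0)
  expect_equal(interface_angle(g), 90, tolerance = 0.5)
})

test_that("interface angle recovers encoded wetting and de-wetting angles", {
  cfg <- quiet_cfg()
  for (area in c(3000, 15000, 40000)) {
    g <- generate_chamber(area, "wt", seed = 2, config = cfg)
    expect_equal(interface_angle(g), g$interface_angle_true, tolerance = 2)
  }
  ## oocyte wetting (<90) in mid phase 2, nurse bulging (>90) in phase 1
  expect_lt(measure(generate_chamber(18000, "wt", 1, cfg))$interface_angle, 90)
  expect_gt(measure(generate_chamber(3000, "wt", 1, cfg))$interface_angle, 90)
})

test_that("interface angle is invariant under dorso-ventral mirroring", {
  g <- generate_chamber(9000, "wt", seed = 5, config = quiet_cfg())
  a0 <- interface_angle(g)
  gm <- g
  gm$outer_contour[, 2L] <- -gm$outer_contour[, 2L]
  gm$nc_oocyte_interface[, 2L] <- -gm$nc_oocyte_interface[, 2L]
  expect_equal(interface_angle(gm), a0, tolerance = 1e-6)
})

test_that("nurse-cell CVs: identical cells give zero, known split gives sd/mean", {
  g <- generate_chamber(3000, "wt", seed = 1, config = quiet_cfg())
  cv <- nurse_cell_cv(g)
  expect_equal(cv$cv_area_fraction, 0, tolerance = 1e-12)
  expect_equal(cv$cv_interface_fraction, 0, tolerance = 1e-12)
  ## two cells at 0.25 / 0.75 -> cv = sd/mean = 0.7071
  g$nc_area_fraction <- c(0.25, 0.75)
  g$nc_interface_fraction <- c(0.5, 0.5)
  expect_equal(nurse_cell_cv(g)$cv_area_fraction, 0.7071068,
               tolerance = 1e-6)
  g$nc_area_fraction <- 0.5
  expect_error(nurse_cell_cv(g), "at least 2")
})

test_that("Eya knockdown disorganizes nurse cells relative to wild type", {
  cfg <- quiet_cfg()
  wt <- nurse_cell_cv(generate_chamber(4000, "wt", 1, cfg))
  kd <- nurse_cell_cv(generate_chamber(4000, "gr1_eyaRNAi", 1, cfg))
  expect_gt(kd$cv_area_fraction, wt$cv_area_fraction)
  expect_gt(kd$cv_interface_fraction, wt$cv_interface_fraction)
})

test_that("apical profile: flat in phase 1, anterior-high gradient in phase 2", {
  cfg <- quiet_cfg()
  p1 <- apical_area_profile(generate_chamber(3000, "wt", 1, cfg))
  expect_lt(diff(range(p1$apical_extent)) / mean(p1$apical_extent), 0.03)
  p2 <- apical_area_profile(generate_chamber(15000, "wt", 1, cfg))
  afc_rows <- p2[p2$row <= 6, ]
  expect_lt(cor(afc_rows$apical_extent, afc_rows$distance_to_anterior,
                method = "spearman"), 0)
})

test_that("measured phase-3 record reproduces the headline proportions", {
  rec <- measure(generate_chamber(45000, "wt", seed = 9, config = quiet_cfg()))
  expect_equal(rec$prop_fc_on_oocyte, 0.84, tolerance = 0.03)
  expect_equal(rec$oocyte_fraction_of_germline, 0.40, tolerance = 0.02)
  expect_gt(rec$interface_angle, 90)
  expect_gt(rec$eya_mean_anterior, 72)
  expect_lt(rec$eya_mean_posterior, 72)
})
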