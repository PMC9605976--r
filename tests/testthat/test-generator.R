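test_that("a cyst has 16 cells, one oocyte, fifteen nurse cells, unit mass", {
  cyst <- generate_cyst(1, 0)
  expect_equal(nrow(cyst), 16L)
  expect_equal(sum(cyst$role == "oocyte"), 1L)
  expect_equal(sum(cyst$role == "nurse"), 15L)
  expect_equal(cyst$volume_fraction, rep(1 / 16, 16))
  ## noisy cyst still normalizes and keeps a single oocyte
  noisy <- generate_cyst(7, 0.1)
  expect_equal(sum(noisy$volume_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(noisy$role == "oocyte"), 1L)
  expect_true(all(noisy$volume_fraction > 0))
  expect_error(generate_cyst(1, -0.2), "cv_volume")
})

test_that("chamber generation is deterministic under a fixed seed", {
  cfg <- generator_config(noise_cv = 0.08)
  g1 <- generate_chamber(3000, "wt", seed = 5, config = cfg)
  g2 <- generate_chamber(3000, "wt", seed = 5, config = cfg)
  expect_identical(g1$fc_eya, g2$fc_eya)
  expect_identical(g1$outer_contour, g2$outer_contour)
  g3 <- generate_chamber(3000, "wt", seed = 6, config = cfg)
  expect_false(identical(g1$fc_eya, g3$fc_eya))
})

test_that("geometry invariants hold across areas, genotypes and seeds", {
  cfg <- generator_config(noise_cv = 0.05)
  for (gt in c("wt", "mirr_eya", "gr1_eyaRNAi", "tj_egfr")) {
    for (area in c(2000, 9000, 40000)) {
      g <- generate_chamber(area, gt, seed = 11, config = cfg)
      expect_true(all(diff(g$fc_s) > 0))                # strictly increasing
      expect_true(all(g$fc_s >= 0 & g$fc_s < g$perimeter))
      expect_true(all(g$fc_eya >= 0))
      expect_gt(g$germline_area, 0)
      expect_lt(polygon_area_of(g$oocyte_region), g$germline_area * 1.001)
    }
  }
})


test_that("round trip: measured area and oocyte fraction match the generator", {
  cfg <- quiet_cfg()
  for (area in c(2000, 8000, 20000, 45000)) {
    g <- generate_chamber(area, "wt", seed = 2, config = cfg)
    rec <- measure(g)
    expect_equal(rec$germline_area, area, tolerance = 5e-3)
    expect_equal(rec$oocyte_fraction_of_germline, g$oocyte_fraction,
                 tolerance = 1e-2)
  }
})

test_that("oocyte fraction progression is non-decreasing up to the phase-2/3 boundary", {
  cfg <- quiet_cfg()
  areas <- seq(1600, 31500, length.out = 40)
  f <- vapply(areas, function(a)
    generate_chamber(a, "wt", seed = 1, config = cfg)$oocyte_fraction,
    numeric(1))
  expect_true(all(diff(f) >= -1e-12))
  expect_equal(f[1L], 1 / 16, tolerance = 1e-9)
})

test_that("the 3-D fate map assigns round(afc_fraction x count) anterior cells", {
  for (seed in c(0, 3, 99)) {
    g <- generate_chamber(9000, "wt", seed = seed,
                          config = generator_config(seed = seed))
    expect_equal(g$afc_count_3d, round(0.10 * 850))
  }
  g2 <- generate_chamber(9000, "wt", seed = 1,
                         config = generator_config(afc_fraction = 0.2,
                                                   fc_count_at_arrest = 700L))
  expect_equal(g2$afc_count_3d, round(0.2 * 700))
})

test_that("phase-1 wild-type Eya is uniformly above the 72-unit zero point", {
  cfg <- quiet_cfg()
  for (area in c(1600, 3000, 6400)) {
    g <- generate_chamber(area, "wt", seed = 4, config = cfg)
    expect_true(all(g$fc_eya > 72))
  }
})

test_that("genotype rules act only beyond their critical sizes", {
  cfg <- quiet_cfg()
  below <- generate_chamber(10000, "mirr_eya", seed = 1, config = cfg)
  wt10k <- generate_chamber(10000, "wt", seed = 1, config = cfg)
  expect_equal(below$fc_eya, wt10k$fc_eya)
  above <- generate_chamber(13000, "mirr_eya", seed = 1, config = cfg)
  wt13k <- generate_chamber(13000, "wt", seed = 1, config = cfg)
  expect_gt(mean(above$fc_eya[above$fc_ordinal >= 7L]),
            mean(wt13k$fc_eya[wt13k$fc_ordinal >= 7L]))
  ## gr1 knockdown collapses Eya above 1600 um^2
  kd <- generate_chamber(2500, "gr1_eyaRNAi", seed = 1, config = cfg)
  wt25 <- generate_chamber(2500, "wt", seed = 1, config = cfg)
  expect_lt(mean(kd$fc_eya), 0.2 * mean(wt25$fc_eya))
  expect_error(generate_chamber(3000, "not_a_genotype", 1, cfg), "genotype")
})

test_that("cohorts are reproducible, span all phases, and write tidy tables", {
  cfg <- generator_config(seed = 42, n_chambers = 60)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  a1 <- vapply(coh1, `[[`, numeric(1), "germline_area")
  a2 <- vapply(coh2, `[[`, numeric(1), "germline_area")
  expect_identical(a1, a2)
  expect_setequal(unique(assign_phase(a1)), 1:3)
  dir <- tempfile()
  paths <- write_cohort(coh1, dir)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths[1L])
  expect_equal(nrow(tab), 60L)
  expect_true(all(morphometric_parameters() %in% names(tab)))
  ## byte-identical rerun
  dir2 <- tempfile()
  write_cohort(generate_cohort(cfg), dir2)
  expect_identical(readLines(file.path(dir, "chambers.csv")),
                   readLines(file.path(dir2, "chambers.csv")))
  expect_error(generate_cohort(generator_config(n_chambers = 0)), "n_chambers")
})
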