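test_that("standardization yields zero mean, unit variance, and drops constants", {
  coh <- small_cohort(24)
  rec <- measure_cohort(coh)
  z <- suppressWarnings(standardize(rec))
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  ## a constant column is flagged and dropped
  rec$fc_count_section <- 74
  expect_warning(z2 <- standardize(rec), "zero-variance")
  expect_false("fc_count_section" %in% colnames(z2))
  expect_error(standardize(rec[1, ]), "at least 2")
})

test_that("pooling with a shifted cohort changes the z-scores of shared rows", {
  wt <- measure_cohort(small_cohort(20, "wt", seed = 1))
  mut <- measure_cohort(small_cohort(20, "gr1_eyaRNAi", seed = 2))
  z_alone <- suppressWarnings(standardize(wt, "wt_alone"))
  z_pool <- suppressWarnings(standardize(rbind(wt, mut),
                                         "pooled_with_control"))
  common <- intersect(colnames(z_alone), colnames(z_pool))
  expect_false(isTRUE(all.equal(z_alone[1, common], z_pool[1, common])))
})

test_that("PCA retention matches an explicit eigendecomposition", {
  set.seed(7)
  z <- scale(matrix(rnorm(60 * 8), 60, 8) %*% matrix(rnorm(64), 8, 8))
  res <- pca_select(z, 0.90)
  ev <- eigen(stats::cov(z), symmetric = TRUE)$values
  cum <- cumsum(ev) / sum(ev)
  ## prcomp divides by n-1 as cov does; cumvar must agree
  expect_equal(res$cumvar, cum, tolerance = 1e-8)
  expect_equal(res$k, which(cum > 0.90)[1L])
  ## rank-1 data retains a single component explaining everything
  r1 <- matrix(rnorm(30), 30, 1) %*% t(c(1, 2, 3))
  res1 <- pca_select(r1)
  expect_equal(res1$k, 1L)
  expect_equal(res1$cumvar[1L], 1, tolerance = 1e-10)
  expect_error(pca_select(z, 1.5), "cumvar_threshold")
})

test_that("UMAP embedding is seeded, tolerant of duplicates, and orders the trajectory", {
  rec <- measure_cohort(small_cohort(80, seed = 3))
  z <- suppressWarnings(standardize(rec))
  pc <- pca_select(z)
  e1 <- umap_embed(pc, germline_area = rec$germline_area, seed = 0)
  e2 <- umap_embed(pc, germline_area = rec$germline_area, seed = 0)
  expect_identical(e1$umap_xy, e2$umap_xy)
  expect_true(all(is.finite(e1$umap_xy)))
  expect_equal(e1$params, list(n_neighbors = 15L, min_dist = 0.2, seed = 0L))
  ## developmental ordering follows germline area
  expect_gt(cor(e1$geodesic, rec$germline_area, method = "spearman"), 0.9)
  ## duplicated rows stay finite
  pc_dup <- rbind(pc$pc_scores, pc$pc_scores[1:10, ])
  e3 <- umap_embed(pc_dup, seed = 1)
  expect_true(all(is.finite(e3$umap_xy)))
  expect_error(umap_embed(pc$pc_scores[1:10, ]), "n_neighbors")
})

test_that("the embedding pipeline is invariant to row order", {
  rec <- measure_cohort(small_cohort(60, seed = 5))
  z <- suppressWarnings(standardize(rec))
  perm <- sample(nrow(z))
  e1 <- umap_embed(pca_select(z), germline_area = rec$germline_area, seed = 2)
  zp <- suppressWarnings(standardize(rec[perm, ]))
  e2 <- umap_embed(pca_select(zp), germline_area = rec$germline_area[perm],
                   seed = 2)
  ## geodesic ordering agrees up to the permutation
  expect_gt(cor(rank(e1$geodesic)[perm], rank(e2$geodesic),
                method = "spearman"), 0.98)
})

test_that("divergence detection flags the ectopic-Eya cohort at its critical size", {
  ctl <- measure_cohort(small_cohort(110, "wt", seed = 1, noise_cv = 0.04,
                                     amin = 2000, amax = 45000))
  mut <- measure_cohort(small_cohort(110, "mirr_eya", seed = 7,
                                     noise_cv = 0.04,
                                     amin = 2000, amax = 45000))
  res <- divergence_point(ctl, mut, critical_size = 11650,
                          critical_ci = c(10630, 12570), B = 100, seed = 3)
  expect_true(res$diverged)
  expect_true(res$area_at_divergence >= 10630 &&
              res$area_at_divergence <= 12570)
  expect_true(res$within_ci)
})

test_that("divergence detection stays silent on wild type versus wild type", {
  a <- measure_cohort(small_cohort(90, "wt", seed = 11, noise_cv = 0.04))
  b <- measure_cohort(small_cohort(90, "wt", seed = 23, noise_cv = 0.04))
  res <- divergence_point(a, b, B = 100, seed = 5)
  expect_false(res$diverged)
  expect_error(divergence_point(a[a$germline_area < 4000, ],
                                b[b$germline_area > 30000, ]),
               "overlap")
})

test_that("gr1 knockdown diverges from control during phase 1", {
  ctl <- measure_cohort(small_cohort(100, "wt", seed = 2, noise_cv = 0.04,
                                     amin = 1700, amax = 20000))
  mut <- measure_cohort(small_cohort(100, "gr1_eyaRNAi", seed = 8,
                                     noise_cv = 0.04,
                                     amin = 1700, amax = 20000))
  res <- divergence_point(ctl, mut, B = 100, seed = 4)
  expect_true(res$diverged)
  expect_lt(res$area_at_divergence, 6500)
})
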