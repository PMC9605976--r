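test_that("LOESS recovers a noiseless line and a constant exactly", {
  x <- seq(1, 100, length.out = 60)
  lc <- loess_curve(x, 2 * x)
  expect_lt(max(abs(lc$fit - 2 * lc$x)), 1e-6)
  cc <- loess_curve(x, rep(5, 60))
  expect_lt(max(abs(cc$fit - 5)), 1e-9)
  expect_true(all(cc$lower <= cc$fit & cc$fit <= cc$upper))
  expect_error(loess_curve(1:5, 1:5), "at least 10")
})

test_that("wild-type contact proportion plateaus near 17-19% through phase 1", {
  rec <- measure_cohort(small_cohort(60, seed = 2, noise_cv = 0.03))
  lc <- loess_curve(rec$germline_area, rec$prop_fc_on_oocyte, span = 0.5)
  p1 <- lc$fit[lc$x < 6000]
  expect_true(all(p1 > 0.14 & p1 < 0.22))
  ## rises through phase 2
  expect_gt(lc$fit[which.min(abs(lc$x - 28000))],
            lc$fit[which.min(abs(lc$x - 8000))])
})

test_that("genotype comparison equals the closed-form least-squares solution", {
  set.seed(3)
  d <- data.frame(germline_area = runif(120, 1000, 50000),
                  genotype = rep(c("ctl", "mut"), each = 60))
  d$y <- 2 + 1e-4 * d$germline_area +
    ifelse(d$genotype == "mut", 5e-5 * d$germline_area - 0.5, 0) +
    rnorm(120, 0, 0.3)
  fit <- compare_genotypes(d, "y")
  X <- cbind(1, d$germline_area, d$genotype == "mut",
             d$germline_area * (d$genotype == "mut"))
  beta <- solve(crossprod(X), crossprod(X, d$y))
  if (fit$used_interaction) {
    expect_equal(unname(fit$coefficients),
                 as.numeric(beta), tolerance = 1e-8)
  } else {
    beta2 <- solve(crossprod(X[, 1:3]), crossprod(X[, 1:3], d$y))
    expect_equal(unname(fit$coefficients), as.numeric(beta2),
                 tolerance = 1e-8)
  }
  expect_error(compare_genotypes(d[d$genotype == "ctl", ], "y"),
               "two genotype levels")
})

test_that("a true slope difference is recovered within two standard errors", {
  set.seed(11)
  d <- data.frame(germline_size = runif(200, 0, 1),
                  genotype = rep(c("a", "b"), each = 100))
  d$y <- 1 + 1.0 * d$germline_size +
    ifelse(d$genotype == "b", 0.5 * d$germline_size, 0) + rnorm(200, 0, 0.1)
  fit <- compare_genotypes(d, "y")
  expect_true(fit$used_interaction)
  est <- fit$coefficients["germline_size:genotype"]
  se <- summary(fit$fit)$coefficients["size:geno", 2L]
  expect_lt(abs(est - 0.5), 2 * se)
})

test_that("the additive fallback triggers on null data and reads off intercept gaps", {
  ## label split of one population: interaction retained in < 10% of seeds
  used <- vapply(1:20, function(s) {
    set.seed(s)
    d <- data.frame(germline_size = runif(200), genotype = rep(c("a", "b"), 100))
    d$y <- 1 + d$germline_size + rnorm(200, 0, 0.2)
    compare_genotypes(d, "y")$used_interaction
  }, logical(1))
  expect_lte(mean(used), 0.10)
  ## zero noise, equal slopes, different intercepts: exact gap via fallback
  d <- data.frame(germline_size = rep(seq(0, 1, length.out = 50), 2),
                  genotype = rep(c("a", "b"), each = 50))
  d$y <- 2 + 3 * d$germline_size + ifelse(d$genotype == "b", 0.75, 0)
  fit <- compare_genotypes(d, "y")
  expect_false(fit$used_interaction)
  expect_equal(unname(fit$coefficients["genotype"]), 0.75, tolerance = 1e-9)
})

test_that("interaction-test type-I error sits near the nominal 5% level", {
  reject <- vapply(1:500, function(s) {
    set.seed(s)
    x <- runif(60); g <- rep(0:1, each = 30)
    y <- x + rnorm(60)
    X <- cbind(1, x, g, x * g)
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    res <- y - X %*% beta
    sigma2 <- sum(res^2) / (60 - 4)
    se <- sqrt(diag(chol2inv(qr.R(qrX))) * sigma2)
    p <- 2 * pt(abs(beta / se), df = 60 - 4, lower.tail = FALSE)
    p[4L] < 0.05
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 0.03)
  ## and the packaged test agrees with the oracle decision on fixtures
  for (s in 1:5) {
    set.seed(s)
    d <- data.frame(germline_size = runif(60),
                    genotype = rep(c("a", "b"), each = 30))
    d$y <- d$germline_size + rnorm(60)
    fit <- compare_genotypes(d, "y")
    X <- cbind(1, d$germline_size, d$genotype == "b",
               d$germline_size * (d$genotype == "b"))
    ml <- lm(d$y ~ X - 1)
    p_or <- summary(ml)$coefficients[4L, 4L]
    expect_equal(fit$used_interaction, p_or < 0.05)
  }
})

test_that("critical-size ANOVA matches direct sums of squares and detects the pattern", {
  set.seed(5)
  n <- 60
  d <- data.frame(germline_area = runif(2 * n, 1000, 30000),
                  genotype = rep(c("ctl", "mut"), each = n))
  crit <- 11650
  ## mutant effect only above the critical size
  d$y <- rnorm(2 * n, 0, 0.5) +
    ifelse(d$genotype == "mut" & d$germline_area >= crit, 2, 0)
  res <- critical_size_anova(d, "y", crit)
  ## oracle: sequential sums of squares from explicit model fits
  grp <- factor(d$germline_area < crit, labels = c("above", "below"))
  gt <- factor(d$genotype)
  rss <- function(f) sum(lm(f, data = data.frame(y = d$y, grp, gt))$residuals^2)
  ss_int <- rss(y ~ grp + gt) - rss(y ~ grp * gt)
  expect_equal(res$anova["group:genotype", "Sum Sq"], ss_int,
               tolerance = 1e-8)
  ## interaction significant; below-group contrast non-significant
  expect_lt(res$anova["group:genotype", "Pr(>F)"], 0.01)
  ctr <- res$contrasts
  expect_gt(ctr$p.value[ctr$group == "below"], 0.05)
  expect_lt(ctr$p.value[ctr$group == "above"], 0.01)
  ## degenerate grouping errors out
  expect_error(critical_size_anova(d, "y", 100), "empty group")
})

test_that("identical populations yield non-significant Sidak contrasts", {
  rej <- vapply(1:30, function(s) {
    set.seed(s)
    d <- data.frame(germline_area = runif(80, 1000, 30000),
                    genotype = rep(c("a", "b"), each = 40),
                    y = rnorm(80))
    any(critical_size_anova(d, "y", 11650)$contrasts$p.value < 0.05)
  }, logical(1))
  expect_lt(mean(rej), 0.25)
})

test_that("angle-versus-Eya regression solves the 90-degree crossing", {
  ## exact two-point line
  fit <- angle_vs_eya(data.frame(eya = c(62, 82), angle = c(85, 95)))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$eya_at_90, 72, tolerance = 1e-9)
  ## synthetic cohort built on the 72-unit zero point
  set.seed(2)
  e <- runif(80, 20, 130)
  d <- data.frame(eya = e, angle = 90 + 0.5 * (e - 72) + rnorm(80, 0, 1))
  f2 <- angle_vs_eya(d)
  expect_equal(f2$eya_at_90, 72, tolerance = 2)
  band <- f2$ci_band(c(60, 72, 90))
  expect_true(all(band$lower < band$fit & band$fit < band$upper))
  ## flat data: flagged degenerate
  f3 <- angle_vs_eya(data.frame(eya = c(10, 20, 30), angle = c(90, 90, 90)))
  expect_true(f3$degenerate_slope)
  expect_true(is.na(f3$eya_at_90))
})

test_that("eya_at_90 is equivariant under shifting all Eya levels", {
  set.seed(4)
  e <- runif(40, 30, 120)
  d <- data.frame(eya = e, angle = 88 + 0.4 * e + rnorm(40, 0, 0.5))
  f1 <- angle_vs_eya(d)
  d2 <- d; d2$eya <- d2$eya + 17
  f2 <- angle_vs_eya(d2)
  expect_equal(f2$eya_at_90, f1$eya_at_90 + 17, tolerance = 1e-8)
})

test_that("measured wild-type records reproduce the angle-Eya relationship", {
  rec <- measure_cohort(small_cohort(60, seed = 6, noise_cv = 0.02))
  fit <- angle_vs_eya(rec)
  expect_gt(fit$slope, 0)
  expect_equal(fit$eya_at_90, 72, tolerance = 8)
})
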