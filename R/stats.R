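## Statistical procedures of the analysis pipeline: LOESS curves against
## germline area, genotype comparison by interaction regression with an
## additive fallback, critical-size grouping ANOVA with Sidak-corrected
## contrasts, and the interface-angle-versus-Eya regression.

#' LOESS curve with confidence band
#'
#' Locally weighted regression of y on x with a pointwise confidence
#' band, evaluated on a uniform grid - the standard presentation of
#' morphometric parameters as a function of germline area.
#'
#' @param x,y numeric vectors (>= 10 points).
#' @param span LOESS span (the published figures do not state one;
#'   0.75 is the conventional default).
#' @param level confidence level of the pointwise band.
#' @param n_grid grid size.
#' @param degree local polynomial degree.
#' @return data.frame with columns \code{x}, \code{fit}, \code{lower},
#'   \code{upper}.
#' @export
loess_curve <- function(x, y, span = 0.75, level = 0.95, n_grid = 100L,
                        degree = 2L) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10L) stopf("need at least 10 finite points, got %d", sum(ok))
  fit <- loess(y ~ x, data = data.frame(x = x[ok], y = y[ok]), span = span,
               degree = degree,
               control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x[ok]), max(x[ok]), length.out = n_grid)
  pr <- predict(fit, newdata = data.frame(x = grid), se = TRUE)
  q <- qt(1 - (1 - level) / 2, pr$df)
  data.frame(x = grid, fit = pr$fit,
             lower = pr$fit - q * pr$se.fit,
             upper = pr$fit + q * pr$se.fit)
}

#' Compare genotypes by interaction regression
#'
#' Fits \code{Y ~ germline_size + genotype + germline_size:genotype}.
#' When the interaction p-value is >= 0.05 the model is refit without
#' the interaction and the genotype main effect is reported (the
#' additive fallback).  Genotype is coded as a 0/1 indicator of the
#' second (non-reference) level.
#'
#' @param data data.frame with columns \code{germline_area} (or
#'   \code{germline_size}), \code{genotype} (exactly two levels), and
#'   the response.
#' @param response name of the response column.
#' @param alpha interaction retention threshold.
#' @return object of class \code{genotype_comparison}: list with
#'   \code{coefficients}, \code{p_values}, \code{used_interaction},
#'   \code{n}, \code{response}, \code{fit}.
#' @export
compare_genotypes <- function(data, response, alpha = 0.05) {
  size <- data$germline_size %||% data$germline_area
  if (is.null(size)) stopf("data must contain germline_size or germline_area")
  gl <- unique(as.character(data$genotype))
  if (length(gl) != 2L)
    stopf("need exactly two genotype levels, got %d", length(gl))
  df <- data.frame(y = data[[response]], size = size,
                   geno = as.integer(as.character(data$genotype) == gl[2L]))
  full <- lm(y ~ size + geno + size:geno, data = df)
  p_int <- summary(full)$coefficients["size:geno", 4L]
  used_interaction <- is.finite(p_int) && p_int < alpha
  fit <- if (used_interaction) full else lm(y ~ size + geno, data = df)
  sm <- summary(fit)$coefficients
  rn <- c("(Intercept)" = "intercept", size = "germline_size",
          geno = "genotype", "size:geno" = "germline_size:genotype")
  structure(list(coefficients = setNames(sm[, 1L], rn[rownames(sm)]),
                 p_values = setNames(sm[, 4L], rn[rownames(sm)]),
                 interaction_p = p_int,
                 used_interaction = used_interaction,
                 n = nrow(df), response = response,
                 levels = gl, fit = fit),
            class = "genotype_comparison")
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cat(sprintf("Genotype comparison for '%s' (n = %d; %s vs %s)\n",
              x$response, x$n, x$levels[1L], x$levels[2L]))
  cat(sprintf("  interaction p = %.4g -> %s model\n", x$interaction_p,
              if (x$used_interaction) "interaction" else "additive"))
  co <- cbind(estimate = x$coefficients, p = x$p_values)
  print(signif(co, 4))
  invisible(x)
}

#' Critical-size grouping ANOVA
#'
#' Groups chambers into those below and above the critical germline
#' size, fits a two-way ANOVA (group x genotype), and reports
#' Sidak-corrected genotype contrasts within each group.
#'
#' @param data data.frame with \code{germline_area}, \code{genotype}
#'   (two levels) and the response.
#' @param response response column name.
#' @param critical_size grouping threshold (um^2).
#' @return object of class \code{critical_size_anova}: list with
#'   \code{anova} (two-way table), \code{contrasts} (per-group genotype
#'   contrasts, Sidak-adjusted), \code{critical_size}.
#' @export
critical_size_anova <- function(data, response, critical_size) {
  df <- data.frame(y = data[[response]],
                   group = factor(ifelse(data$germline_area < critical_size,
                                         "below", "above"),
                                  levels = c("below", "above")),
                   genotype = factor(data$genotype))
  if (nlevels(df$genotype) != 2L) stopf("need exactly two genotype levels")
  cells <- table(df$group, df$genotype)
  if (any(cells == 0L))
    stopf("empty group x genotype cell (critical size %.0f)", critical_size)
  fit <- aov(y ~ group * genotype, data = df)
  em <- emmeans::emmeans(fit, ~ genotype | group)
  ctr <- summary(emmeans::contrast(em, "pairwise", adjust = "sidak"))
  structure(list(anova = summary(fit)[[1L]], contrasts = as.data.frame(ctr),
                 critical_size = critical_size, fit = fit),
            class = "critical_size_anova")
}

#' @export
print.critical_size_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA with critical-size grouping at %.0f um^2\n",
              x$critical_size))
  print(x$anova)
  cat("Sidak-adjusted genotype contrasts by group:\n")
  print(x$contrasts)
  invisible(x)
}

#' Interface angle versus Eya regression
#'
#' Ordinary linear regression of the interface angle on the Eya level of
#' boundary follicle cells; the Eya level predicting a 90-degree
#' (force-balanced) angle is solved from the fit.
#'
#' @param data data.frame with columns \code{eya} and \code{angle} (or
#'   \code{eya_mean_at_ncob} / \code{interface_angle}).
#' @param level confidence level for the band.
#' @return object of class \code{angle_eya_fit}: list with \code{slope}
#'   (degrees per arb. unit), \code{intercept} (degrees),
#'   \code{eya_at_90} (arb. unit; NA and flagged when the slope is 0),
#'   \code{ci_band} (function of Eya returning fit/lower/upper),
#'   \code{fit}, \code{n}.
#' @export
angle_vs_eya <- function(data, level = 0.95) {
  eya <- data$eya %||% data$eya_mean_at_ncob
  angle <- data$angle %||% data$interface_angle
  if (is.null(eya) || is.null(angle)) stopf("need eya and angle columns")
  ok <- is.finite(eya) & is.finite(angle)
  if (sum(ok) < 2L) stopf("need at least 2 (Eya, angle) pairs")
  df <- data.frame(eya = eya[ok], angle = angle[ok])
  fit <- lm(angle ~ eya, data = df)
  slope <- unname(coef(fit)[2L]); intercept <- unname(coef(fit)[1L])
  degenerate <- !is.finite(slope) || abs(slope) < 1e-9
  band <- function(e) {
    pr <- predict(fit, newdata = data.frame(eya = e), se.fit = TRUE,
                  interval = "confidence", level = level)
    data.frame(eya = e, fit = pr$fit[, "fit"], lower = pr$fit[, "lwr"],
               upper = pr$fit[, "upr"])
  }
  structure(list(slope = slope, intercept = intercept,
                 eya_at_90 = if (degenerate) NA_real_ else
                   (90 - intercept) / slope,
                 degenerate_slope = degenerate,
                 ci_band = band, fit = fit, n = nrow(df)),
            class = "angle_eya_fit")
}

#' @export
print.angle_eya_fit <- function(x, ...) {
  cat(sprintf("Interface angle ~ Eya (n = %d)\n", x$n))
  cat(sprintf("  angle = %.3f + %.4f * Eya\n", x$intercept, x$slope))
  if (x$degenerate_slope)
    cat("  slope is zero: Eya at 90 degrees undefined\n")
  else
    cat(sprintf("  Eya predicting a 90-degree angle: %.2f arb. unit\n",
                x$eya_at_90))
  invisible(x)
}
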