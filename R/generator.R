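## Synthetic egg-chamber generator.
##
## Replaces the confocal dataset: seeded cohorts of 2-D medial-section
## egg-chamber geometries with the statistical structure the downstream
## analysis assumes (germline-area-indexed progression, anterior ->
## posterior Eya dynamics, AFC flattening, a measurable oocyte-nurse-cell
## interface angle, genotype perturbations with critical onset sizes).

#' Generator configuration
#'
#' @param seed integer root seed; per-chamber streams are derived from it.
#' @param n_chambers cohort size.
#' @param area_range germline-area range (um^2) sampled by the cohort.
#' @param genotype one of \code{wt}, \code{mirr_eya} (ectopic Eya in
#'   main-body cells above the critical size), \code{gr1_eyaRNAi}
#'   (epithelium-wide Eya collapse above the critical size),
#'   \code{tj_egfr} (no anterior fate; Eya-negative epithelium from
#'   phase 2 onward), or \code{custom}.
#' @param fc_count_at_arrest total follicle-cell count in 3-D at mitotic
#'   arrest (end of phase 1).
#' @param afc_fraction fraction of follicle cells adopting anterior fate.
#' @param phase1_aspect_ratio anterior-posterior aspect ratio of phase-1
#'   medial sections (rises linearly to 2.0 by late phase 3).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal measurement noise on Eya and the additive contour noise.
#' @param critical_size_mirr,critical_size_gr1 germline areas (um^2) at
#'   which the respective drivers first act.
#' @param fc_count_section number of follicle cells tracked in the medial
#'   section (perimeter samples; proportions are the quantities of record).
#' @param n_nc_section nurse cells resolvable in the medial section.
#' @param oocyte_fraction_plateau oocyte area fraction of the germline at
#'   the end of phase 2 (~40 percent).
#' @param angle_slope interface-angle response to boundary Eya
#'   (degrees per arb. unit about the 72 arb. unit zero point).
#' @return object of class \code{generator_config} (a validated list).
#' @export
generator_config <- function(seed = 0L, n_chambers = 126L,
                             area_range = c(1500, 60000),
                             genotype = c("wt", "mirr_eya", "gr1_eyaRNAi",
                                          "tj_egfr", "custom"),
                             fc_count_at_arrest = 850L, afc_fraction = 0.10,
                             phase1_aspect_ratio = 1.5, noise_cv = 0.05,
                             critical_size_mirr = 11650,
                             critical_size_gr1 = 1600,
                             fc_count_section = 74L, n_nc_section = 5L,
                             oocyte_fraction_plateau = 0.40,
                             angle_slope = 0.35) {
  genotype <- match.arg(genotype)
  if (afc_fraction <= 0 || afc_fraction >= 1)
    stopf("afc_fraction must lie in (0, 1)")
  if (length(area_range) != 2L || any(area_range <= 0) ||
      diff(area_range) <= 0)
    stopf("area_range must be positive and increasing")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  structure(list(seed = as.integer(seed), n_chambers = as.integer(n_chambers),
                 area_range = area_range, genotype = genotype,
                 fc_count_at_arrest = as.integer(fc_count_at_arrest),
                 afc_fraction = afc_fraction,
                 phase1_aspect_ratio = phase1_aspect_ratio,
                 noise_cv = noise_cv,
                 critical_size_mirr = critical_size_mirr,
                 critical_size_gr1 = critical_size_gr1,
                 fc_count_section = as.integer(fc_count_section),
                 n_nc_section = as.integer(n_nc_section),
                 oocyte_fraction_plateau = oocyte_fraction_plateau,
                 angle_slope = angle_slope),
            class = "generator_config")
}

## run code under a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## derived per-chamber stream seed (kept below 2^31)
chamber_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 9973) %% 2147483629)
}

## smoothstep progression variable through phase 2: 0 for areas below t12,
## 1 above t23
progression <- function(area, t12 = 6500, t23 = 31500) {
  s <- pmin(1, pmax(0, (log(area) - log(t12)) / (log(t23) - log(t12))))
  s * s * (3 - 2 * s)
}

#' Generate a germline cyst
#'
#' A cyst of 16 interconnected germ cells: 1 oocyte and 15 nurse cells.
#' At the start of progression the oocyte holds 1/16 of the cyst volume;
#' nurse-cell volumes are drawn around equality with the requested
#' coefficient of variation and renormalized.
#'
#' @param seed integer seed.
#' @param cv_volume coefficient of variation of nurse-cell volume
#'   fractions (0 gives the exact equal partition).
#' @return object of class \code{germline_cyst}: data.frame with columns
#'   \code{role} ("oocyte"/"nurse") and \code{volume_fraction}.
#' @export
#' @examples
#' generate_cyst(1, 0)      # sixteen cells of fraction 1/16 each
generate_cyst <- function(seed = 0L, cv_volume = 0) {
  if (cv_volume < 0) stopf("cv_volume must be >= 0")
  nurse <- if (cv_volume == 0) rep(1, 15) else with_seed(seed, {
    sdlog <- sqrt(log(1 + cv_volume^2))
    rlnorm(15, -sdlog^2 / 2, sdlog)
  })
  nurse <- nurse / sum(nurse) * (15 / 16)
  structure(data.frame(role = c("oocyte", rep("nurse", 15)),
                       volume_fraction = c(1 / 16, nurse),
                       stringsAsFactors = FALSE),
            class = c("germline_cyst", "data.frame"))
}

## wild-type oocyte area fraction of the germline as a function of area
oocyte_fraction_curve <- function(area, genotype, config) {
  f0 <- 1 / 16; fp <- config$oocyte_fraction_plateau
  switch(genotype,
    wt = f0 + (fp - f0) * progression(area),
    mirr_eya = {                      # frozen once the driver reaches the oocyte
      cap <- pmin(area, config$critical_size_mirr)
      f0 + (fp - f0) * progression(cap)
    },
    gr1_eyaRNAi = {                   # premature expansion above the onset size
      s <- pmin(1, pmax(0, (log(pmax(area, 1)) - log(config$critical_size_gr1)) /
                           (log(31500) - log(config$critical_size_gr1))))
      f0 + (fp - f0) * (s * s * (3 - 2 * s))
    },
    tj_egfr = {                       # no halt at the end of phase 2
      s <- pmin(1, pmax(0, (log(pmax(area, 1)) - log(6500)) /
                           (log(60000) - log(6500))))
      f0 + (0.55 - f0) * (s * s * (3 - 2 * s))
    },
    custom = f0 + (fp - f0) * progression(area))
}

## total 3-D follicle-cell count: proliferating through phase 1, constant after
fc_total_count <- function(area, config) {
  round(config$fc_count_at_arrest * pmin(1, (area / 6500)^0.8))
}

## noise-free Eya level of the cell at anterior ordinal `ord` (1 = most
## anterior within its side), at time t, for the given genotype
eya_of_ordinal <- function(ord, t, genotype, area, config, schedules) {
  r <- pmin(ord, 7L)
  E <- vapply(seq_along(ord), function(i)
    eval_schedule(schedules[[as.character(r[i])]], t), numeric(1))
  if (genotype == "gr1_eyaRNAi" && area > config$critical_size_gr1) {
    E <- E * 0.12
  } else if (genotype == "mirr_eya" && area > config$critical_size_mirr) {
    high <- eval_schedule(schedules[["2"]], t)
    E[ord >= 7L] <- high
  } else if (genotype == "tj_egfr") {
    t12 <- 15
    w <- pmin(1, pmax(0, (t - t12) / 2))
    E <- E * (1 - w) + 10 * w
  }
  E
}

#' Generate one synthetic egg chamber
#'
#' Builds a medial-section geometry at the requested germline area:
#' an ellipse with a phase-dependent aspect ratio, the oocyte as the
#' posterior segment whose area fraction follows the genotype's
#' progression curve, follicle cells distributed along the perimeter with
#' a phase-dependent anterior flattening profile, per-cell Eya levels
#' from the row schedules, and an oocyte-nurse-cell interface drawn as a
#' circular arc realizing the Eya-predicted contact angle.
#'
#' @param area germline medial-section area (um^2).
#' @param genotype genotype label (see [generator_config()]).
#' @param seed integer seed for this chamber's noise stream.
#' @param config a [generator_config()].
#' @param schedules row Eya schedules (default [fit_all_schedules()]).
#' @return object of class \code{egg_chamber_geometry}.
#' @export
#' @examples
#' g <- generate_chamber(3000, "wt", seed = 3,
#'                       config = generator_config(noise_cv = 0))
#' g$oocyte_fraction
generate_chamber <- function(area, genotype = "wt", seed = 0L,
                             config = generator_config(),
                             schedules = fit_all_schedules()) {
  if (!genotype %in% c("wt", "mirr_eya", "gr1_eyaRNAi", "tj_egfr", "custom"))
    stopf("unknown genotype '%s'", genotype)
  if (area < config$area_range[1] || area > config$area_range[2])
    stopf("area %.0f outside config area_range [%g, %g]", area,
          config$area_range[1], config$area_range[2])
  amap <- area_time_map()
  t <- min(36, max(0, amap$time(area)))
  S <- progression(area)

  ## --- outline ---------------------------------------------------------
  aspect <- config$phase1_aspect_ratio + (2.0 - config$phase1_aspect_ratio) * S
  b <- sqrt(area / (pi * aspect)); a <- aspect * b
  contour <- ellipse_contour(a, b, 720L)
  P <- ellipse_perimeter(a, b)

  ## --- oocyte region ---------------------------------------------------
  f_ooc <- oocyte_fraction_curve(area, genotype, config)

  ## --- follicle cells --------------------------------------------------
  n <- config$fc_count_section
  n_half <- n %/% 2L
  ## interface chord (pre-bulge) to place cells
  x0 <- ellipse_segment_chord(a, b, f_ooc)
  arc_oo <- ellipse_arc_fraction(a, b, x0)
  L_half <- P / 2
  L_oo_half <- arc_oo * L_half              # oocyte-adjacent arc per side
  L_nc_half <- L_half - L_oo_half
  ## cells on the nurse-adjacent arc per side: from the uniform count in
  ## phase 1 down to the 6 anterior rows by phase 3 (AFC flattening)
  m_uniform <- n_half * (1 - arc_oo)
  Sm <- if (genotype == "tj_egfr") 0 else
    if (genotype == "mirr_eya") progression(pmin(area, config$critical_size_mirr)) else S
  m <- max(6L, min(n_half - 1L, round((1 - Sm) * m_uniform + Sm * 6)))
  ## within-side extents: anterior->posterior gradient mid-phase 2
  grad <- 4 * Sm * (1 - Sm)
  w_nc <- 1 + 0.8 * grad * rev(seq_len(m) - 1) / max(1, m - 1)
  w_nc <- w_nc / sum(w_nc) * L_nc_half
  w_oo <- rep(L_oo_half / (n_half - m), n_half - m)
  widths <- c(w_nc, w_oo)
  pos_half <- cumsum(widths) - widths / 2   # arc distance from anterior pole
  ## mirror to the full perimeter: s in [0, P), anterior pole at s = 0
  s_all <- c(pos_half, P - rev(pos_half))
  extent <- c(widths, rev(widths))
  ord <- c(seq_len(n_half), rev(seq_len(n_half)))  # anterior ordinal per side
  on_oocyte <- c(seq_len(n_half) > m, rev(seq_len(n_half) > m))

  ## --- fates -----------------------------------------------------------
  fate <- rep("MBFC", n)
  if (genotype != "tj_egfr") fate[ord <= 6L] <- "AFC"
  fate[ord > n_half - 3L] <- "PFC"
  afc_count_3d <- if (genotype == "tj_egfr") 0L else
    as.integer(round(config$afc_fraction * config$fc_count_at_arrest))

  ## --- Eya -------------------------------------------------------------
  eya0 <- eya_of_ordinal(ord, t, genotype, area, config, schedules)
  eya <- if (config$noise_cv > 0) with_seed(seed, {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    eya0 * rlnorm(n, -sdlog^2 / 2, sdlog)
  }) else eya0
  ## boundary (nurse-side) cells: one per side, the last nurse-arc cell
  e_ncob_true <- mean(eya0[ord == m])

  ## --- interface with encoded contact angle ----------------------------
  angle_target <- 90 + config$angle_slope * (e_ncob_true - 72)
  angle_target <- min(160, max(20, angle_target))
  iface <- build_interface(a, b, f_ooc, angle_target)
  angle_true <- iface$angle_realized

  ## --- nurse-cell section fractions ------------------------------------
  k <- config$n_nc_section
  disorg <- genotype == "gr1_eyaRNAi" && area > config$critical_size_gr1
  base_area <- if (disorg) c(0.34, 0.12, 0.27, 0.08, 0.19)[seq_len(k)]
               else rep(1, k)
  base_if <- if (disorg) c(0.30, 0.10, 0.28, 0.06, 0.26)[seq_len(k)]
             else rep(1, k)
  if (config$noise_cv > 0) {
    mult <- with_seed(seed + 1L, {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      matrix(rlnorm(2L * k, -sdlog^2 / 2, sdlog), nrow = 2L)
    })
    base_area <- base_area * mult[1L, ]
    base_if <- base_if * mult[2L, ]
  }
  nc_area_fraction <- base_area / sum(base_area)
  nc_interface_fraction <- base_if / sum(base_if)

  ## --- contour measurement noise ---------------------------------------
  if (config$noise_cv > 0) {
    jitter <- with_seed(seed + 2L, {
      sigma <- config$noise_cv * sqrt(area) * 0.02
      matrix(rnorm(2L * nrow(contour), 0, sigma), ncol = 2L)
    })
    contour_obs <- contour + jitter
  } else contour_obs <- contour

  structure(list(
    genotype = genotype, seed = as.integer(seed), time_h = t,
    germline_area = area, a = a, b = b, aspect = aspect, perimeter = P,
    outer_contour = contour_obs, outer_contour_true = contour,
    oocyte_fraction = f_ooc,
    oocyte_region = iface$oocyte_polygon,
    nc_oocyte_interface = iface$interface,
    interface_angle_true = angle_true,
    interface_endpoints = iface$endpoints,
    chord_x = iface$x0,
    fc_positions = sort(s_all), fc_order = order(s_all),
    fc_s = s_all, fc_extent = extent, fc_ordinal = ord,
    fc_fate = fate, fc_eya = eya, fc_eya_true = eya0,
    fc_on_oocyte = on_oocyte,
    eya_ncob_true = e_ncob_true,
    fc_count_section = n, fc_count_total = fc_total_count(area, config),
    afc_count_3d = afc_count_3d,
    nc_area_fraction = nc_area_fraction,
    nc_interface_fraction = nc_interface_fraction,
    egg_chamber_area = pi * (a + 8) * (b + 8),
    config = config), class = "egg_chamber_geometry")
}

## Construct the oocyte-nurse-cell interface as a straight chord with
## endpoint-localized "hooks" whose tangents realize the target contact
## angle `angle_deg` (measured through the oocyte), and whose enclosed
## posterior region has area f_ooc * pi * a * b.  Deflecting the
## interface towards the anterior at its endpoints widens the oocyte
## corner; the deflection is confined near the triple points so that the
## displaced area stays small, and the chord position is iterated so the
## enclosed area is exact.
build_interface <- function(a, b, f_ooc, angle_deg, n_arc = 181L,
                            lambda1 = 0.08, lambda2 = 0.10) {
  target <- f_ooc * pi * a * b
  x0 <- ellipse_segment_chord(a, b, f_ooc)
  tt <- seq(0, 1, length.out = n_arc)
  ## hook profile: linear ramp then smooth decay back to the chord
  hook <- function(t) ifelse(t < lambda1, t,
                      ifelse(t < lambda1 + lambda2,
                             lambda1 * cos((t - lambda1) / lambda2 * pi / 2),
                             0))
  arc <- NULL
  for (iter in 1:10) {
    y0 <- b * sqrt(max(0, 1 - (x0 / a)^2))
    th1 <- acos(pmin(1, pmax(-1, x0 / a)))
    ## outline tangent at the upper endpoint, pointing towards the
    ## posterior pole (the oocyte side): theta decreasing
    tc <- c(a * sin(th1), -b * cos(th1)); tc <- tc / sqrt(sum(tc^2))
    ## chord direction at the upper endpoint, pointing into the interface
    th_chord <- acos(pmin(1, pmax(-1, sum(tc * c(0, -1))))) * 180 / pi
    ## signed endpoint deflection: positive (posterior) narrows the
    ## oocyte corner, negative (anterior) widens it
    delta <- max(-70, min(70, th_chord - angle_deg)) * pi / 180
    L <- 2 * y0
    defl <- tan(delta) * L * (hook(tt) + hook(1 - tt))
    arc <- cbind(x = x0 + defl, y = y0 - L * tt)
    ## enclosed area of the candidate oocyte polygon
    poly <- oocyte_polygon(a, b, x0, arc)
    resid <- polygon_area(poly) - target
    if (abs(resid) < 1e-9 * pi * a * b) break
    ## move the chord to absorb the residual (dA/dx0 ~ -2 y0)
    x0 <- x0 + resid / max(2 * y0, 1e-6)
    x0 <- min(a * (1 - 1e-6), max(-a * (1 - 1e-6), x0))
  }
  y0 <- b * sqrt(max(0, 1 - (x0 / a)^2))
  list(interface = arc, oocyte_polygon = oocyte_polygon(a, b, x0, arc),
       endpoints = rbind(c(x0, y0), c(x0, -y0)),
       x0 = x0, angle_realized = th_chord - delta * 180 / pi)
}

## closed polygon of the posterior (oocyte) region bounded by the
## outline arc through x = +a and the interface polyline
oocyte_polygon <- function(a, b, x0, arc) {
  th1 <- acos(pmin(1, pmax(-1, x0 / a)))
  th_seq <- seq(th1, -th1, length.out = 241L)
  outline_arc <- cbind(x = a * cos(th_seq), y = b * sin(th_seq))
  rbind(outline_arc, arc[rev(seq_len(nrow(arc)))[-1L], , drop = FALSE])
}

#' Generate a cohort of egg chambers
#'
#' Areas are sampled log-uniformly over the configured range (covering
#' all three phases); each chamber draws its noise from a derived stream
#' of the root seed, so cohorts are reproducible.
#'
#' @param config a [generator_config()].
#' @param schedules row Eya schedules.
#' @return object of class \code{egg_chamber_cohort}: list of
#'   \code{egg_chamber_geometry} objects with the config attached.
#' @export
generate_cohort <- function(config = generator_config(),
                            schedules = fit_all_schedules()) {
  if (config$n_chambers < 1L) stopf("n_chambers must be >= 1")
  areas <- with_seed(config$seed,
    exp(runif(config$n_chambers, log(config$area_range[1]),
              log(config$area_range[2]))))
  chambers <- lapply(seq_along(areas), function(i)
    generate_chamber(areas[i], config$genotype,
                     seed = chamber_seed(config$seed, i),
                     config = config, schedules = schedules))
  structure(chambers, class = "egg_chamber_cohort", config = config)
}

#' @export
print.egg_chamber_geometry <- function(x, ...) {
  cat(sprintf("Egg chamber (%s): germline area %.0f um^2, phase %d\n",
              x$genotype, x$germline_area, assign_phase(x$germline_area)))
  cat(sprintf("  aspect %.2f, oocyte fraction %.3f, %d section FCs, angle %.1f deg\n",
              x$aspect, x$oocyte_fraction, x$fc_count_section,
              x$interface_angle_true))
  invisible(x)
}

#' @export
print.egg_chamber_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  ar <- range(vapply(x, `[[`, numeric(1), "germline_area"))
  cat(sprintf("Cohort of %d %s egg chambers, areas %.0f-%.0f um^2\n",
              length(x), cfg$genotype, ar[1], ar[2]))
  invisible(x)
}

#' Write a cohort to disk (per-chamber CSV, per-FC CSV, config JSON)
#'
#' @param cohort an \code{egg_chamber_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- measure_cohort(cohort)
  fcs <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    g <- cohort[[i]]
    data.frame(chamber = i, arc_position = g$fc_s, fate = g$fc_fate,
               eya = g$fc_eya, extent = g$fc_extent,
               on_oocyte = g$fc_on_oocyte)
  }))
  paths <- file.path(dir, c("chambers.csv", "follicle_cells.csv",
                            "config.json"))
  write.csv(rec, paths[1], row.names = FALSE)
  write.csv(fcs, paths[2], row.names = FALSE)
  cfg <- attr(cohort, "config")
  jsonlite::write_json(unclass(cfg), paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
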