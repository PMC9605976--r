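## Eya row dynamics and their mapping to affinity inputs for the
## phase-field models.
##
## Follicle-cell Eya levels are summarized per anterior cell row (rows 1-6
## are anterior follicle cells, row 7 the first main-body row; the row-7
## dynamic stands in for all posterior rows).  Per-stage mean intensities
## are interpolated over a 36 h developmental window by a 6th-order
## polynomial constrained to have vanishing derivatives at t = 0 and
## t = 36 h, and the resulting schedules act as direct proxies for
## cell-boundary affinities.

#' Developmental stage-duration table
#'
#' Durations (hours) of egg-chamber stages 5 to 10b, summing to 36 h.  The
#' published per-stage durations live in the primary literature on
#' oogenesis timing; the values shipped here are an editable default that
#' preserves the canonical ordering and the 36 h total.  Phase boundaries
#' fall at mid stage 7 and mid stage 10a.
#'
#' @param durations named numeric vector of stage durations in hours;
#'   must be positive and sum to 36.
#' @return data.frame with columns \code{stage}, \code{duration},
#'   \code{t_start}, \code{t_mid}, \code{t_end}, plus attributes
#'   \code{t12}/\code{t23} giving the phase-boundary times (mid stage 7,
#'   mid stage 10a).
#' @export
#' @examples
#' stage_table()
stage_table <- function(durations = c("5" = 6, "6" = 6, "7" = 6, "8" = 6,
                                      "9e" = 3, "9m" = 3,
                                      "10a" = 3, "10b" = 3)) {
  if (any(durations <= 0)) stopf("stage durations must be positive")
  if (abs(sum(durations) - 36) > 1e-8)
    stopf("stage durations must sum to 36 h (got %.3f)", sum(durations))
  t_end <- cumsum(durations)
  t_start <- c(0, t_end[-length(t_end)])
  tab <- data.frame(stage = names(durations), duration = unname(durations),
                    t_start = unname(t_start),
                    t_mid = unname((t_start + t_end) / 2),
                    t_end = unname(t_end),
                    stringsAsFactors = FALSE)
  attr(tab, "t12") <- tab$t_mid[tab$stage == "7"]
  attr(tab, "t23") <- tab$t_mid[tab$stage == "10a"]
  tab
}

#' Map between germline area and developmental time
#'
#' Germline area is the continuous progression variable of the analysis;
#' the simulations run on the 36 h stage clock.  The two are linked by an
#' exponential growth curve anchored so that the phase boundaries
#' (6500 and 31500 um^2) fall at mid stage 7 and mid stage 10a.
#'
#' @param stages stage table from [stage_table()].
#' @param thresholds phase thresholds, see [phase_thresholds()].
#' @return list with functions \code{area(t)} and \code{time(area)} and
#'   the anchor constants.
#' @export
area_time_map <- function(stages = stage_table(),
                          thresholds = phase_thresholds()) {
  t12 <- attr(stages, "t12"); t23 <- attr(stages, "t23")
  k <- log(thresholds$t23 / thresholds$t12) / (t23 - t12)
  a0 <- thresholds$t12 * exp(-k * t12)
  list(area = function(t) a0 * exp(k * t),
       time = function(area) log(area / a0) / k,
       a0 = a0, k = k, t12 = t12, t23 = t23)
}

## ---- synthetic stage means -------------------------------------------

#' Default synthetic per-stage Eya means for rows 1-7
#'
#' Synthetic stage-mean Eya intensities (arbitrary units) for the seven
#' anterior follicle-cell rows.  The family encodes the qualitative
#' dynamics of the measured intensities: uniform high levels through
#' phase 1, then a divergence in which anterior rows retain or gain Eya
#' in a graded fashion while row 7 decays towards Eya-negative levels,
#' crossing the zero-affinity constant (72 arb. unit) shortly after the
#' phase-1/2 boundary.  Measured per-stage values are figure-only in the
#' source data and are not reproduced here.
#'
#' @param stages stage table from [stage_table()].
#' @param high uniform phase-1 level (arb. unit).
#' @param end_levels length-7 vector of late (t = 36 h) levels per row.
#' @param t_switch,tau centre (h) and width (h) of the logistic
#'   transition from uniform to graded expression.
#' @return data.frame with columns \code{row}, \code{stage},
#'   \code{t_mid}, \code{mean_eya}.
#' @export
default_stage_means <- function(stages = stage_table(), high = 112,
                                end_levels = c(128, 118, 108, 98, 88, 78, 15),
                                t_switch = 18, tau = 3) {
  stopifnot(length(end_levels) == 7L)
  grid <- expand.grid(row = 1:7, stage = seq_len(nrow(stages)))
  tm <- stages$t_mid[grid$stage]
  s <- plogis((tm - t_switch) / tau)
  mean_eya <- high + (end_levels[grid$row] - high) * s
  data.frame(row = grid$row, stage = stages$stage[grid$stage],
             t_mid = tm, mean_eya = mean_eya, stringsAsFactors = FALSE)
}

## ---- constrained polynomial fit --------------------------------------

#' Fit a constrained Eya schedule
#'
#' Least-squares 6th-order polynomial through (stage midpoint, mean
#' intensity) pairs, constrained to have vanishing first derivatives at
#' t = 0 and t = 36 h.  The fit is performed on the scaled variable
#' u = t/36 for conditioning; coefficients are reported in both bases.
#'
#' @param stage_means data.frame with columns \code{t_mid} (or
#'   \code{stage}) and \code{mean_eya}; at least 7 stages.
#' @param stages stage table used to resolve stage midpoints when
#'   \code{t_mid} is absent.
#' @param row integer row label carried on the result.
#' @return object of class \code{eya_schedule}: list with \code{row},
#'   \code{coefficients} (c0..c6, powers of t in hours), \code{coef_u}
#'   (powers of u = t/36), \code{domain}, \code{fitted}, \code{residuals}.
#' @export
fit_schedule <- function(stage_means, stages = stage_table(), row = NA_integer_) {
  if (is.null(stage_means$t_mid)) {
    idx <- match(stage_means$stage, stages$stage)
    if (anyNA(idx)) stopf("unknown stage labels in stage_means")
    stage_means$t_mid <- stages$t_mid[idx]
  }
  tt <- stage_means$t_mid; y <- stage_means$mean_eya
  if (length(tt) < 7L) stopf("need at least 7 stage means, got %d", length(tt))
  u <- tt / 36
  V <- outer(u, 0:6, `^`)                     # Vandermonde, 7 columns
  ## constraints in u-basis: p'(0) = 0 -> c1 = 0 ;
  ## p'(1) = 0 -> sum_{k>=1} k c_k = 0
  C <- rbind(c(0, 1, 0, 0, 0, 0, 0),
             c(0, 1, 2, 3, 4, 5, 6))
  N <- null_space(C)                          # 7 x 5
  A <- V %*% N
  z <- qr.solve(qr(A), y)
  cu <- as.numeric(N %*% z)
  structure(list(row = row,
                 coefficients = cu / 36^(0:6),
                 coef_u = cu,
                 domain = c(0, 36),
                 fitted = as.numeric(V %*% cu),
                 residuals = y - as.numeric(V %*% cu)),
            class = "eya_schedule")
}

## orthonormal basis of the null space of a matrix
null_space <- function(M) {
  s <- svd(M, nu = 0, nv = ncol(M))
  rank <- sum(s$d > max(dim(M)) * max(s$d) * .Machine$double.eps)
  s$v[, seq.int(rank + 1L, ncol(M)), drop = FALSE]
}

#' Evaluate an Eya schedule
#'
#' @param schedule an \code{eya_schedule}.
#' @param t time in hours, within the 0-36 h domain (values outside are
#'   clamped).
#' @param clip clip negative intensities at zero (the default; intensity
#'   is non-negative by construction).
#' @return Eya intensity (arb. unit).
#' @export
eval_schedule <- function(schedule, t, clip = TRUE) {
  u <- pmin(1, pmax(0, t / 36))
  cu <- schedule$coef_u
  y <- rep(cu[7], length(u))
  for (k in 6:1) y <- y * u + cu[k]           # Horner in u
  if (clip) y <- pmax(y, 0)
  y
}

#' @export
print.eya_schedule <- function(x, ...) {
  cat(sprintf("Eya schedule (row %s), 6th-order polynomial on [0, 36] h\n",
              x$row))
  cat(sprintf("  E(0) = %.1f, E(18) = %.1f, E(36) = %.1f arb. unit\n",
              eval_schedule(x, 0), eval_schedule(x, 18), eval_schedule(x, 36)))
  cat(sprintf("  max |residual| = %.3g\n", max(abs(x$residuals))))
  invisible(x)
}

## derivative of the schedule (arb. unit per hour)
schedule_deriv <- function(schedule, t) {
  u <- t / 36
  cu <- schedule$coef_u
  y <- rep(6 * cu[7], length(u))
  for (k in 5:1) y <- y * u + k * cu[k + 1L]
  y / 36
}

#' Fit schedules for all rows
#'
#' @param stage_means data.frame from [default_stage_means()] (columns
#'   \code{row}, \code{t_mid} or \code{stage}, \code{mean_eya}).
#' @param stages stage table.
#' @return named list of \code{eya_schedule} objects, one per row
#'   (\code{"1"} .. \code{"7"}).
#' @export
fit_all_schedules <- function(stage_means = default_stage_means(),
                              stages = stage_table()) {
  rows <- sort(unique(stage_means$row))
  out <- lapply(rows, function(r)
    fit_schedule(stage_means[stage_means$row == r, , drop = FALSE],
                 stages = stages, row = r))
  names(out) <- as.character(rows)
  out
}

## constant schedule helper (exactly constraint-compatible)
constant_schedule <- function(value, row = NA_integer_) {
  structure(list(row = row,
                 coefficients = c(value, 0, 0, 0, 0, 0, 0),
                 coef_u = c(value, 0, 0, 0, 0, 0, 0),
                 domain = c(0, 36), fitted = NULL, residuals = numeric(0)),
            class = "eya_schedule")
}

## ---- Eya -> affinity --------------------------------------------------

#' Map Eya intensity to affinity
#'
#' For the follicle-cell model, affinity is a non-negative, linearly
#' increasing function of Eya intensity (a = E / kappa_fc).  For the
#' germline model, the effective affinity is signed about the
#' zero-affinity constant of 72 arb. unit: positive values denote
#' effective nurse-cell affinity of the boundary, negative values
#' effective oocyte affinity.
#'
#' @param E Eya intensity (arb. unit), non-negative.
#' @param model \code{"fc"} or \code{"germline"}.
#' @param kappa_fc scale (arb. unit) dividing Eya for the fc model.
#' @param kappa_germline scale (arb. unit) dividing (E - eya_zero).
#' @param eya_zero Eya level of zero effective affinity (72 arb. unit).
#' @return affinity (dimensionless, order 1 at typical intensities).
#' @export
#' @examples
#' eya_to_affinity(72, "germline")   # exactly 0
#' eya_to_affinity(130, "fc")
eya_to_affinity <- function(E, model = c("fc", "germline"),
                            kappa_fc = 130, kappa_germline = 60,
                            eya_zero = 72) {
  model <- match.arg(model)
  if (any(E < 0)) stopf("Eya intensity must be non-negative")
  switch(model,
         fc = E / kappa_fc,
         germline = (E - eya_zero) / kappa_germline)
}

## ---- scenarios --------------------------------------------------------

fc_scenarios <- c("wt", "uniform_high", "row3_kd", "rows6to8_ectopic")
germline_scenarios <- c("germline_wt", "premature_loss",
                        "ectopic_nc_affinity", "all_negative")

#' Build a simulation scenario
#'
#' Applies the named perturbation to a base set of row schedules and
#' returns the per-cell (fc model) or per-row (germline model) schedule
#' assignment.  In the 14-cell follicle-cell model, rows 1-6 drive cells
#' 1-6 and the row-7 dynamic drives cells 7-14.
#'
#' Follicle-cell scenarios: \code{wt} (identity), \code{uniform_high}
#' (rows 1-6 all carry the row-1 high-affinity dynamic), \code{row3_kd}
#' (row 3 replaced by a low constant, an Eya knockdown), and
#' \code{rows6to8_ectopic} (rows 6-8 carry the row-2 dynamic).
#'
#' Germline scenarios: \code{germline_wt}; \code{premature_loss}
#' (epithelium-wide Eya collapse in phase 1, onset at a germline area of
#' 1600 um^2); \code{ectopic_nc_affinity} (main-body rows keep high Eya
#' after phase 1, onset at the phase-1/2 boundary); \code{all_negative}
#' (entire epithelium Eya-negative after phase 1).
#'
#' @param name scenario name.
#' @param base_schedules named list of row schedules covering rows 1-7
#'   (from [fit_all_schedules()]).
#' @param low_eya intensity used for knocked-down/negative rows.
#' @param stages stage table (onset times for germline scenarios).
#' @return object of class \code{scenario_spec}: list with \code{model},
#'   \code{name}, \code{schedules} (per cell for fc, per row for
#'   germline), \code{onset} (h, germline perturbations), and
#'   \code{overrides} (description of substitutions).
#' @export
scenario <- function(name, base_schedules = fit_all_schedules(),
                     low_eya = 15, stages = stage_table()) {
  if (!name %in% c(fc_scenarios, germline_scenarios))
    stopf("unknown scenario '%s'", name)
  if (!all(as.character(1:7) %in% names(base_schedules)))
    stopf("base schedules must cover rows 1-7")
  sch <- base_schedules[as.character(1:7)]
  amap <- area_time_map(stages)
  if (name %in% fc_scenarios) {
    ## per-cell assignment for 14 cells: rows 1-6 -> cells 1-6, row 7 -> 7-14
    cell_rows <- c(1:6, rep(7L, 8L))
    cells <- sch[as.character(cell_rows)]
    overrides <- list()
    if (name == "uniform_high") {
      cells[1:6] <- sch["1"]
      overrides <- list(rows = 1:6, from = "row 1")
    } else if (name == "row3_kd") {
      cells[[3L]] <- constant_schedule(low_eya, row = 3L)
      overrides <- list(rows = 3L, from = sprintf("constant %g", low_eya))
    } else if (name == "rows6to8_ectopic") {
      cells[6:8] <- sch["2"]
      overrides <- list(rows = 6:8, from = "row 2")
    }
    names(cells) <- sprintf("cell%02d", 1:14)
    structure(list(model = "fc", name = name, schedules = cells,
                   cell_rows = cell_rows, onset = NULL,
                   overrides = overrides),
              class = "scenario_spec")
  } else {
    onset <- NULL; overrides <- list()
    if (name == "premature_loss") {
      onset <- amap$time(1600)          # driver reaches strength early in phase 1
      overrides <- list(rows = 1:7, to = sprintf("constant %g", low_eya),
                        onset_area = 1600)
    } else if (name == "ectopic_nc_affinity") {
      onset <- attr(stages, "t12")
      overrides <- list(rows = 7L, to = "row 2", onset_area = amap$area(onset))
    } else if (name == "all_negative") {
      onset <- attr(stages, "t12")
      overrides <- list(rows = 1:7, to = sprintf("constant %g", low_eya),
                        onset_area = amap$area(onset))
    }
    structure(list(model = "germline", name = name, schedules = sch,
                   onset = onset, low_eya = low_eya, overrides = overrides),
              class = "scenario_spec")
  }
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s model)\n", x$name, x$model))
  if (length(x$overrides))
    cat("  overrides:", paste(names(x$overrides),
                              vapply(x$overrides, function(v)
                                paste(format(v), collapse = ","),
                                character(1)),
                              sep = "=", collapse = "; "), "\n")
  invisible(x)
}

## Eya level of germline-scenario row r at time t, with scenario
## perturbations (onset ramps over `ramp` hours) applied.
scenario_row_eya <- function(spec, r, t, ramp = 2) {
  base <- eval_schedule(spec$schedules[[as.character(r)]], t)
  if (spec$name == "germline_wt" || is.null(spec$onset)) return(base)
  w <- pmin(1, pmax(0, (t - spec$onset) / ramp))   # 0 before onset, 1 after
  if (spec$name == "premature_loss" || spec$name == "all_negative") {
    base * (1 - w) + spec$low_eya * w
  } else if (spec$name == "ectopic_nc_affinity") {
    if (r == 7L) {
      high <- eval_schedule(spec$schedules[["2"]], t)
      base * (1 - w) + high * w
    } else base
  } else base
}

## ---- row positions & boundary affinity field -------------------------

#' Default normalized row positions along the anterior-posterior boundary
#'
#' Normalized arc distance (0 = anterior pole, 1 = posterior pole) of the
#' centres of follicle-cell rows 1-7 as a function of time.  Anterior
#' rows expand their footprint as flattening proceeds: the posterior
#' edge of row 6 advances from 0.40 to 0.52 of the boundary through
#' phases 1-2 and accelerates to 0.64 during phase 3, when anterior-cell
#' flattening completes and Eya-positive rows overrun the nurse
#' cell-oocyte boundary.  Row 7 territory (carrying the Eya-low dynamic)
#' begins just posterior of row 6's edge.
#'
#' @param t time (h).
#' @param edge6_waypoints posterior edge of row 6 at t = 0, at the
#'   phase-2/3 boundary (31.5 h) and at t = 36.
#' @return matrix (length(t) x 7) of row positions.
#' @export
default_row_positions <- function(t, edge6_waypoints = c(0.40, 0.52, 0.64)) {
  e6 <- approx(c(0, 31.5, 36), edge6_waypoints,
               xout = pmin(36, pmax(0, t)), rule = 2)$y
  centres <- outer(e6, (1:6 - 0.5) / 6)       # rows 1-6 within [0, edge6]
  row7 <- e6 + 0.02                           # row-7 territory starts here
  cbind(centres, row7)
}

#' Boundary affinity field for the germline model
#'
#' Interpolates per-row effective affinities at their time-dependent
#' positions into a continuous signed field g(s, t) over the normalized
#' boundary coordinate s.  Posterior of the row-7 position the (Eya-low)
#' row-7 value applies; anterior of row 1 the row-1 value applies.
#'
#' @param spec a germline \code{scenario_spec} (see [scenario()]).
#' @param row_positions function(t) returning a (1 x 7) or (length(t) x 7)
#'   matrix of row-centre positions; default [default_row_positions()].
#' @param kappa_germline,eya_zero passed to [eya_to_affinity()].
#' @return object of class \code{affinity_field}: function \code{g(s, t)}
#'   (vectorized over s for scalar t) with the scenario attached.
#' @export
boundary_affinity_field <- function(spec,
                                    row_positions = default_row_positions,
                                    kappa_germline = 60, eya_zero = 72) {
  if (!inherits(spec, "scenario_spec") || spec$model != "germline")
    stopf("boundary_affinity_field() needs a germline scenario_spec")
  g <- function(s, t) {
    stopifnot(length(t) == 1L)
    pos <- drop(row_positions(t))
    if (is.unsorted(pos, strictly = TRUE))
      stopf("row positions must be strictly increasing along the boundary")
    E <- vapply(1:7, function(r) scenario_row_eya(spec, r, t), numeric(1))
    aff <- eya_to_affinity(E, "germline", kappa_germline = kappa_germline,
                           eya_zero = eya_zero)
    approx(pos, aff, xout = pmin(1, pmax(0, s)), rule = 2)$y
  }
  structure(g, class = c("affinity_field", "function"), spec = spec)
}

## ---- schedule IO ------------------------------------------------------

#' Write/read schedules as CSV (row, c0..c6; coefficients in hours basis)
#' @param schedules named list of \code{eya_schedule}s.
#' @param path CSV path.
#' @export
write_schedules <- function(schedules, path) {
  m <- t(vapply(schedules, function(s) s$coefficients, numeric(7)))
  df <- data.frame(row = vapply(schedules, function(s) s$row, numeric(1)), m)
  names(df) <- c("row", paste0("c", 0:6))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedules
#' @export
read_schedules <- function(path) {
  df <- read.csv(path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    ch <- as.numeric(df[i, paste0("c", 0:6)])
    structure(list(row = df$row[i], coefficients = ch,
                   coef_u = ch * 36^(0:6), domain = c(0, 36),
                   fitted = NULL, residuals = numeric(0)),
              class = "eya_schedule")
  })
  names(out) <- as.character(df$row)
  out
}
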