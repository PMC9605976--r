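## Morphometric description of a medial egg-chamber section: the
## 24-parameter record, phase assignment by germline area, contact
## proportions, the oocyte-nurse-cell interface angle, row profiles and
## nurse-cell variance statistics.
##
## The published parameter schema lives in supplementary material that
## only lists a subset of parameters by name; the 24-parameter schema
## implemented here (see [measure()]) is a documented reconstruction
## that covers the named germline, follicle-cell and interaction
## descriptors.

#' Phase thresholds
#'
#' Germline-area boundaries separating the three morphogenetic phases:
#' 6500 um^2 (phase 1/2) and 31500 um^2 (phase 2/3).
#'
#' @param t12,t23 thresholds in um^2, 0 < t12 < t23.
#' @return list with elements \code{t12}, \code{t23}.
#' @export
phase_thresholds <- function(t12 = 6500, t23 = 31500) {
  if (!(t12 > 0 && t23 > t12)) stopf("need 0 < t12 < t23")
  list(t12 = t12, t23 = t23)
}

#' Assign a morphogenetic phase from germline area
#'
#' Intervals are left-closed/right-open: phase 1 is [0, t12), phase 2
#' [t12, t23), phase 3 [t23, Inf).
#'
#' @param area germline area (um^2), positive; vectorized.
#' @param thresholds a [phase_thresholds()] list.
#' @return integer phase in {1, 2, 3}.
#' @export
#' @examples
#' assign_phase(c(5000, 6500, 40000))   # 1 2 3
assign_phase <- function(area, thresholds = phase_thresholds()) {
  if (any(area <= 0)) stopf("germline area must be positive")
  1L + (area >= thresholds$t12) + (area >= thresholds$t23)
}

## arc distance of the interface endpoints from the anterior pole
interface_arc_position <- function(g) {
  th1 <- acos(pmin(1, pmax(-1, g$chord_x / g$a)))
  ellipse_arc_from_anterior(g$a, g$b, th1)
}

#' Proportion of section follicle cells in contact with the oocyte
#'
#' Fraction of section FCs whose arc position lies on the
#' oocyte-adjacent portion of the outer contour (posterior of the
#' interface endpoints).
#'
#' @param geometry an \code{egg_chamber_geometry}.
#' @return proportion in [0, 1].
#' @export
contact_proportion <- function(geometry) {
  if (geometry$fc_count_section < 1L) stopf("geometry has no follicle cells")
  if (geometry$oocyte_fraction <= 0) return(0)
  if (geometry$oocyte_fraction >= 1) return(1)
  s_if <- interface_arc_position(geometry)
  d <- pmin(geometry$fc_s, geometry$perimeter - geometry$fc_s)
  mean(d > s_if)
}

## local tangent of a polyline at index i by quadratic fit over a window
## of total arc length 2*halfwidth
polyline_tangent <- function(pts, i, halfwidth) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  keep <- abs(s - s[i]) <= halfwidth
  if (sum(keep) < 3L) keep <- seq.int(max(1L, i - 2L), min(nrow(pts), i + 2L))
  u <- s[keep] - s[i]
  fx <- lm.fit(cbind(1, u, u^2), pts[keep, 1L])$coefficients
  fy <- lm.fit(cbind(1, u, u^2), pts[keep, 2L])$coefficients
  v <- c(fx[2L], fy[2L])
  v / sqrt(sum(v^2))
}

#' Interface contact angle
#'
#' Angle at the contact points between the oocyte-nurse-cell interface
#' and the outer contour, measured through the oocyte and averaged over
#' both contact points.  90 degrees reflects balanced forces; values
#' below 90 indicate effective oocyte affinity for the epithelium
#' (oocyte wetting), values above 90 effective nurse-cell affinity.
#'
#' Contour tangents are estimated by a local quadratic fit over a
#' +/-5 percent perimeter window (configurable).
#'
#' @param geometry an \code{egg_chamber_geometry}.
#' @param tangent_window half-window for the contour tangent fit, as a
#'   fraction of the perimeter.
#' @return angle in degrees.
#' @export
interface_angle <- function(geometry, tangent_window = 0.05) {
  iface <- geometry$nc_oocyte_interface
  if (is.null(iface) || nrow(iface) < 3L)
    stopf("interface does not reach the contour")
  contour <- geometry$outer_contour
  P <- geometry$perimeter
  posterior_pole <- contour[which.max(contour[, 1L]), ]
  ang_at <- function(endpoint, into) {
    ## nearest contour vertex to the triple point
    i <- which.min((contour[, 1L] - endpoint[1L])^2 +
                   (contour[, 2L] - endpoint[2L])^2)
    closed <- rbind(contour, contour[1:2, , drop = FALSE])
    tc <- polyline_tangent(closed, i, tangent_window * P)
    ## orient the contour tangent towards the posterior pole (oocyte side)
    if (sum(tc * (posterior_pole - contour[i, ])) < 0) tc <- -tc
    v <- into / sqrt(sum(into^2))
    acos(pmin(1, pmax(-1, sum(tc * v)))) * 180 / pi
  }
  n <- nrow(iface)
  iface_len <- sum(sqrt(rowSums(diff(iface)^2)))
  t_top <- polyline_tangent(iface, 1L, 0.04 * iface_len)
  if (sum(t_top * (iface[min(5L, n), ] - iface[1L, ])) < 0) t_top <- -t_top
  t_bot <- polyline_tangent(iface, n, 0.04 * iface_len)
  if (sum(t_bot * (iface[max(1L, n - 4L), ] - iface[n, ])) < 0) t_bot <- -t_bot
  mean(c(ang_at(iface[1L, ], t_top), ang_at(iface[n, ], t_bot)))
}

#' Nurse-cell variance statistics
#'
#' Coefficients of variation (sd/mean) of per-nurse-cell FC-interface
#' fractions and of per-nurse-cell area fractions within the sectioned
#' cluster.
#'
#' @param geometry an \code{egg_chamber_geometry}.
#' @return list with \code{cv_interface_fraction}, \code{cv_area_fraction}.
#' @export
nurse_cell_cv <- function(geometry) {
  af <- geometry$nc_area_fraction
  iff <- geometry$nc_interface_fraction
  if (length(af) < 2L || length(iff) < 2L)
    stopf("need at least 2 nurse cells resolvable in the section")
  list(cv_interface_fraction = sd(iff) / mean(iff),
       cv_area_fraction = sd(af) / mean(af))
}

#' Apical-extent and Eya profile by follicle-cell row
#'
#' Rows are equal-arc-length positional bins from the anterior pole with
#' bin width equal to the mean apical extent of the current anterior
#' follicle cells (a reproducible stand-in for visual row counting).
#'
#' @param geometry an \code{egg_chamber_geometry}.
#' @return data.frame with columns \code{row}, \code{distance_to_anterior}
#'   (um, bin midpoint), \code{apical_extent} (um, mean over the bin),
#'   \code{eya} (arb. unit, mean over the bin), \code{n_cells}.
#' @export
apical_area_profile <- function(geometry) {
  d <- pmin(geometry$fc_s, geometry$perimeter - geometry$fc_s)
  w <- afc_bin_width(geometry)
  row <- pmax(1L, ceiling(d / w))
  agg <- function(v) vapply(split(v, row), mean, numeric(1))
  out <- data.frame(row = as.integer(names(agg(d))),
                    distance_to_anterior = (as.integer(names(agg(d))) - 0.5) * w,
                    apical_extent = agg(geometry$fc_extent),
                    eya = agg(geometry$fc_eya),
                    n_cells = as.integer(table(row)))
  out[order(out$row), , drop = FALSE]
}

## row-bin width: mean apical extent of current anterior follicle cells
## (fate AFC if present, otherwise the six most anterior ordinals)
afc_bin_width <- function(geometry) {
  sel <- geometry$fc_fate == "AFC"
  if (!any(sel)) sel <- geometry$fc_ordinal <= 6L
  mean(geometry$fc_extent[sel])
}

#' Measure the 24-parameter morphometric record
#'
#' Computes the full morphometric description of a medial-section
#' geometry: germline/compartment areas (polygon integration of the
#' stored contours), contact proportions and interface lengths, the
#' interface angle (tangent fitting), anterior/posterior apical-extent
#' summaries, row counts, Eya summaries and nurse-cell variance
#' statistics.  Deterministic given the geometry.
#'
#' @param geometry an \code{egg_chamber_geometry}.
#' @param thresholds phase thresholds for the phase label.
#' @return an \code{egg_chamber_record}: one-row data.frame with 24
#'   quantitative parameters plus metadata columns \code{genotype} and
#'   \code{phase}.
#' @export
measure <- function(geometry, thresholds = phase_thresholds()) {
  g <- geometry
  area <- polygon_area(g$outer_contour)
  ooc <- polygon_area(g$oocyte_region)
  s_if <- interface_arc_position(g)
  d <- pmin(g$fc_s, g$perimeter - g$fc_s)
  on_oo <- d > s_if
  prop_oo <- mean(on_oo)
  L_oo <- g$perimeter - 2 * s_if
  ## nurse-side boundary cells: last nurse-arc cell on each side
  ncob <- which(!on_oo & (d >= sort(d[!on_oo], decreasing = TRUE)[min(2L, sum(!on_oo))]))
  nc_cv <- nurse_cell_cv(g)
  rec <- data.frame(
    germline_area = area,
    egg_chamber_area = g$egg_chamber_area,
    oocyte_area = ooc,
    nc_compartment_area = area - ooc,
    oocyte_fraction_of_germline = ooc / area,
    fc_count_section = g$fc_count_section,
    fc_count_total = g$fc_count_total,
    prop_fc_on_oocyte = prop_oo,
    oocyte_fc_interface_fraction = L_oo / g$perimeter,
    oocyte_fc_interface_length = L_oo,
    nc_fc_interface_length = g$perimeter - L_oo,
    interface_angle = interface_angle(g),
    afc_row_count_on_nc = round(s_if / afc_bin_width(g)),
    aspect_ratio = diff(range(g$outer_contour[, 1L])) /
                   diff(range(g$outer_contour[, 2L])),
    mean_apical_anterior = mean(g$fc_extent[!on_oo]),
    max_apical_anterior = max(g$fc_extent[!on_oo]),
    mean_apical_posterior = mean(g$fc_extent[on_oo]),
    max_apical_posterior = max(g$fc_extent[on_oo]),
    eya_mean_at_ncob = mean(g$fc_eya[ncob]),
    eya_mean_anterior = mean(g$fc_eya[g$fc_ordinal <= 6L]),
    eya_mean_posterior = mean(g$fc_eya[g$fc_ordinal >= 7L]),
    nc_size_cv = nc_cv$cv_area_fraction,
    nc_fc_interface_cv = nc_cv$cv_interface_fraction,
    perimeter = g$perimeter)
  stopifnot(ncol(rec) == 24L)
  rec$genotype <- g$genotype
  rec$phase <- assign_phase(area, thresholds)
  class(rec) <- c("egg_chamber_record", "data.frame")
  rec
}

#' Measure a whole cohort
#'
#' @param cohort an \code{egg_chamber_cohort} (or list of geometries).
#' @param thresholds phase thresholds.
#' @return data.frame with one \code{egg_chamber_record} row per chamber
#'   and an \code{id} column.
#' @export
measure_cohort <- function(cohort, thresholds = phase_thresholds()) {
  recs <- lapply(cohort, measure, thresholds = thresholds)
  out <- do.call(rbind, recs)
  out$id <- seq_along(cohort)
  class(out) <- c("egg_chamber_records", "data.frame")
  out
}

#' Names of the 24 quantitative morphometric parameters
#' @return character vector of the parameter column names.
#' @export
morphometric_parameters <- function() {
  c("germline_area", "egg_chamber_area", "oocyte_area",
    "nc_compartment_area", "oocyte_fraction_of_germline",
    "fc_count_section", "fc_count_total", "prop_fc_on_oocyte",
    "oocyte_fc_interface_fraction", "oocyte_fc_interface_length",
    "nc_fc_interface_length", "interface_angle", "afc_row_count_on_nc",
    "aspect_ratio", "mean_apical_anterior", "max_apical_anterior",
    "mean_apical_posterior", "max_apical_posterior", "eya_mean_at_ncob",
    "eya_mean_anterior", "eya_mean_posterior", "nc_size_cv",
    "nc_fc_interface_cv", "perimeter")
}
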