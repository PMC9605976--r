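## Two-phase germline model: a single order parameter psi (1 = oocyte,
## 0 = nurse compartment) in a fixed elliptical domain whose boundary
## carries the signed, Eya-derived affinity field g(s, t).  Positive g
## favours nurse-compartment contact with the epithelium, negative g
## favours oocyte contact.  psi is non-conserved; the compartment volume
## is stabilized against bulk (curvature-driven) drift so that the
## oocyte fraction responds only to the boundary wetting energetics and
## is an emergent output of the simulation.

#' Parameters of the germline phase-field model
#'
#' @param nx,ny grid size; the domain is the inscribed ellipse with
#'   semi-axes \code{margin} cells inside the grid.
#' @param margin grid cells between the ellipse and the grid edge.
#' @param D gradient-energy coefficient.
#' @param well double-well scale.
#' @param cwet wetting strength multiplying g(s, t) on the boundary
#'   band; sets the dynamic range of the contact angle.
#' @param kappa_germline,eya_zero Eya-to-affinity map constants
#'   (see [eya_to_affinity()]).
#' @param M mobility.
#' @param dt time step.
#' @param n_steps steps mapped onto the 36 h schedule window.
#' @param record_every,sched_every,snapshot_every strides.
#' @param growth_rate_max cap on the relative growth rate of the oocyte
#'   area fraction (per hour of schedule time); 0 disables the cap.
#' @return list of parameters.
#' @export
germline_params <- function(nx = 160L, ny = 108L, margin = 4L, D = 6,
                            well = 0.6, cwet = 0.35, kappa_germline = 60,
                            eya_zero = 72, M = 1, dt = 0.04,
                            n_steps = 90000L, record_every = 600L,
                            sched_every = 300L, snapshot_every = 3000L,
                            growth_rate_max = 0.15) {
  as.list(environment())
}

#' Initialize the germline model
#'
#' psi is initialized as a posterior cap of the requested area fraction
#' with a smoothed, chord-like interface; at the canonical starting
#' point the oocyte holds 1/16 of the germline section.
#'
#' @param oocyte_fraction0 initial oocyte area fraction, in (0, 1).
#' @param angle0 initial contact angle (degrees) encoded in the cap
#'   shape; NULL gives a straight chord.  Starting near the phase-1
#'   force balance shortens the initial transient.
#' @param seed integer seed for the symmetry-breaking perturbation.
#' @param params model parameters from [germline_params()].
#' @return object of class \code{germline_state}: psi matrix, domain
#'   mask, boundary-node indices and their normalized arc coordinate s
#'   (0 = anterior pole, 1 = posterior pole).
#' @export
init_germline <- function(oocyte_fraction0 = 1 / 16, angle0 = NULL,
                          seed = 0L, params = germline_params()) {
  if (!(oocyte_fraction0 > 0 && oocyte_fraction0 < 1))
    stopf("oocyte_fraction0 must lie in (0, 1)")
  p <- params
  cx <- (p$nx + 1) / 2; cy <- (p$ny + 1) / 2
  a <- p$nx / 2 - p$margin; b <- p$ny / 2 - p$margin
  xg <- matrix(seq_len(p$nx), p$nx, p$ny)
  yg <- matrix(seq_len(p$ny), p$nx, p$ny, byrow = TRUE)
  r <- sqrt(((xg - cx) / a)^2 + ((yg - cy) / b)^2)
  mask <- r <= 1
  ## boundary band: inside nodes with at least one outside 4-neighbour
  m <- mask
  shift <- function(mm, dx, dy) {
    out <- matrix(FALSE, p$nx, p$ny)
    xs <- seq_len(p$nx) - dx; ys <- seq_len(p$ny) - dy
    ok_x <- xs >= 1 & xs <= p$nx; ok_y <- ys >= 1 & ys <= p$ny
    out[ok_x, ok_y] <- mm[xs[ok_x], ys[ok_y]]
    out
  }
  interior <- m & shift(m, 1, 0) & shift(m, -1, 0) &
              shift(m, 0, 1) & shift(m, 0, -1)
  bnd <- which(m & !interior)
  ## normalized arc coordinate of boundary nodes (0 anterior, 1 posterior)
  bx <- (bnd - 1) %% p$nx + 1; by <- (bnd - 1) %/% p$nx + 1
  theta <- atan2((by - cy) / b, (bx - cx) / a)   # 0 = posterior, pi = anterior
  s <- ellipse_arc_from_anterior(a, b, abs(theta)) /
       (ellipse_perimeter(a, b) / 2)
  ## initial cap: chord (or angle-encoded interface) at the target fraction
  xi <- sqrt(p$D / (8 * p$well))
  if (is.null(angle0)) {
    x0 <- ellipse_segment_chord(a, b, oocyte_fraction0)
    psi <- (1 + tanh(((xg - cx) - x0) / (2 * xi))) / 2
  } else {
    iface <- build_interface(a, b, oocyte_fraction0, angle0)
    arc <- iface$interface
    x_if <- approx(arc[, 2L], arc[, 1L], xout = yg[1, ] - cy, rule = 2)$y
    psi <- (1 + tanh(((xg - cx) - rep(x_if, each = p$nx)) / (2 * xi))) / 2
  }
  psi[!mask] <- 0
  psi <- psi + with_seed(seed, matrix(runif(p$nx * p$ny, 0, 1e-3),
                                      p$nx, p$ny)) * mask
  structure(list(psi = psi, mask = mask, bnd_idx = bnd, bnd_s = s,
                 a = a, b = b, cx = cx, cy = cy,
                 oocyte_fraction0 = oocyte_fraction0,
                 seed = as.integer(seed), time = 0, params = p),
            class = "germline_state")
}

#' Evolve the germline model under a scenario
#'
#' Relaxational dynamics of the interfacial energy with the boundary
#' wetting term g(s, t) built from the scenario's row schedules and
#' row positions (see [boundary_affinity_field()]).
#'
#' @param state a \code{germline_state}.
#' @param scenario_spec a germline \code{scenario_spec}, an
#'   \code{affinity_field}, or a single number (uniform constant g, used
#'   for calibration against the analytic contact-angle relation).
#' @param t_end end of the simulated window (h).
#' @param params overrides \code{state$params} when given.
#' @return object of class \code{germline_trajectory}: psi snapshots
#'   (nx x ny x n_snap), time series of energy, oocyte area fraction and
#'   oocyte boundary (interface) fraction, snapshot times, state.
#' @export
evolve_germline <- function(state, scenario_spec, t_end = 36,
                            params = NULL) {
  p <- params %||% state$params
  n_steps <- as.integer(round(p$n_steps * t_end / 36))
  n_upd <- n_steps %/% p$sched_every + 1L
  t_upd <- seq(0, t_end, length.out = n_upd)
  gfun <- if (inherits(scenario_spec, "scenario_spec")) {
    boundary_affinity_field(scenario_spec,
                            kappa_germline = p$kappa_germline,
                            eya_zero = p$eya_zero)
  } else if (is.function(scenario_spec)) scenario_spec
  else function(s, t) rep(scenario_spec, length(s))
  gmat <- t(vapply(t_upd, function(t) gfun(state$bnd_s, t),
                   numeric(length(state$bnd_idx))))
  if (p$dt * p$M * (4 * p$D + 2 * p$well) > 1.2)
    stopf("dt = %g unstable for D = %g (explicit scheme)", p$dt, p$D)
  res <- germline_evolve_cpp(as.numeric(state$psi), p$nx, p$ny,
                             as.integer(state$mask),
                             as.integer(state$bnd_idx - 1L), gmat,
                             p$sched_every, p$D, p$well, p$cwet, p$M,
                             p$dt, n_steps, p$record_every,
                             p$snapshot_every,
                             p$growth_rate_max * 36 / p$n_steps)
  final <- state
  nsnap <- dim(res$psi)[3L]
  final$psi <- matrix(res$psi[, , nsnap], p$nx, p$ny)
  final$time <- t_end
  structure(list(psi = res$psi,
                 snap_time_h = as.numeric(res$snap_step) / p$n_steps * 36,
                 energy = as.numeric(res$energy),
                 oocyte_area_fraction = as.numeric(res$area_fraction),
                 oocyte_interface_fraction = as.numeric(res$boundary_fraction),
                 time_h = as.numeric(res$step) / p$n_steps * 36,
                 final = final, state = state,
                 scenario = if (inherits(scenario_spec, "scenario_spec"))
                   scenario_spec$name else "custom",
                 params = p), class = "germline_trajectory")
}

#' Interface contact angle of a psi field
#'
#' The psi = 0.5 level set is extracted, its portion interior to the
#' domain taken as the oocyte-nurse-cell interface, and the contact
#' angle with the domain boundary measured through the oocyte at both
#' triple points by tangent fitting (averaged).
#'
#' @param psi matrix field.
#' @param state the \code{germline_state} (for the domain geometry).
#' @return angle in degrees, or NA when the interface does not reach
#'   the boundary (detached/vanished oocyte).
#' @export
germline_angle <- function(psi, state, reach = 0.2) {
  cl <- grDevices::contourLines(x = seq_len(nrow(psi)),
                                y = seq_len(ncol(psi)), z = psi,
                                levels = 0.5)
  if (!length(cl)) return(NA_real_)
  ## longest contour run interior to the domain = the oocyte-nurse
  ## interface; its endpoints are the triple points
  best <- NULL; best_len <- 0
  for (cc in cl) {
    pts <- cbind(cc$x, cc$y)
    if (nrow(pts) > 2L && all(pts[1L, ] == pts[nrow(pts), ])) {
      ## rotate closed curves so runs do not wrap across the seam
      r0 <- sqrt(((pts[, 1] - state$cx) / state$a)^2 +
                 ((pts[, 2] - state$cy) / state$b)^2)
      k <- which.max(r0)
      pts <- rbind(pts[k:nrow(pts), , drop = FALSE],
                   pts[seq_len(k - 1L), , drop = FALSE])
    }
    r <- sqrt(((pts[, 1] - state$cx) / state$a)^2 +
              ((pts[, 2] - state$cy) / state$b)^2)
    interior <- r < 0.985
    if (!any(interior)) next
    runs <- rle(interior)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (j in which(runs$values)) {
      seg <- pts[starts[j]:ends[j], , drop = FALSE]
      len <- if (nrow(seg) > 1) sum(sqrt(rowSums(diff(seg)^2))) else 0
      if (len > best_len) { best <- seg; best_len <- len }
    }
  }
  if (is.null(best) || nrow(best) < 5L) return(NA_real_)
  ## mesoscopic secant angle at each triple point, measured through the
  ## oocyte: the interface direction is the secant from the triple
  ## point to the point `reach` of the interface length inward, and the
  ## boundary tangent points towards increasing arc coordinate s (the
  ## posterior, oocyte-contacting side)
  arc <- c(0, cumsum(sqrt(rowSums(diff(best)^2))))
  angle_at <- function(from_start) {
    if (from_start) { pt <- best[1L, ]; d <- arc } else {
      pt <- best[nrow(best), ]; d <- max(arc) - arc
    }
    target <- min(reach * best_len, 14)
    k <- which.min(abs(d - target))
    v <- best[k, ] - pt
    if (sqrt(sum(v^2)) < 1e-9) return(NA_real_)
    v <- v / sqrt(sum(v^2))
    th <- atan2((pt[2] - state$cy) / state$b, (pt[1] - state$cx) / state$a)
    ## increasing-s direction: towards theta = 0 (posterior pole)
    tb <- c(state$a * sin(th), -state$b * cos(th)) * sign(th + 1e-12)
    tb <- tb / sqrt(sum(tb^2))
    acos(pmin(1, pmax(-1, sum(v * tb)))) * 180 / pi
  }
  mean(c(angle_at(TRUE), angle_at(FALSE)), na.rm = TRUE)
}

#' Read out a germline trajectory
#'
#' @param trajectory a \code{germline_trajectory}.
#' @return object of class \code{germline_readout}: data.frame time
#'   series of \code{interface_angle} (NA where the oocyte is detached
#'   from the boundary), \code{oocyte_interface_fraction},
#'   \code{oocyte_area_fraction}, plus the angle series at snapshot
#'   resolution.
#' @export
readout_germline <- function(trajectory) {
  tr <- trajectory
  nsnap <- dim(tr$psi)[3L]
  ang <- vapply(seq_len(nsnap), function(k)
    germline_angle(matrix(tr$psi[, , k], dim(tr$psi)[1L]), tr$state),
    numeric(1))
  angles <- data.frame(time_h = tr$snap_time_h, interface_angle = ang)
  series <- data.frame(time_h = tr$time_h,
                       oocyte_area_fraction = tr$oocyte_area_fraction,
                       oocyte_interface_fraction = tr$oocyte_interface_fraction)
  structure(list(angles = angles, series = series,
                 scenario = tr$scenario), class = "germline_readout")
}

#' @export
print.germline_trajectory <- function(x, ...) {
  cat(sprintf("Germline phase-field trajectory: scenario '%s', %.0f h\n",
              x$scenario, max(x$time_h)))
  cat(sprintf("  oocyte area fraction %.3f -> %.3f\n",
              x$oocyte_area_fraction[1L],
              x$oocyte_area_fraction[length(x$oocyte_area_fraction)]))
  invisible(x)
}

#' @export
print.germline_readout <- function(x, ...) {
  ok <- is.finite(x$angles$interface_angle)
  cat(sprintf("Germline readout ('%s'): angle %.1f-%.1f deg, final oocyte fraction %.3f\n",
              x$scenario, min(x$angles$interface_angle[ok]),
              max(x$angles$interface_angle[ok]),
              x$series$oocyte_area_fraction[nrow(x$series)]))
  invisible(x)
}

#' @export
plot.germline_readout <- function(x, ...) {
  plot(x$angles$time_h, x$angles$interface_angle, type = "b", pch = 16,
       xlab = "time (h)", ylab = "interface angle (deg)", ...)
  graphics::abline(h = 90, lty = 2)
  invisible(x)
}
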