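## Multicellular phase-field model of follicle cells on the germline
## surface.  N cells are smooth indicator fields on a 2-D strip whose
## bottom boundary represents the germline surface, divided into an
## affine (nurse-cell) and a non-affine (oocyte) compartment.  Affinity
## enters as a boundary contact-energy reward, so cells with high
## affinity expand their contact with the affine segment at the expense
## of their neighbours.

#' Parameters of the follicle-cell phase-field model
#'
#' Shipped wild-type calibration; all coefficients of the reconstructed
#' energy functional live here.
#'
#' @param nx,ny grid size (the germline surface is the bottom row).
#' @param D gradient-energy coefficient (sets interface width).
#' @param well double-well scale.
#' @param alpha_v volume-penalty stiffness (volumes are soft-constrained;
#'   drift stays within ~2 percent).
#' @param beta pairwise overlap penalty.
#' @param a_bg non-specific boundary adhesion of every cell.
#' @param kappa_fc Eya units per unit affinity (see [eya_to_affinity()]).
#' @param M mobility.
#' @param dt time step (stability-limited by the explicit scheme).
#' @param n_steps steps mapped onto the 36 h schedule window.
#' @param cell_height initial cell height in grid units.
#' @param record_every,sched_every recording / schedule-update strides.
#' @param detach_frac detachment threshold as a fraction of the cell's
#'   perimeter measure.
#' @return list of parameters.
#' @export
fc_params <- function(nx = 256L, ny = 64L, D = 4, well = 0.5, alpha_v = 4,
                      beta = 3, a_bg = 0.7, kappa_fc = 130, M = 1,
                      dt = 0.05, n_steps = 48000L, cell_height = 13,
                      record_every = 800L, sched_every = 40L,
                      detach_frac = 0.01) {
  as.list(environment())
}

#' Initialize the follicle-cell model
#'
#' Cells are seeded side by side on the bottom boundary with equal
#' volumes and smoothed indicator profiles.
#'
#' @param n_cells number of cells (3 for the local competition model,
#'   14 for the full anterior-posterior model).
#' @param affine_fraction portion of the bottom boundary that is affine
#'   (nurse-cell) territory, anchored at the anterior (left) end.  The
#'   default corresponds to the nurse-cell share of the germline surface
#'   during phase 2.
#' @param seed integer seed for the symmetry-breaking perturbation.
#' @param params model parameters from [fc_params()].
#' @return object of class \code{fc_state}.
#' @export
init_fc <- function(n_cells = 14L, affine_fraction = 0.55, seed = 0L,
                    params = fc_params()) {
  if (!(affine_fraction > 0 && affine_fraction <= 1))
    stopf("affine_fraction must lie in (0, 1]")
  nx <- params$nx; ny <- params$ny
  if (nx < 6L * n_cells) stopf("domain too small for %d cells", n_cells)
  w0 <- nx / n_cells
  h0 <- params$cell_height
  xi <- sqrt(params$D / (8 * params$well))   # interface half-width scale
  xg <- seq_len(nx) - 0.5; yg <- seq_len(ny) - 0.5
  prof <- function(d) (1 + tanh(d / (2 * xi))) / 2
  phi <- array(0, dim = c(nx, ny, n_cells))
  for (i in seq_len(n_cells)) {
    x0 <- (i - 1) * w0; x1 <- i * w0
    px <- prof(xg - x0) * prof(x1 - xg)
    py <- prof(h0 - yg)
    phi[, , i] <- outer(px, py)
  }
  phi <- phi + with_seed(seed, array(runif(length(phi), 0, 1e-3), dim(phi)))
  V0 <- vapply(seq_len(n_cells), function(i) {
    p <- phi[, , i]; sum(p^2 * (3 - 2 * p))
  }, numeric(1))
  structure(list(phi = phi, n_cells = n_cells,
                 affine_fraction = affine_fraction,
                 n_affine = as.integer(round(affine_fraction * nx)),
                 V0 = V0, time = 0, seed = as.integer(seed),
                 params = params),
            class = "fc_state")
}

#' Energy of a follicle-cell state
#'
#' Total and per-term energy of the reconstructed functional:
#' interfacial (gradient + double well), volume penalty, pairwise
#' overlap penalty, and the (negative) boundary contact reward, which is
#' linear in each cell's affinity.
#'
#' @param state an \code{fc_state}.
#' @param affinities per-cell affinities (dimensionless); defaults to 0.
#' @return list with \code{total} and the individual terms.
#' @export
fc_energy <- function(state, affinities = rep(0, state$n_cells)) {
  p <- state$params
  fc_energy_cpp(as.numeric(state$phi), p$nx, p$ny, state$n_cells,
                as.numeric(affinities), state$n_affine, p$D, p$well,
                p$alpha_v, p$beta, p$a_bg, state$V0)
}

#' Evolve the follicle-cell model under a scenario
#'
#' Relaxational (gradient-flow) dynamics of the energy with
#' time-varying per-cell affinities taken from the scenario's Eya
#' schedules; the simulated window maps linearly onto the 36 h schedule
#' domain.
#'
#' @param state an \code{fc_state} from [init_fc()].
#' @param scenario_spec an fc \code{scenario_spec} (see [scenario()]),
#'   or a numeric matrix/vector of per-cell affinities (constant or one
#'   row per schedule update) for direct control.
#' @param t_end end of the simulated window (h).
#' @param params overrides \code{state$params} when given.
#' @return object of class \code{fc_trajectory}: list with
#'   \code{contact_affine}, \code{contact_nonaffine}, \code{volumes}
#'   (time x cell matrices), \code{energy}, \code{time_h}, \code{final}
#'   (an \code{fc_state}), \code{affinities}, \code{scenario}.
#' @export
evolve_fc <- function(state, scenario_spec, t_end = 36, params = NULL) {
  p <- params %||% state$params
  n_steps <- as.integer(round(p$n_steps * t_end / 36))
  n_upd <- n_steps %/% p$sched_every + 1L
  t_upd <- seq(0, t_end, length.out = n_upd)
  aff <- if (inherits(scenario_spec, "scenario_spec")) {
    if (scenario_spec$model != "fc")
      stopf("scenario '%s' is not an fc scenario", scenario_spec$name)
    vapply(scenario_spec$schedules, function(s)
      eya_to_affinity(eval_schedule(s, t_upd), "fc", kappa_fc = p$kappa_fc),
      numeric(n_upd))
  } else if (is.matrix(scenario_spec)) scenario_spec
  else matrix(scenario_spec, nrow = n_upd, ncol = state$n_cells,
              byrow = TRUE)
  if (ncol(aff) != state$n_cells)
    stopf("affinity matrix must have %d columns", state$n_cells)
  ## stability guard for the explicit scheme
  if (p$dt * p$M * (4 * p$D + 2 * p$well) > 1)
    stopf("dt = %g unstable for D = %g (explicit scheme)", p$dt, p$D)
  res <- fc_evolve_cpp(as.numeric(state$phi), p$nx, p$ny, state$n_cells,
                       aff, p$sched_every, state$n_affine, p$D, p$well,
                       p$alpha_v, p$beta, p$a_bg, state$V0, p$M, p$dt,
                       n_steps, p$record_every)
  final <- state
  final$phi <- array(res$phi, dim = c(p$nx, p$ny, state$n_cells))
  final$time <- t_end
  structure(list(contact_affine = res$contact_affine,
                 contact_nonaffine = res$contact_nonaffine,
                 volumes = res$volumes, energy = as.numeric(res$energy),
                 time_h = as.numeric(res$step) / p$n_steps * 36,
                 final = final, affinities = aff,
                 scenario = if (inherits(scenario_spec, "scenario_spec"))
                   scenario_spec$name else "custom",
                 params = p), class = "fc_trajectory")
}

## perimeter measure of each cell's final field: integral of |grad phi|
fc_perimeters <- function(state) {
  vapply(seq_len(state$n_cells), function(i) {
    p <- state$phi[, , i]
    gx <- p[-1, ] - p[-nrow(p), ]
    gy <- p[, -1] - p[, -ncol(p)]
    sum(sqrt(gx[, -1]^2 + gy[-1, ]^2))
  }, numeric(1))
}

#' Read out a follicle-cell trajectory
#'
#' Per-cell contact-length time series on the affine and non-affine
#' boundary segments, squared apical lengths (comparable to apical
#' surface areas), compartment classification, and the detached set:
#' cells whose total boundary contact stays below \code{detach_frac}
#' of their perimeter measure over the final tenth of the run.
#'
#' @param trajectory an \code{fc_trajectory}.
#' @return object of class \code{fc_readout}: list with
#'   \code{contact_lengths} (long data.frame), \code{apical_extent_sq},
#'   \code{on_affine} (logical, final time), \code{detached} (integer
#'   cell ids), \code{n_on_affine}.
#' @export
readout_fc <- function(trajectory) {
  tr <- trajectory
  nt <- nrow(tr$contact_affine); nc <- ncol(tr$contact_affine)
  perim <- fc_perimeters(tr$final)
  thr <- tr$params$detach_frac * perim
  total <- tr$contact_affine + tr$contact_nonaffine
  tail_win <- which(tr$time_h >= max(tr$time_h) * 0.9)
  detached <- which(vapply(seq_len(nc), function(i)
    all(total[tail_win, i] < thr[i]), logical(1)))
  ## attached cells are assigned to their majority compartment
  on_affine <- tr$contact_affine[nt, ] > pmax(thr, tr$contact_nonaffine[nt, ]) &
    !(seq_len(nc) %in% detached)
  long <- data.frame(
    cell = rep(seq_len(nc), each = nt),
    time_h = rep(tr$time_h, nc),
    contact_affine = as.vector(tr$contact_affine),
    contact_nonaffine = as.vector(tr$contact_nonaffine))
  structure(list(contact_lengths = long,
                 apical_extent_sq = total^2,
                 on_affine = on_affine,
                 detached = detached,
                 n_on_affine = sum(on_affine),
                 time_h = tr$time_h), class = "fc_readout")
}

#' @export
print.fc_trajectory <- function(x, ...) {
  cat(sprintf("FC phase-field trajectory: scenario '%s', %d cells, %.0f h\n",
              x$scenario, ncol(x$contact_affine), max(x$time_h)))
  cat(sprintf("  energy %.1f -> %.1f; max volume drift %.2f%%\n",
              x$energy[1L], x$energy[length(x$energy)],
              100 * max(abs(t(x$volumes) / x$volumes[1L, ] - 1))))
  invisible(x)
}

#' @export
print.fc_readout <- function(x, ...) {
  cat(sprintf("FC readout: %d cells on the affine compartment at final time\n",
              x$n_on_affine))
  if (length(x$detached))
    cat("  detached cells:", paste(x$detached, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.fc_trajectory <- function(x, ...) {
  graphics::matplot(x$time_h, x$contact_affine, type = "l", lty = 1,
                    xlab = "time (h)", ylab = "affine contact length",
                    ...)
  invisible(x)
}
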