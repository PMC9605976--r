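## shared fixtures: everything is generated in code at test time

quiet_cfg <- function(...) generator_config(noise_cv = 0, ...)

## small noise-free wild-type cohort over a fixed area grid
small_cohort <- function(n = 24, genotype = "wt", seed = 1,
                         noise_cv = 0, amin = 1600, amax = 55000) {
  cfg <- generator_config(seed = seed, n_chambers = n, genotype = genotype,
                          noise_cv = noise_cv)
  areas <- exp(seq(log(amin), log(amax), length.out = n))
  chambers <- lapply(seq_along(areas), function(i)
    generate_chamber(areas[i], genotype, seed = seed + i, config = cfg))
  structure(chambers, class = "egg_chamber_cohort", config = cfg)
}

## fast parameter sets for the PDE models (coarse but stable)
quick_fc_params <- function(...) {
  args <- list(nx = 96L, ny = 40L, n_steps = 4000L, record_every = 200L,
               sched_every = 40L)
  do.call(fc_params, utils::modifyList(args, list(...)))
}
quick_germ_params <- function(...) {
  args <- list(nx = 96L, ny = 64L, n_steps = 20000L, record_every = 500L,
               sched_every = 250L, snapshot_every = 2000L)
  do.call(germline_params, utils::modifyList(args, list(...)))
}

## independent equality-constrained least squares via KKT system
kkt_constrained_fit <- function(tt, y) {
  u <- tt / 36
  V <- outer(u, 0:6, `^`)
  C <- rbind(c(0, 1, 0, 0, 0, 0, 0), c(0, 1, 2, 3, 4, 5, 6))
  A <- rbind(cbind(2 * crossprod(V), t(C)),
             cbind(C, matrix(0, 2, 2)))
  b <- c(2 * crossprod(V, y), 0, 0)
  solve(A, b)[1:7]
}

polygon_area_of <- function(p) eggchamber:::polygon_area(p)
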