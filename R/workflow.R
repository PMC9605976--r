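## Orchestration: configured, seeded, logged runs of the full pipeline
## (generate -> measure -> embed -> stats and simulate -> readout).
## The package's functions are the primary interface; `run_workflow()`
## provides the one-command configured entry point and
## `inst/cli/eggchamber.R` a thin command-line wrapper over it.

#' Run a configured workflow step
#'
#' Dispatches on \code{config$command}: \code{generate} (cohort CSVs),
#' \code{measure} (alias of generate, kept for symmetry), \code{embed}
#' (PCA + UMAP coordinates), \code{stats} (genotype comparison against a
#' control cohort), \code{simulate-fc}, \code{simulate-germline}
#' (scenario runs with readout CSVs), or \code{report} (summary of a
#' generated cohort).  Every run writes a config echo
#' (\code{config_echo.json}) and a log with package version and seeds;
#' outputs are deterministic given the seed.
#'
#' @param config named list (or path to a YAML file) with at least
#'   \code{command}, \code{out} (output directory) and \code{seed};
#'   remaining entries are command-specific parameter blocks (see the
#'   package vignette).
#' @return invisibly, a named list of artifact paths.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cmd <- config$command %||% stopf("config must name a command")
  out <- config$out %||% stopf("config must name an output directory")
  seed <- as.integer(config$seed %||% 0L)
  known <- c("generate", "measure", "embed", "stats", "simulate-fc",
             "simulate-germline", "report")
  if (!cmd %in% known)
    stopf("unknown command '%s' (expected one of %s)", cmd,
          paste(known, collapse = ", "))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(out, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  t0 <- Sys.time()
  paths <- switch(cmd,
    generate = , measure = wf_generate(config, out, seed),
    embed = wf_embed(config, out, seed),
    stats = wf_stats(config, out, seed),
    `simulate-fc` = wf_sim_fc(config, out, seed),
    `simulate-germline` = wf_sim_germline(config, out, seed),
    report = wf_report(config, out, seed))
  log <- c(sprintf("command: %s", cmd), sprintf("seed: %d", seed),
           sprintf("package: eggchamber %s",
                   as.character(utils::packageVersion("eggchamber"))),
           sprintf("elapsed_s: %.2f",
                   as.numeric(Sys.time() - t0, units = "secs")),
           sprintf("artifact: %s", unlist(paths)))
  writeLines(log, file.path(out, "run_log.txt"))
  invisible(paths)
}

wf_config <- function(config, seed) {
  gc <- config$generator %||% list()
  gc$seed <- seed
  do.call(generator_config, gc)
}

wf_generate <- function(config, out, seed) {
  cohort <- generate_cohort(wf_config(config, seed))
  write_cohort(cohort, out)
}

wf_embed <- function(config, out, seed) {
  cohort <- generate_cohort(wf_config(config, seed))
  rec <- measure_cohort(cohort)
  z <- standardize(rec, "wt_alone")
  pc <- pca_select(z, config$cumvar_threshold %||% 0.90)
  emb <- umap_embed(pc, germline_area = rec$germline_area,
                    n_neighbors = config$n_neighbors %||% 15L,
                    min_dist = config$min_dist %||% 0.2, seed = seed)
  df <- data.frame(id = rec$id, UMAP_1 = emb$umap_xy[, 1L],
                   UMAP_2 = emb$umap_xy[, 2L], phase = rec$phase,
                   genotype = rec$genotype,
                   germline_area = rec$germline_area,
                   trajectory_rank = rank(emb$geodesic))
  p1 <- file.path(out, "embedding.csv")
  write.csv(df, p1, row.names = FALSE)
  p2 <- file.path(out, "embedding_params.json")
  jsonlite::write_json(c(emb$params, list(k = emb$k,
                                          cumvar = emb$cumvar[emb$k])),
                       p2, auto_unbox = TRUE, digits = NA)
  list(embedding = p1, params = p2)
}

wf_stats <- function(config, out, seed) {
  cfg_ctl <- wf_config(config, seed)
  gc_mut <- config$generator %||% list()
  gc_mut$seed <- seed + 1L
  gc_mut$genotype <- config$mutant %||% "mirr_eya"
  ctl <- measure_cohort(generate_cohort(cfg_ctl))
  mut <- measure_cohort(generate_cohort(do.call(generator_config, gc_mut)))
  pooled <- rbind(ctl, mut)
  response <- config$response %||% "prop_fc_on_oocyte"
  cmpg <- compare_genotypes(pooled, response)
  res <- data.frame(term = names(cmpg$coefficients),
                    estimate = unname(cmpg$coefficients),
                    p_value = unname(cmpg$p_values[names(cmpg$coefficients)]))
  p1 <- file.path(out, "genotype_comparison.csv")
  write.csv(res, p1, row.names = FALSE)
  info <- list(response = response, used_interaction = cmpg$used_interaction,
               interaction_p = cmpg$interaction_p, n = cmpg$n,
               formula = if (cmpg$used_interaction)
                 "Y ~ germline_size + genotype + germline_size:genotype"
               else "Y ~ germline_size + genotype")
  p2 <- file.path(out, "genotype_comparison.json")
  jsonlite::write_json(info, p2, auto_unbox = TRUE, digits = NA)
  list(comparison = p1, info = p2)
}

wf_sim_fc <- function(config, out, seed) {
  sc <- scenario(config$scenario %||% "wt")
  st <- init_fc(n_cells = config$n_cells %||% 14L,
                affine_fraction = config$affine_fraction %||% 0.6,
                seed = seed,
                params = do.call(fc_params, config$params %||% list()))
  tr <- evolve_fc(st, sc)
  ro <- readout_fc(tr)
  p1 <- file.path(out, "fc_contacts.csv")
  write.csv(ro$contact_lengths, p1, row.names = FALSE)
  p2 <- file.path(out, "fc_readout.json")
  jsonlite::write_json(list(scenario = sc$name,
                            n_on_affine = ro$n_on_affine,
                            on_affine = which(ro$on_affine),
                            detached = ro$detached),
                       p2, auto_unbox = TRUE, digits = NA)
  list(contacts = p1, readout = p2)
}

wf_sim_germline <- function(config, out, seed) {
  sc <- scenario(config$scenario %||% "germline_wt")
  st <- init_germline(seed = seed,
                      params = do.call(germline_params,
                                       config$params %||% list()))
  tr <- evolve_germline(st, sc)
  ro <- readout_germline(tr)
  p1 <- file.path(out, "germline_angle.csv")
  write.csv(ro$angles, p1, row.names = FALSE)
  p2 <- file.path(out, "germline_series.csv")
  write.csv(ro$series, p2, row.names = FALSE)
  list(angles = p1, series = p2)
}

wf_report <- function(config, out, seed) {
  cohort <- generate_cohort(wf_config(config, seed))
  rec <- measure_cohort(cohort)
  ph <- table(factor(rec$phase, levels = 1:3))
  p1_prop <- rec$prop_fc_on_oocyte[rec$phase == 1L]
  rep_list <- list(
    n_chambers = nrow(rec),
    phase_counts = as.list(setNames(as.integer(ph), paste0("phase", 1:3))),
    phase1_contact_proportion_mean = mean(p1_prop),
    phase3_contact_proportion_mean =
      mean(rec$prop_fc_on_oocyte[rec$phase == 3L]),
    oocyte_fraction_plateau =
      mean(rec$oocyte_fraction_of_germline[rec$phase == 3L]),
    interface_angle_by_phase = lapply(split(rec$interface_angle, rec$phase),
                                      median))
  p1 <- file.path(out, "report.json")
  jsonlite::write_json(rep_list, p1, auto_unbox = TRUE, digits = NA)
  list(report = p1)
}
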