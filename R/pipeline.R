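#' Read and validate a pipeline configuration
#'
#' Configuration is YAML or JSON (by file extension). Top-level blocks:
#' `paths` (input/output file locations; `outdir` required), `filter`
#' (`min_length`, `min_abundance`, `control_max`, optional `mapping` CSV
#' path, `burnin_days`, `excluded_species`, `target_species`, `consumer`),
#' `model` (`n_chains`, `n_iter`, `n_burnin`, `seed`, flags) and `curves`
#' (`proportion`, `target_p`, `lag_day`), plus an optional `simulate`
#' block naming every generator parameter and its seed. A `weather` path,
#' if given, is echoed into the run manifest but drives no computation.
#'
#' @param path Config file path (`.yaml`, `.yml` or `.json`).
#' @return A validated config list of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json", call. = FALSE)
  validate_pipeline_config(cfg)
}

#' Validate an in-memory pipeline configuration
#'
#' @param cfg A config list (see [read_pipeline_config()]).
#' @return The config, with defaults filled in, of class
#'   `"pipeline_config"`.
#' @export
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$paths$outdir))
    stop("config error: paths$outdir is required", call. = FALSE)
  defaults <- list(
    filter = list(min_length = 80L, min_abundance = 10L, control_max = 10L,
                  burnin_days = 3L,
                  excluded_species = "Meleagris gallopavo",
                  consumer = "Acinonyx jubatus"),
    model = list(n_chains = 3L, n_iter = 20000L, n_burnin = 5000L,
                 thin = 1L, hierarchical = TRUE, random_effect = TRUE,
                 monitor_alpha = FALSE),
    curves = list(proportion = 0.5, target_p = 0.5, lag_day = 1L))
  for (block in names(defaults)) {
    for (key in names(defaults[[block]]))
      if (is.null(cfg[[block]][[key]]))
        cfg[[block]][[key]] <- defaults[[block]][[key]]
  }
  if (cfg$model$n_iter <= cfg$model$n_burnin)
    stop("config error: model$n_iter must exceed model$n_burnin",
         call. = FALSE)
  for (p in setdiff(names(cfg$paths), "outdir")) {
    if (!is.null(cfg$paths[[p]]) && !file.exists(cfg$paths[[p]]) &&
        !p %in% c("detections", "model_input", "draws"))
      stop("config error: paths$", p, " does not exist: ", cfg$paths[[p]],
           call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_path <- function(cfg, name, default) {
  p <- cfg$paths[[name]]
  if (is.null(p)) file.path(cfg$paths$outdir, default) else p
}

log_stage <- function(manifest, stage, ...) {
  info <- list(...)
  message("[", stage, "] ",
          paste(names(info), unlist(lapply(info, format)), sep = "=",
                collapse = " "))
  manifest[[stage]] <- info
  manifest
}

#' Run the analysis pipeline
#'
#' Chains the stages `simulate` (synthetic schedule, detections and read
#' tables), `filter` (length/abundance filter, taxon reassignment,
#' presence calling against controls, burn-in exclusion), `build` (lagged
#' covariates), `fit` (MCMC), `summarize` (posterior and convergence
#' reports) and `curves` (detection curves and the meal-proportion
#' inversion). `"all"` runs every configured stage in order. Each stage is
#' a pure file-to-file transform below `paths$outdir`; inputs are never
#' modified, every stochastic stage logs its seed, and a machine-readable
#' run manifest (`run_manifest.json`) accumulates row counts, dropped
#' record tallies, acceptance rates and the Rhat summary.
#'
#' @param config A `pipeline_config` (or path to one).
#' @param stage One of `"simulate"`, `"filter"`, `"build"`, `"fit"`,
#'   `"summarize"`, `"curves"`, `"all"`.
#' @return The run-manifest list, invisibly.
#' @export
run_pipeline <- function(config, stage = "all") {
  stage <- match.arg(stage, c("simulate", "filter", "build", "fit",
                              "summarize", "curves", "all"))
  cfg <- if (is.character(config)) read_pipeline_config(config) else
    validate_pipeline_config(unclass(config))
  out <- cfg$paths$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c(if (!is.null(cfg$simulate)) "simulate", "filter", "build", "fit",
      "summarize", "curves")
  } else stage
  manifest <- list(config = unclass(cfg))

  for (st in stages) {
    manifest <- switch(st,
      simulate = stage_simulate(cfg, out, manifest),
      filter = stage_filter(cfg, out, manifest),
      build = stage_build(cfg, out, manifest),
      fit = stage_fit(cfg, out, manifest),
      summarize = stage_summarize(cfg, out, manifest),
      curves = stage_curves(cfg, out, manifest))
  }
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(manifest)
}

stage_simulate <- function(cfg, out, manifest) {
  sim <- cfg$simulate
  if (is.null(sim)) stop("config error: no `simulate` block", call. = FALSE)
  if (is.null(sim$seed))
    stop("config error: simulate$seed is required", call. = FALSE)
  sched <- generate_feeding_schedule(
    n_days = sim$n_days, individuals = sim$individuals,
    species = sim$species,
    max_species_per_day = sim$max_species_per_day %||% length(sim$species),
    seed = sim$seed,
    start_date = sim$start_date %||% "2017-11-03")
  params <- do.call(true_parameters,
                    c(list(species = sim$species), sim$true_params))
  start <- as.Date(sim$start_date %||% "2017-11-03")
  scat_days <- start + seq(3L, sim$n_days - 1L)
  det <- simulate_detections(sched, params, scat_days,
                             sim$degradation_days %||% c(0, 3, 5, 12, 15,
                                                         20, 27, 48, 60),
                             seed = sim$seed + 1L)
  rt <- simulate_read_table(
    det, consumer_fraction = sim$consumer_fraction %||% 0.54,
    mean_depth = sim$mean_depth %||% 10000,
    control_contamination_rate = sim$control_contamination_rate %||% 0,
    seed = sim$seed + 2L, consumer = cfg$filter$consumer,
    short_read_fraction = sim$short_read_fraction %||% 0)
  write_table_csv(sched, file.path(out, "schedule.csv"))
  write_table_csv(det, file.path(out, "detections_true.csv"))
  write_table_csv(rt$reads, file.path(out, "reads.csv"))
  write_table_csv(rt$controls, file.path(out, "controls.csv"))
  write_table_csv(rt$subsamples, file.path(out, "subsamples.csv"))
  log_stage(manifest, "simulate", seed = sim$seed,
            schedule_rows = nrow(sched), detection_rows = nrow(det),
            read_rows = nrow(rt$reads), control_rows = nrow(rt$controls))
}

stage_filter <- function(cfg, out, manifest) {
  f <- cfg$filter
  reads <- read_read_table(pipeline_path(cfg, "reads", "reads.csv"))
  controls <- read_control_table(pipeline_path(cfg, "controls",
                                               "controls.csv"))
  subs <- read_subsample_info(pipeline_path(cfg, "subsamples",
                                            "subsamples.csv"))
  sched <- read_feeding_schedule(pipeline_path(cfg, "schedule",
                                               "schedule.csv"))
  target_species <- f$target_species %||% sort(subs_species(reads,
                                                            f$consumer))
  mapping <- if (!is.null(f$mapping))
    utils::read.csv(f$mapping, stringsAsFactors = FALSE) else
      default_taxon_mapping()
  mapping <- mapping[mapping$target %in% c(target_species, f$consumer), ,
                     drop = FALSE]

  filtered <- filter_reads(reads, f$min_length, f$min_abundance)
  reassigned <- reassign_taxa(filtered, mapping, target_species,
                              f$consumer)
  det <- call_presence(reassigned, controls, f$control_max, target_species,
                       f$consumer, subsample_info = subs)
  det <- exclude_burnin_scats(det, sched, f$burnin_days,
                              f$excluded_species)
  write_table_csv(det, file.path(out, "detections.csv"))
  excl <- list(reassign = attr(reassigned, "exclusions"),
               burnin = attr(det, "exclusions"))
  jsonlite::write_json(excl, file.path(out, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_stage(manifest, "filter", rows_in = nrow(reads),
            rows_after_filter = nrow(filtered),
            rows_after_reassign = nrow(reassigned),
            detection_rows = nrow(det))
}

# target species = every taxon in the read table except the consumer;
# used only when the config does not name them
subs_species <- function(reads, consumer) {
  setdiff(unique(reads$taxon), consumer)
}

stage_build <- function(cfg, out, manifest) {
  det <- read_detection_matrix(pipeline_path(cfg, "detections",
                                             "detections.csv"))
  sched <- read_feeding_schedule(pipeline_path(cfg, "schedule",
                                               "schedule.csv"))
  input <- build_model_input(det, sched)
  write_table_csv(input$data, file.path(out, "model_input.csv"))
  jsonlite::write_json(
    list(species = as.list(stats::setNames(seq_along(input$species),
                                           input$species)),
         scats = as.list(stats::setNames(seq_along(input$scats),
                                         input$scats)),
         individuals = input$individuals),
    file.path(out, "index_map.json"), auto_unbox = TRUE)
  log_stage(manifest, "build", rows = input$n_rows,
            species = input$n_species, scats = input$n_scats)
}

stage_fit <- function(cfg, out, manifest) {
  mcfg <- cfg$model
  if (is.null(mcfg$seed))
    stop("config error: model$seed is required", call. = FALSE)
  rows <- utils::read.csv(pipeline_path(cfg, "model_input",
                                        "model_input.csv"),
                          stringsAsFactors = FALSE)
  input <- model_input_from_rows(rows)
  draws <- run_mcmc(input, n_chains = mcfg$n_chains, n_iter = mcfg$n_iter,
                    n_burnin = mcfg$n_burnin, seed = mcfg$seed,
                    thin = mcfg$thin, hierarchical = mcfg$hierarchical,
                    random_effect = mcfg$random_effect,
                    monitor_alpha = mcfg$monitor_alpha)
  write_posterior_draws(draws, file.path(out, "draws.csv"))
  log_stage(manifest, "fit", seed = mcfg$seed, chains = mcfg$n_chains,
            iterations = mcfg$n_iter, burnin = mcfg$n_burnin,
            acceptance = round(mean(draws$acceptance_rates), 3))
}

stage_summarize <- function(cfg, out, manifest) {
  draws <- read_posterior_draws(pipeline_path(cfg, "draws", "draws.csv"))
  summ <- summarize_posterior(draws)
  conv <- gelman_rubin(draws)
  write_table_csv(summ, file.path(out, "posterior_summary.csv"))
  jsonlite::write_json(summ, file.path(out, "posterior_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(
    list(rhat = as.list(conv$rhat), ess = as.list(conv$ess),
         converged = conv$converged, threshold = conv$threshold),
    file.path(out, "convergence.json"), auto_unbox = TRUE, digits = NA)
  if (draws$hierarchical)
    write_table_csv(main_effect_summary(draws),
                    file.path(out, "main_effects.csv"))
  log_stage(manifest, "summarize", parameters = nrow(summ),
            max_rhat = round(max(conv$rhat), 4), converged = conv$converged)
}

stage_curves <- function(cfg, out, manifest) {
  draws <- read_posterior_draws(pipeline_path(cfg, "draws", "draws.csv"))
  ccfg <- cfg$curves
  curves <- do.call(rbind, lapply(draws$species, function(sp) {
    cv <- species_detection_vs_day(draws, sp, ccfg$proportion)
    cbind(species = sp, as.data.frame(cv))
  }))
  write_table_csv(curves, file.path(out, "detection_curves.csv"))
  inv <- tryCatch(
    proportion_for_target_probability(draws, species = NULL,
                                      lag_day = ccfg$lag_day,
                                      target_p = ccfg$target_p),
    error = function(e) list(error = conditionMessage(e)))
  jsonlite::write_json(unclass(inv), file.path(out,
                                               "proportion_for_target.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_stage(manifest, "curves", species = length(draws$species),
            proportion = ccfg$proportion, target_p = ccfg$target_p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
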