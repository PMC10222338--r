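#' Default pipeline configuration
#'
#' The full set of recognized configuration keys with their defaults; user
#' configs are validated against this schema and merged over it.
#'
#' @return A nested list.
#' @export
pipeline_defaults <- function() {
  list(
    name = "run",
    seed = 1,
    system = list(kind = "harmonic", k_low = 1, k_high = 4, offset = 0,
                  kT = 0.6, path = NULL),
    equilibrate = list(n_equil_steps = 2000L, n_prod_steps = 8000L,
                       save_every = 40L, n_replicates = 4L),
    select = list(stride = 1L),
    switch = list(schedule = "L1", n_steps = 500L,
                  directions = c("forward", "backward")),
    estimate = list(methods = c("jar", "cro"))
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

validate_pipeline_config <- function(cfg) {
  known <- names(pipeline_defaults())
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stopf("validation error: unknown config section(s): %s",
          paste(extra, collapse = ", "))
  # validates the schedule label before any compute
  schedule_preset(cfg$switch$schedule, total_fs = cfg$switch$n_steps)
  if (!all(cfg$switch$directions %in% c("forward", "backward")))
    stopf("validation error: directions must be 'forward' and/or 'backward'")
  if (!all(cfg$estimate$methods %in% c("jar", "cro")))
    stopf("validation error: estimate methods must be 'jar' and/or 'cro'")
  invisible(cfg)
}

config_system <- function(cfg) {
  s <- cfg$system
  if (!is.null(s$path)) return(read_system(s$path))
  if (identical(s$kind, "harmonic")) {
    th <- if (!is.null(s$kT)) thermo_state_kT(s$kT) else thermo_state(s$temperature)
    make_harmonic_pair(s$k_low, s$k_high, offset = s$offset, thermo = th)
  } else if (identical(s$kind, "polar_solute_64rotors")) {
    polar_solute_system()
  } else {
    stopf("validation error: unknown inline system kind '%s'", s$kind)
  }
}

#' Run the switching workflow end-to-end
#'
#' Executes equilibrate, select-starts, switch and estimate stages in
#' dependency order, writing all artifacts (restart pools, work tables,
#' estimates, a report and a run manifest with full seed provenance) to
#' `out_dir`.  Re-running with the same configuration and seed reproduces
#' the scientific artifacts bit-identically.
#'
#' @param config Path to a YAML configuration file or a configuration list
#'   (see [pipeline_defaults()] for the schema).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the estimates and artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  t0 <- Sys.time()
  system <- config_system(cfg)
  beta <- system$thermo$beta
  seeds <- list(equilibrate_fwd = child_seed(cfg$seed, "pipeline-eq", 0),
                equilibrate_bwd = child_seed(cfg$seed, "pipeline-eq", 1),
                switch_fwd = child_seed(cfg$seed, "pipeline-sw", 0),
                switch_bwd = child_seed(cfg$seed, "pipeline-sw", 1))

  eq <- cfg$equilibrate
  paths <- list()
  works <- list()
  sched <- schedule_preset(cfg$switch$schedule, total_fs = cfg$switch$n_steps)
  for (dir in cfg$switch$directions) {
    lam <- if (dir == "forward") 0 else 1
    tag <- if (dir == "forward") "fwd" else "bwd"
    st <- sampler_settings(n_equil_steps = eq$n_equil_steps,
                           n_prod_steps = eq$n_prod_steps,
                           save_every = eq$save_every,
                           n_replicates = eq$n_replicates,
                           seed = seeds[[paste0("equilibrate_", tag)]])
    pool <- sample_equilibrium(system, lam, st)
    pool_path <- file.path(out_dir, sprintf("pool_%s.jsonl", dir))
    write_pool(pool, pool_path)
    starts <- select_switch_starts(pool, cfg$select$stride)
    sw <- switch_settings(n_switch_steps = cfg$switch$n_steps,
                          schedule = sched, direction = dir,
                          seed = seeds[[paste0("switch_", tag)]])
    wt <- run_switch_ensemble(system, starts, sw)
    wt_path <- file.path(out_dir, sprintf("works_%s.tsv", dir))
    write_work_table(wt, wt_path)
    works[[dir]] <- wt
    paths[[paste0("pool_", dir)]] <- pool_path
    paths[[paste0("works_", dir)]] <- wt_path
  }

  estimates <- list()
  if ("jar" %in% cfg$estimate$methods) {
    if (is.null(works$forward))
      stopf("dependency error: stage 'estimate jar' requires forward switches")
    estimates$jar <- jarzynski(as_work_sample(works$forward, beta),
                               seed = child_seed(cfg$seed, "pipeline-boot", 0))
  }
  if ("cro" %in% cfg$estimate$methods) {
    if (is.null(works$forward) || is.null(works$backward))
      stopf("dependency error: stage 'estimate cro' requires forward and backward switches")
    estimates$cro <- two_sided(as_work_sample(works$forward, beta),
                               as_work_sample(works$backward, beta),
                               seed = child_seed(cfg$seed, "pipeline-boot", 1))
  }
  for (m in names(estimates)) {
    p <- file.path(out_dir, sprintf("estimate_%s.json", m))
    write_estimate(estimates[[m]], p)
    paths[[paste0("estimate_", m)]] <- p
  }

  report <- list(name = cfg$name, beta = beta,
                 analytic_delta_a = system$analytic_delta_a)
  for (m in names(estimates)) {
    report[[paste0("delta_a_", m)]] <- estimates[[m]]$delta_a
    report[[paste0("stderr_", m)]] <- estimates[[m]]$stderr
    if (!is.null(system$analytic_delta_a))
      report[[paste0("delta_delta_a_", m)]] <-
        delta_delta_a(estimates[[m]]$delta_a, system$analytic_delta_a)
  }
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths$report <- report_path

  manifest <- list(
    command = "run_pipeline",
    config = cfg,
    config_path = config_path,
    config_md5 = if (!is.null(config_path)) unname(tools::md5sum(config_path))
                 else NA_character_,
    master_seed = cfg$seed,
    child_seeds = seeds,
    artifacts = paths,
    package_version = as.character(packageVersion("neqswitch")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(estimates = estimates, report = report, paths = paths,
                 manifest = manifest))
}
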