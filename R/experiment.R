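# Experiment configuration, artifact management and the programmatic entry
# point behind the command-line interface.

# Fletcher-32 checksum of the serialized object; a stable fingerprint that
# ties artifacts to the exact resolved configuration.
.config_hash <- function(obj) {
  raw <- serialize(obj, NULL, version = 2)
  b <- as.integer(raw)
  a <- 0; c2 <- 0
  for (i in seq_along(b)) {
    a <- (a + b[i]) %% 65535
    c2 <- (c2 + a) %% 65535
  }
  sprintf("%04x%04x", c2, a)
}

#' Assemble an experiment configuration
#'
#' Bundles a task, a search space and the outer-loop settings into a single
#' validated object that fully determines a run (together with nothing
#' else): every artifact is reproducible from the configuration alone.
#'
#' @param task A [stability_task()] or [familiarity_task()].
#' @param space Search-space label.
#' @param seed Master seed.
#' @param mode `"meta_learn"` (optimize a rule) or `"evaluate"` (score a
#'   saved rule over randomized trials).
#' @param max_iter,popsize,sigma0,n_trials,stop_loss,snapshot_iters Outer
#'   loop settings, see [run_meta_learning()].
#' @param frozen_seed Frozen-layer seed (MLP space).
#' @param rule_files Character vector of rule JSON paths (`"evaluate"`
#'   mode; one per plastic block).
#' @param out_dir Output directory for artifacts (`NULL`: return results
#'   only).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(task, space = "small_poly", seed = 1,
                              mode = c("meta_learn", "evaluate"),
                              max_iter = 40, popsize = NULL, sigma0 = 0.3,
                              n_trials = NULL, stop_loss = 0.05,
                              snapshot_iters = c(10, 15, 20),
                              frozen_seed = 42L, rule_files = NULL,
                              out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(task, "task_spec"))
  theta_length(space) # validates the space label
  if (mode == "evaluate" && is.null(rule_files))
    stop("evaluate mode requires rule_files")
  structure(list(task = task, space = space, seed = as.integer(seed),
                 mode = mode, max_iter = max_iter, popsize = popsize,
                 sigma0 = sigma0,
                 n_trials = if (is.null(n_trials)) task$n_trials
                            else n_trials,
                 stop_loss = stop_loss, snapshot_iters = snapshot_iters,
                 frozen_seed = as.integer(frozen_seed),
                 rule_files = rule_files, out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The file holds a `task:` mapping (fields of [stability_task()] /
#' [familiarity_task()], including `kind:`) plus any of the top-level
#' fields of [experiment_config()].  Unknown fields raise an error rather
#' than being silently ignored.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$task) || is.null(y$task$kind))
    stop("config must contain a task mapping with a 'kind' field")
  kind <- y$task$kind
  maker <- switch(kind, stability = stability_task,
                  familiarity = familiarity_task,
                  stop("unknown task kind: ", kind))
  targs <- y$task; targs$kind <- NULL
  unknown <- setdiff(names(targs), names(formals(maker)))
  if (length(unknown) > 0)
    stop("unknown task fields: ", paste(unknown, collapse = ", "))
  task <- do.call(maker, targs)
  top <- y; top$task <- NULL
  known <- setdiff(names(formals(experiment_config)), "task")
  unknown <- setdiff(names(top), known)
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(experiment_config, c(list(task = task), top))
}

# resolved config as plain lists for the YAML dump
.config_as_list <- function(cfg) {
  lst <- unclass(cfg)
  lst$task <- unclass(cfg$task)
  lst
}

#' Run an experiment and write its artifacts
#'
#' In `"meta_learn"` mode runs the full outer loop and writes the
#' per-iteration trajectory (`trajectory.csv`), the learned rule(s)
#' (`best_rule_<block>.json`), covariance snapshots
#' (`covariance_iter<k>.csv`), the resolved configuration
#' (`resolved_config.yaml`) and a manifest with the configuration hash
#' (`manifest.json`).  In `"evaluate"` mode scores saved rules over the
#' task's randomized trials and writes `trials.csv`.  All outputs are a
#' pure function of the configuration (including its master seed).
#'
#' @param config An [experiment_config()] or the path to a YAML file.
#' @param verbose Print progress.
#' @return The `meta_result` (meta-learn) or per-trial data frame
#'   (evaluate), invisibly; attribute `files` lists written artifacts.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$out_dir
  files <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    files <<- c(files, path)
    path
  }
  if (!is.null(out_dir) &&
      !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (config$mode == "meta_learn") {
    res <- run_meta_learning(
      task = config$task, space = config$space, seed = config$seed,
      max_iter = config$max_iter, popsize = config$popsize,
      n_trials = config$n_trials, sigma0 = config$sigma0,
      stop_loss = config$stop_loss,
      snapshot_iters = config$snapshot_iters,
      frozen_seed = config$frozen_seed, verbose = verbose)
    if (!is.null(out_dir)) {
      write.csv(res$trajectory, emit("trajectory.csv"), row.names = FALSE)
      for (nm in names(res$best_rule))
        write_rule(res$best_rule[[nm]],
                   emit(sprintf("best_rule_%s.json", nm)),
                   bounds = config$task$bounds)
      for (it in names(res$snapshots))
        write.csv(res$snapshots[[it]],
                  emit(sprintf("covariance_iter%s.csv", it)),
                  row.names = FALSE)
      yaml::write_yaml(.config_as_list(config), emit("resolved_config.yaml"))
      jsonlite::write_json(
        list(config_hash = .config_hash(.config_as_list(config)),
             seed = config$seed, space = config$space,
             iterations = nrow(res$trajectory),
             frozen_seed = config$frozen_seed,
             package_version = as.character(
               utils::packageVersion("metaplast"))),
        emit("manifest.json"), auto_unbox = TRUE, digits = NA)
    }
    attr(res, "files") <- files
    return(invisible(res))
  }

  # evaluate mode
  rules <- lapply(config$rule_files, read_rule)
  theta <- unlist(lapply(rules, encode_theta))
  loss <- evaluate_candidate(theta, config$space, config$task,
                             n_trials = config$n_trials,
                             seed_base = config$seed,
                             frozen_seed = config$frozen_seed)
  trials <- attr(loss, "trials")
  trials$mean_loss <- as.numeric(loss)
  if (!is.null(out_dir)) {
    write.csv(trials, emit("trials.csv"), row.names = FALSE)
    yaml::write_yaml(.config_as_list(config), emit("resolved_config.yaml"))
  }
  attr(trials, "files") <- files
  invisible(trials)
}
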