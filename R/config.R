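# Run configuration and result serialization: YAML config in, tidy CSV out.
# A config echo plus the package version is written next to the tables so a
# run can be reproduced bit-identically.

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration, validates it and merges it with the
#' documented defaults. Recognised top-level keys: `experiment`, `group`,
#' `condition`, `n_repeats`, `master_seed`, `record_steps`, `output_dir` and
#' `params` (a named block of [wm_params()] overrides). Unknown keys, an
#' invalid experiment/group pair, or a missing seed raise descriptive
#' errors.
#'
#' @param path config file path.
#' @return a validated named list (class `wm_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("experiment", "group", "condition", "n_repeats", "master_seed",
             "record_steps", "output_dir", "params")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (is.null(cfg$experiment)) stop("config must name an experiment (I-VI)")
  if (!cfg$experiment %in% c("I", "II", "III", "IV", "V", "VI")) {
    stop("unknown experiment: ", cfg$experiment)
  }
  if (is.null(cfg$master_seed)) stop("config must set master_seed")
  cfg$group <- cfg$group %||% "DP"
  if (!cfg$group %in% c("DP", "D", "P", "DL", "L", "chance")) {
    stop("unknown group: ", cfg$group)
  }
  if (cfg$experiment == "VI" && is.null(cfg$condition)) {
    stop("experiment VI requires a condition")
  }
  cfg$n_repeats <- cfg$n_repeats %||% 50
  cfg$record_steps <- cfg$record_steps %||% "probe"
  cfg$output_dir <- cfg$output_dir %||% "."
  cfg$params <- do.call(wm_params, c(list(), cfg$params))
  structure(cfg, class = "wm_config")
}

#' Write a configuration back to YAML
#'
#' @param cfg a config list.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17)
  invisible(path)
}

#' Run an experiment from a configuration
#'
#' @param cfg a [load_config()] result (or a path to one).
#' @return the [run_experiment()] result.
#' @export
run_config <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  run_experiment(cfg$experiment, cfg$group, cfg$condition,
                 n_repeats = cfg$n_repeats, master_seed = cfg$master_seed,
                 params = cfg$params, record_steps = cfg$record_steps)
}

#' Write an experiment result as tidy CSV tables
#'
#' Writes `trials.csv`, `selection.csv`, optional `steps.csv`, a
#' `summary.csv` (per-session group means) and `config.yaml` (the echo that
#' reproduces the run) into `outdir`.
#'
#' @param x a [run_experiment()] result.
#' @param outdir output directory (created if missing).
#' @param steps write the per-timestep table?
#' @return the output directory, invisibly.
#' @export
write_results <- function(x, outdir, steps = !is.null(x$steps)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$trials, file.path(outdir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(selection_rates(x, by = c("session", "tag")),
                   file.path(outdir, "selection.csv"), row.names = FALSE)
  if (steps && !is.null(x$steps)) {
    utils::write.csv(x$steps, file.path(outdir, "steps.csv"),
                     row.names = FALSE)
  }
  lat <- escape_latencies(x, by = "session")
  summ <- dplyr::summarise(
    dplyr::group_by(lat, .data$session),
    mean_latency = mean(.data$latency),
    se_latency = stats::sd(.data$latency) / sqrt(dplyr::n()),
    .groups = "drop")
  utils::write.csv(summ, file.path(outdir, "summary.csv"), row.names = FALSE)
  cfg <- list(experiment = x$experiment, group = x$group,
              condition = x$condition, n_repeats = x$n_repeats,
              master_seed = x$master_seed, record_steps = "probe",
              params = x$params)
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"), precision = 17)
  invisible(outdir)
}
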