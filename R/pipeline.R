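#' Pipeline run configuration
#'
#' A single top-level seed drives every stochastic stage (each stage
#' derives a fixed offset substream). The configuration round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param seed Integer seed for the whole pipeline.
#' @param experiment `"exp1"` (immediate target decision) or `"exp2"`
#'   (delayed; identical generative structure here, kept as a label).
#' @param n_participants Number of synthetic participants.
#' @param trials_per_participant Main-task trials per participant
#'   (multiple of 72 when using two sessions).
#' @param observer Named list of group-level generating parameters
#'   (`w_choice`, `w_conf`, `b`, optional `sd_log`, `sigma`).
#' @param models Character vector of model variants to fit/compare.
#' @param sampler Named list: `chains`, `iter`, `warmup`.
#' @param out_dir Output directory for all stage files.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, experiment = c("exp1", "exp2"),
                       n_participants = 8, trials_per_participant = 360,
                       observer = list(w_choice = 2.17, w_conf = 1.27,
                                       b = 2.18, sd_log = 0.3, sigma = 0.23),
                       models = c("flexible", "flat_prior", "optimal",
                                  "equal"),
                       sampler = list(chains = 2, iter = 400, warmup = 400),
                       out_dir = "priorconf_run") {
  experiment <- match.arg(experiment)
  if (n_participants < 1) stop("invalid config field: n_participants")
  if (trials_per_participant %% 36 != 0)
    stop("invalid config field: trials_per_participant (multiple of 36)")
  bad <- setdiff(models, c("flexible", "flat_prior", "optimal", "equal"))
  if (length(bad)) stop("invalid config field: models (", bad[1], ")")
  structure(list(seed = as.integer(seed), experiment = experiment,
                 n_participants = as.integer(n_participants),
                 trials_per_participant = as.integer(trials_per_participant),
                 observer = observer, models = models, sampler = sampler,
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # hash the scientific config, not its destination
  s <- yaml::as.yaml(cfg)
  # small rolling content hash (hex); stable across sessions
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stage_header <- function(config, stage) {
  c(sprintf("# priorconf stage=%s seed=%d config=%s", stage, config$seed,
            config_hash(config)))
}

write_stage_table <- function(df, config, stage, file) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, file)
  writeLines(stage_header(config, stage), path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, append = TRUE))
  path
}

read_stage_table <- function(config, file) {
  path <- file.path(config$out_dir, file)
  if (!file.exists(path)) stop("missing stage file: ", path)
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#",
                                      stringsAsFactors = FALSE))
}

# stage substreams derived from the single top-level seed
stage_seed <- function(config, stage) {
  offs <- c(simulate = 11L, calibrate = 23L, fit = 37L, compare = 53L,
            recover = 71L)
  (config$seed * 101L + offs[[stage]]) %% .Machine$integer.max
}

#' Pipeline stages
#'
#' Thin orchestration over the package's functions: each stage reads its
#' inputs from the configured output directory, writes delimited text
#' results with a header carrying the stage, seed and config hash, and
#' logs participant/trial counts. The pipeline is resumable stage by stage
#' from the files alone.
#'
#' @param config A [run_config()].
#' @return Invisibly, the written file path(s) (or the result object for
#'   `pipeline_compare()` / `pipeline_recover()`).
#' @export
pipeline_simulate <- function(config) {
  n_main <- config$trials_per_participant
  sessions <- if (n_main %% 72 == 0) 2 else 1
  design <- experiment_design(sessions = sessions,
                              n_blocks = n_main / (36 * sessions))
  cohort <- with_seed_if(stage_seed(config, "simulate"),
    draw_cohort_params(config$n_participants,
                       group = config$observer[c("w_choice", "w_conf", "b")],
                       sd_log = config$observer$sd_log %||% 0.3,
                       sigma = config$observer$sigma %||% 0.23))
  ds <- generate_dataset(cohort, design = design,
                         seed = stage_seed(config, "simulate"))
  p1 <- write_stage_table(ds$main, config, "simulate", "main_trials.tsv")
  p2 <- write_stage_table(ds$control, config, "simulate",
                          "control_trials.tsv")
  yaml::write_yaml(ds$manifest, file.path(config$out_dir, "manifest.yaml"))
  message(sprintf("[simulate] %d participants, %d main + %d control trials",
                  config$n_participants, nrow(ds$main), nrow(ds$control)))
  invisible(c(p1, p2))
}

#' @rdname pipeline_simulate
#' @export
pipeline_calibrate <- function(config) {
  main <- read_stage_table(config, "main_trials.tsv")
  control <- read_stage_table(config, "control_trials.tsv")
  calib <- with_seed_if(stage_seed(config, "calibrate"),
                        calibrate_participants(main, control))
  path <- write_stage_table(calib, config, "calibrate", "calibration.tsv")
  message(sprintf("[calibrate] %d participants", nrow(calib)))
  invisible(path)
}

#' @rdname pipeline_simulate
#' @export
pipeline_fit <- function(config) {
  main <- read_stage_table(config, "main_trials.tsv")
  calib <- read_stage_table(config, "calibration.tsv")
  trials <- normalize_dataset(main, calib)
  sm <- config$sampler
  out <- list()
  for (m in config$models) {
    fit <- suppressWarnings(
      fit_hierarchical(trials, model_spec(m),
                       seed = stage_seed(config, "fit"),
                       chains = sm$chains, iter = sm$iter,
                       warmup = sm$warmup))
    summ <- fit$summary
    summ$model <- m
    summ$flagged <- !fit$converged
    out[[m]] <- summ
    write_stage_table(tibble::as_tibble(as.data.frame(fit$draws)), config,
                      "fit", sprintf("draws_%s.tsv", m))
    if (!fit$converged)
      message(sprintf("[fit] %s flagged: split R-hat >= 1.1", m))
  }
  tab <- dplyr::bind_rows(out)
  path <- write_stage_table(tab, config, "fit", "fit_summaries.tsv")
  write_run_config(config, file.path(config$out_dir, "run_config_used.yaml"))
  message(sprintf("[fit] %d models fit to %d trials", length(config$models),
                  nrow(trials)))
  invisible(path)
}

#' @rdname pipeline_simulate
#' @export
pipeline_compare <- function(config) {
  main <- read_stage_table(config, "main_trials.tsv")
  calib <- read_stage_table(config, "calibration.tsv")
  trials <- normalize_dataset(main, calib)
  sm <- config$sampler
  specs <- lapply(config$models, model_spec)
  holdout <- if (config$n_participants >= 20) 2 else 1
  cv <- logo_cv(trials, specs,
                n_folds = config$n_participants / holdout,
                holdout_size = holdout,
                seed = stage_seed(config, "compare"),
                chains = sm$chains, iter = sm$iter, warmup = sm$warmup)
  path <- write_stage_table(cv$table, config, "compare", "elpd.tsv")
  message(sprintf("[compare] %d models over %d folds", length(specs),
                  max(cv$folds)))
  invisible(cv)
}

#' @rdname pipeline_simulate
#' @param n_observers Number of synthetic observers for the recovery run.
#' @export
pipeline_recover <- function(config, n_observers = 6) {
  grid <- with_seed_if(stage_seed(config, "recover"), tibble::tibble(
    w_choice = exp(runif(n_observers, log(0.5), log(4))),
    w_conf = exp(runif(n_observers, log(0.5), log(4))),
    b = exp(runif(n_observers, log(0.5), log(3)))))
  rec <- parameter_recovery_study(grid,
                                  trials_per_obs = config$trials_per_participant,
                                  seed = stage_seed(config, "recover"),
                                  chains = config$sampler$chains,
                                  iter = config$sampler$iter,
                                  warmup = config$sampler$warmup)
  path <- write_stage_table(rec$table, config, "recover", "recovery.tsv")
  write_stage_table(rec$metrics, config, "recover", "recovery_metrics.tsv")
  message(sprintf("[recover] %d observers", n_observers))
  invisible(rec)
}

#' @rdname pipeline_simulate
#' @export
pipeline_summarize <- function(config) {
  main <- read_stage_table(config, "main_trials.tsv")
  main$target_correct <- as.logical(main$target_correct)
  summ <- condition_summaries(main)
  p1 <- write_stage_table(summ$accuracy, config, "summarize",
                          "summary_accuracy.tsv")
  p2 <- write_stage_table(summ$confidence, config, "summarize",
                          "summary_confidence.tsv")
  invisible(c(p1, p2))
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `calibrate`, `fit`, `compare`, `recover` or
#' `summarize` with a YAML config; used by the installed
#' `cli/priorconf.R` script.
#'
#' @param args Character vector, e.g. `c("simulate", "--config", "run.yaml")`.
#' @return Invisibly, the stage result.
#' @export
priorconf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1)
    stop("usage: priorconf <simulate|calibrate|fit|compare|recover|summarize> --config <yaml>")
  stage <- args[1]
  ci <- which(args == "--config")
  if (length(ci) != 1 || ci == length(args))
    stop("--config <yaml> is required")
  config <- read_run_config(args[ci + 1])
  fn <- switch(stage,
               simulate = pipeline_simulate, calibrate = pipeline_calibrate,
               fit = pipeline_fit, compare = pipeline_compare,
               recover = pipeline_recover, summarize = pipeline_summarize,
               stop("unknown subcommand: ", stage))
  invisible(fn(config))
}
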