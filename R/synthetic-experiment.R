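#' Generate a complete synthetic dual-decision dataset
#'
#' Simulates the full experiment for a cohort of observers: per session a
#' control task of single prior-free decisions at six fixed coherences,
#' followed by the counterbalanced dual-decision main task with live
#' staircases (medium level 2-down-1-up, high level 3-down-1-up, low level
#' yoked 5 coherence points below medium; staircases update on lead
#' decisions of the matching level and carry over across sessions).
#'
#' @param params_list List of [observer_params()], one per participant
#'   (names become participant ids; otherwise `P01`, `P02`, ...).
#' @param design An [experiment_design()].
#' @param seed Optional integer seed; the same seed regenerates identical
#'   tables.
#' @param dropout Fraction of main-task trials to drop at random
#'   (robustness hook emulating trial exclusions; default 0).
#' @return A list of class `pc_dataset` with `main` and `control` tibbles
#'   and a `manifest` recording generating parameters, design and seed.
#' @examples
#' ds <- generate_dataset(list(observer_params(w_choice = 2)),
#'                        design = experiment_design(sessions = 1, n_blocks = 2),
#'                        seed = 1)
#' table(ds$main$condition)
#' @export
generate_dataset <- function(params_list, design = experiment_design(),
                             seed = NULL, dropout = 0) {
  stopifnot(is.list(params_list), length(params_list) >= 1,
            all(vapply(params_list, inherits, TRUE, "observer_params")),
            inherits(design, "experiment_design"))
  ids <- names(params_list)
  if (is.null(ids))
    ids <- sprintf("P%02d", seq_along(params_list))
  with_seed_if(seed, {
    main <- list(); control <- list()
    for (j in seq_along(params_list)) {
      pj <- params_list[[j]]
      sim <- .simulate_participant(ids[j], pj, design)
      main[[j]] <- sim$main
      control[[j]] <- sim$control
    }
    main <- dplyr::bind_rows(main)
    control <- dplyr::bind_rows(control)
    if (dropout > 0) {
      keep <- runif(nrow(main)) >= dropout
      main <- main[keep, ]
    }
    manifest <- list(
      seed = if (is.null(seed)) NA else as.integer(seed),
      dropout = dropout,
      participants = setNames(lapply(params_list, unclass), ids),
      design = unclass(design))
    structure(list(main = main, control = control, manifest = manifest),
              class = "pc_dataset")
  })
}

.simulate_participant <- function(id, params, design) {
  sc_M <- staircase_new("two_down_one_up",
                        coherence = design$staircase_start[["M"]],
                        step = design$staircase_step,
                        bounds = design$staircase_bounds)
  sc_H <- staircase_new("three_down_one_up",
                        coherence = design$staircase_start[["H"]],
                        step = design$staircase_step,
                        bounds = design$staircase_bounds)
  sc_L <- staircase_new("yoked_minus_5pts", coherence = 0.10,
                        bounds = design$staircase_bounds)
  sc_L <- staircase_yoke(sc_L, sc_M$coherence)
  fam <- match(params$metacog_noise_family,
               c("none", "gaussian", "lognormal")) - 1L

  main_rows <- list(); control_rows <- list()
  n_main <- design$n_blocks * design$trials_per_block
  for (sess in seq_len(design$sessions)) {
    # --- control task: single prior-free decisions ---
    coh <- rep(design$control_coherences, each = design$control_trials_per_level)
    coh <- sample(coh)
    dir <- ifelse(runif(length(coh)) < 0.5, -1L, 1L)
    s <- (dir * coh - params$bias) / params$sigma
    r <- rnorm(length(coh), s, 1)
    choice <- ifelse(r > 0, 1L, -1L)
    lapse_flip <- runif(length(coh)) < params$lapse
    choice[lapse_flip] <- ifelse(runif(sum(lapse_flip)) < 0.5, 1L, -1L)
    control_rows[[sess]] <- tibble::tibble(
      participant = id, session = sess, trial = seq_along(coh),
      dir = dir, coh = coh, choice = choice, correct = choice == dir)

    # --- main task with live staircases ---
    sched <- build_design(n_main, design$trials_per_block)
    coh_of <- function(lv) switch(lv, L = sc_L$coherence,
                                  M = sc_M$coherence, H = sc_H$coherence)
    rows <- vector("list", n_main)
    for (t in seq_len(n_main)) {
      lv1 <- sched$lead_level[t]; lv2 <- sched$target_level[t]
      coh1 <- coh_of(lv1); coh2 <- coh_of(lv2)
      tr <- cpp_simulate_trials(sched$lead_dir[t], coh1, coh2,
                                params$sigma, params$bias, params$w_choice,
                                params$w_conf, params$b, params$lapse,
                                params$metacog_noise_sd, fam,
                                params$report_noise_sd)
      # lead decisions drive the staircases (prior-free decisions)
      if (lv1 == "M") {
        sc_M <- staircase_update(sc_M, tr$lead_correct[1])
        sc_L <- staircase_yoke(sc_L, sc_M$coherence)
      } else if (lv1 == "H") {
        sc_H <- staircase_update(sc_H, tr$lead_correct[1])
      }
      rows[[t]] <- list(coh1 = coh1, coh2 = coh2, tr = tr)
    }
    main_rows[[sess]] <- tibble::tibble(
      participant = id, session = sess, block = sched$block,
      trial = sched$trial,
      posterior_level = sched$posterior_level, condition = sched$condition,
      lead_level = sched$lead_level, target_level = sched$target_level,
      lead_dir = sched$lead_dir,
      lead_coh = vapply(rows, function(x) x$coh1, 0),
      target_coh = vapply(rows, function(x) x$coh2, 0),
      target_dir = vapply(rows, function(x) x$tr$target_dir[1], 0L),
      lead_choice = vapply(rows, function(x) x$tr$lead_choice[1], 0L),
      target_choice = vapply(rows, function(x) x$tr$target_choice[1], 0L),
      lead_correct = vapply(rows, function(x) x$tr$lead_correct[1], TRUE),
      target_correct = vapply(rows, function(x) x$tr$target_correct[1], TRUE),
      conf_report = vapply(rows, function(x) x$tr$conf_report[1], 0),
      r_lead = vapply(rows, function(x) x$tr$r_lead[1], 0),
      r_target = vapply(rows, function(x) x$tr$r_target[1], 0),
      conf_model = vapply(rows, function(x) x$tr$conf_model[1], 0))
  }
  list(main = dplyr::bind_rows(main_rows),
       control = dplyr::bind_rows(control_rows))
}

#' Write / read trial tables and the parameter manifest
#'
#' Trial tables are plain tab-separated text with a header row; the
#' manifest is YAML recording the generating parameters and seed.
#'
#' @param dataset A `pc_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `write_dataset()` returns the paths invisibly; `read_trials()`
#'   returns a tibble.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(main = file.path(dir, "main_trials.tsv"),
             control = file.path(dir, "control_trials.tsv"),
             manifest = file.path(dir, "manifest.yaml"))
  utils::write.table(dataset$main, paths["main"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$control, paths["control"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  yaml::write_yaml(dataset$manifest, paths["manifest"])
  invisible(paths)
}

#' @rdname write_dataset
#' @param path Path to a delimited trial table.
#' @param mapping Optional named character vector mapping canonical column
#'   names (names) to the columns in the file (values), for reading
#'   externally deposited trial data through the same downstream code.
#'   Confidence columns on a 50-100 scale are rescaled to `[0.5, 1]`.
#' @param sep Field separator (default tab; use "," for CSV deposits).
#' @export
read_trials <- function(path, mapping = NULL, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    missing <- setdiff(unname(mapping), names(raw))
    if (length(missing))
      stop("columns not found in file: ", paste(missing, collapse = ", "))
    raw <- raw[unname(mapping)]
    names(raw) <- names(mapping)
  }
  out <- tibble::as_tibble(raw)
  if ("conf_report" %in% names(out) && max(out$conf_report, na.rm = TRUE) > 1.5)
    out$conf_report <- out$conf_report / 100
  out
}
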