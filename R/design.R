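#' Experiment design settings
#'
#' The dual-decision design: three stimulus levels (L, M, H) combine into
#' three posterior-information levels, each tested in a Stronger-Lead and a
#' Stronger-Target condition. Level pairs are
#' `L_post = {M+L, L+M}`, `M_post = {H+L, L+H}`, `H_post = {H+M, M+H}`
#' (lead + target; the first member of each pair is Stronger-Lead).
#'
#' @param sessions Number of sessions (default 2).
#' @param n_blocks Blocks per session (default 10).
#' @param trials_per_block Trials per block (default 36).
#' @param control_trials_per_level Control-task trials per coherence level
#'   per session (default 15, i.e. 30 across two sessions).
#' @param control_coherences The six fixed control-task coherences.
#' @param staircase_start Named starting coherences for the medium and high
#'   staircases.
#' @param staircase_step Staircase step size (coherence units).
#' @param staircase_bounds Coherence bounds for the staircases.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(sessions = 2, n_blocks = 10,
                              trials_per_block = 36,
                              control_trials_per_level = 15,
                              control_coherences = c(0.05, 0.10, 0.12, 0.15, 0.20, 0.30),
                              staircase_start = c(M = 0.15, H = 0.25),
                              staircase_step = 0.01,
                              staircase_bounds = c(0.01, 0.90)) {
  stopifnot(sessions >= 1, n_blocks >= 1, trials_per_block %% 6 == 0)
  structure(list(sessions = sessions, n_blocks = n_blocks,
                 trials_per_block = trials_per_block,
                 control_trials_per_level = control_trials_per_level,
                 control_coherences = control_coherences,
                 staircase_start = staircase_start,
                 staircase_step = staircase_step,
                 staircase_bounds = staircase_bounds),
            class = "experiment_design")
}

# posterior level x condition -> (lead level, target level)
.pc_cells <- tibble::tribble(
  ~posterior_level, ~condition,        ~lead_level, ~target_level,
  "L",              "stronger_lead",   "M",         "L",
  "L",              "stronger_target", "L",         "M",
  "M",              "stronger_lead",   "H",         "L",
  "M",              "stronger_target", "L",         "H",
  "H",              "stronger_lead",   "H",         "M",
  "H",              "stronger_target", "M",         "H")

#' Build a counterbalanced trial schedule
#'
#' Within every block the six (posterior level x condition) cells appear
#' equally often and lead directions are balanced within each cell; trial
#' order is shuffled.
#'
#' @param n_trials_total Total number of trials; must be divisible by
#'   `trials_per_block`.
#' @param trials_per_block Block size (default 36; must be divisible by 6,
#'   with cell counts divisible by 2 for direction balance).
#' @param seed Optional integer seed for the shuffle.
#' @return Tibble with `trial`, `block`, `posterior_level`, `condition`,
#'   `lead_level`, `target_level`, `lead_dir`.
#' @export
build_design <- function(n_trials_total, trials_per_block = 36, seed = NULL) {
  if (n_trials_total %% trials_per_block != 0)
    stop("n_trials_total must be divisible by trials_per_block")
  per_cell <- trials_per_block / 6
  if (per_cell %% 1 != 0) stop("trials_per_block must be divisible by 6")
  n_blocks <- n_trials_total / trials_per_block
  with_seed_if(seed, {
    blocks <- lapply(seq_len(n_blocks), function(bl) {
      cell <- .pc_cells[rep(seq_len(6), each = per_cell), ]
      # balance lead direction within cell where possible
      dirs <- rep_len(c(1L, -1L), per_cell)
      cell$lead_dir <- as.vector(vapply(seq_len(6), function(i) sample(dirs),
                                        integer(per_cell)))
      cell <- cell[sample.int(nrow(cell)), ]
      cell$block <- bl
      cell
    })
    out <- dplyr::bind_rows(blocks)
    out$trial <- seq_len(nrow(out))
    dplyr::select(out, trial, block, posterior_level, condition,
                  lead_level, target_level, lead_dir)
  })
}
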