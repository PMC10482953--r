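#' Adaptive staircase state
#'
#' Transformed up-down staircases for coherence. The 2-down-1-up rule
#' converges to about 70.7% correct, the 3-down-1-up rule to about 79.4%;
#' the yoked rule tracks another staircase 5 coherence points lower.
#'
#' @param rule One of `"two_down_one_up"`, `"three_down_one_up"`,
#'   `"yoked_minus_5pts"`.
#' @param coherence Starting coherence.
#' @param step Step size in coherence units (default 0.01, i.e. one
#'   percentage point).
#' @param bounds Length-2 vector of coherence bounds.
#' @return A `staircase_state` list.
#' @export
staircase_new <- function(rule = c("two_down_one_up", "three_down_one_up",
                                   "yoked_minus_5pts"),
                          coherence = 0.15, step = 0.01,
                          bounds = c(0.01, 0.90)) {
  rule <- match.arg(rule)
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2], step > 0)
  coherence <- clamp(coherence, bounds[1], bounds[2])
  structure(list(rule = rule, coherence = coherence,
                 consecutive_correct = 0L, step = step, bounds = bounds),
            class = "staircase_state")
}

#' Update a staircase after one decision
#'
#' N-down-1-up: the coherence steps down (harder) after N consecutive
#' correct responses and up after any error; the consecutive-correct
#' counter resets after any step. Yoked staircases are not updated by
#' decisions (see [staircase_yoke()]).
#'
#' @param state A `staircase_state`.
#' @param correct Logical; was the decision correct?
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  if (state$rule == "yoked_minus_5pts") return(state)
  n_down <- if (state$rule == "two_down_one_up") 2L else 3L
  if (isTRUE(correct)) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= n_down) {
      state$coherence <- max(state$coherence - state$step, state$bounds[1])
      state$consecutive_correct <- 0L
    }
  } else {
    state$coherence <- min(state$coherence + state$step, state$bounds[2])
    state$consecutive_correct <- 0L
  }
  state
}

#' Yoke a staircase 5 coherence points below a reference
#'
#' @param state A `staircase_state` with rule `"yoked_minus_5pts"`.
#' @param reference_coherence Coherence of the staircase being tracked.
#' @return The updated state, floored at the lower bound.
#' @export
staircase_yoke <- function(state, reference_coherence) {
  stopifnot(inherits(state, "staircase_state"),
            state$rule == "yoked_minus_5pts")
  state$coherence <- max(reference_coherence - 0.05, state$bounds[1])
  state
}

#' Run a staircase against a simulated observer
#'
#' Drives an N-down-1-up staircase with single prior-free decisions from an
#' observer with the given psychometric function
#' (`P(correct | coh) = Phi(coh / sigma)` for an unbiased observer with
#' stimulus directions balanced), and returns the trial-by-trial record.
#'
#' @param state A `staircase_state`.
#' @param n_trials Number of trials to run.
#' @param sigma Internal noise of the simulated observer.
#' @param bias Decision bias of the simulated observer.
#' @param seed Optional integer seed.
#' @return Tibble with `trial`, `coherence`, `dir`, `correct`.
#' @export
staircase_run <- function(state, n_trials, sigma = 0.1, bias = 0,
                          seed = NULL) {
  stopifnot(inherits(state, "staircase_state"), n_trials >= 1)
  with_seed_if(seed, {
    coh <- numeric(n_trials); dir <- integer(n_trials)
    correct <- logical(n_trials)
    for (t in seq_len(n_trials)) {
      coh[t] <- state$coherence
      dir[t] <- if (runif(1) < 0.5) -1L else 1L
      s <- (dir[t] * coh[t] - bias) / sigma
      r <- rnorm(1, s, 1)
      choice <- if (r > 0) 1L else -1L
      correct[t] <- choice == dir[t]
      state <- staircase_update(state, correct[t])
    }
    tibble::tibble(trial = seq_len(n_trials), coherence = coh,
                   dir = dir, correct = correct)
  })
}
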