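#' Observer parameters for the dual-decision model
#'
#' Bundles the generative (or fitted) parameters of one observer. Weighting
#' parameters scale the *perceived variance* of the prior: a value of 1 is
#' the optimal observer, values above 1 underweight the prior (its variance
#' is overestimated), values below 1 overweight it.
#'
#' @param w_choice Positive scalar; prior-variance scaling in the target
#'   decision. 1 = optimal.
#' @param w_conf Positive scalar; prior-variance scaling in the confidence
#'   computation. 1 = optimal.
#' @param b Positive scalar; confidence bias. Scales the perceived variance
#'   of both prior and likelihood in confidence: `b > 1` compresses
#'   confidence toward 50%, `b < 1` inflates it.
#' @param sigma Positive scalar; internal noise in stimulus (coherence)
#'   units. The default 0.23 reproduces typical staircased lead accuracies
#'   (about 63/71/79% at the low/medium/high levels).
#' @param bias Scalar decision bias in stimulus units (positive = leftward
#'   criterion shift, i.e. a rightward response bias).
#' @param lapse Probability in `[0, 0.5]` that a choice is replaced by a
#'   fair coin flip.
#' @param metacog_noise_sd Non-negative scalar; SD of metacognitive noise
#'   applied to the internal responses entering the confidence computation
#'   (first-order choices are unaffected).
#' @param metacog_noise_family `"none"`, `"gaussian"` (additive on r) or
#'   `"lognormal"` (multiplicative on |r|).
#' @param report_noise_sd Non-negative scalar; SD of truncated-Gaussian
#'   report noise on the `[0.5, 1]` confidence scale.
#'
#' @return An object of class `observer_params` (a validated named list).
#' @examples
#' observer_params()                      # the optimal observer
#' observer_params(w_choice = 3)          # underweights the prior in choices
#' @export
observer_params <- function(w_choice = 1, w_conf = 1, b = 1,
                            sigma = 0.23, bias = 0, lapse = 0,
                            metacog_noise_sd = 0,
                            metacog_noise_family = c("none", "gaussian", "lognormal"),
                            report_noise_sd = 0.08) {
  metacog_noise_family <- match.arg(metacog_noise_family)
  stopifnot(is.numeric(w_choice), length(w_choice) == 1,
            is.numeric(w_conf), length(w_conf) == 1,
            is.numeric(b), length(b) == 1,
            is.numeric(sigma), length(sigma) == 1)
  if (w_choice <= 0) stop("w_choice must be > 0")
  if (w_conf <= 0) stop("w_conf must be > 0")
  if (b <= 0) stop("b must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (lapse < 0 || lapse > 0.5) stop("lapse must be in [0, 0.5]")
  if (metacog_noise_sd < 0) stop("metacog_noise_sd must be >= 0")
  if (report_noise_sd < 0) stop("report_noise_sd must be >= 0")
  structure(list(w_choice = w_choice, w_conf = w_conf, b = b,
                 sigma = sigma, bias = bias, lapse = lapse,
                 metacog_noise_sd = metacog_noise_sd,
                 metacog_noise_family = metacog_noise_family,
                 report_noise_sd = report_noise_sd),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf("  w_choice = %.3g, w_conf = %.3g, b = %.3g\n",
              x$w_choice, x$w_conf, x$b))
  cat(sprintf("  sigma = %.3g, bias = %.3g, lapse = %.3g\n",
              x$sigma, x$bias, x$lapse))
  if (x$metacog_noise_family != "none")
    cat(sprintf("  metacognitive noise: %s, sd = %.3g\n",
                x$metacog_noise_family, x$metacog_noise_sd))
  cat(sprintf("  report_noise_sd = %.3g\n", x$report_noise_sd))
  invisible(x)
}

#' Stimulus specification
#'
#' @param direction -1 (leftward) or +1 (rightward) coherent motion.
#' @param coherence Motion coherence, strictly in (0, 1).
#' @param level Optional level label, one of `"L"`, `"M"`, `"H"`.
#' @return A `stimulus_spec` list.
#' @export
stimulus_spec <- function(direction, coherence, level = NA_character_) {
  if (!direction %in% c(-1, 1)) stop("direction must be -1 or +1")
  if (!is.numeric(coherence) || coherence <= 0 || coherence >= 1)
    stop("coherence must be strictly in (0, 1)")
  if (!is.na(level) && !level %in% c("L", "M", "H"))
    stop("level must be 'L', 'M' or 'H'")
  structure(list(direction = direction, coherence = coherence, level = level),
            class = "stimulus_spec")
}
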