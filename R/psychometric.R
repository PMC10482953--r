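#' Fit one psychometric-function variant
#'
#' Maximum-likelihood fit of
#' `P(right | x) = lapse/2 + (1 - lapse) * Phi((x - bias) / sigma)`
#' to prior-free decisions, where `x` is the signed coherence. Variants fix
#' absent parameters at 0: `noise_only` (sigma), `noise_bias` (sigma,
#' bias), `noise_lapse` (sigma, lapse), `noise_bias_lapse` (all three).
#' Bounded quasi-Newton (L-BFGS-B) from five jittered starts; the best is
#' reported.
#'
#' @param decisions Data frame with columns `x` (signed coherence) and
#'   `chose_right` (logical or 0/1).
#' @param variant Which variant to fit.
#' @param n_starts Number of jittered optimizer starts.
#' @return A `psychometric_fit` list with `sigma`, `bias`, `lapse`,
#'   `loglik`, `aic`, `variant`, `n`.
#' @export
fit_psychometric <- function(decisions,
                             variant = c("noise_only", "noise_bias",
                                         "noise_lapse", "noise_bias_lapse"),
                             n_starts = 5) {
  variant <- match.arg(variant)
  x <- decisions$x
  y <- as.numeric(decisions$chose_right)
  if (length(unique(abs(x))) < 2)
    stop("need at least 2 distinct coherence magnitudes")
  if (all(y == 1) || all(y == 0))
    stop("degenerate data: all decisions in the same category")
  has_bias <- variant %in% c("noise_bias", "noise_bias_lapse")
  has_lapse <- variant %in% c("noise_lapse", "noise_bias_lapse")

  nll <- function(par) {
    sigma <- exp(par[1])
    bias <- if (has_bias) par[2] else 0
    lapse <- if (has_lapse) par[length(par)] else 0
    p <- lapse / 2 + (1 - lapse) * pnorm((x - bias) / sigma)
    p <- clamp(p, 1e-12, 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  lower <- c(log(1e-4)); upper <- c(log(10))
  start <- c(log(max(sd(x), 0.05)))
  if (has_bias) { lower <- c(lower, -0.5); upper <- c(upper, 0.5); start <- c(start, 0) }
  if (has_lapse) { lower <- c(lower, 0); upper <- c(upper, 0.5); start <- c(start, 0.02) }

  best <- NULL
  for (i in seq_len(n_starts)) {
    st <- start
    if (i > 1) {
      st[1] <- st[1] + rnorm(1, 0, 0.5)
      if (has_bias) st[2] <- st[2] + rnorm(1, 0, 0.05)
      if (has_lapse) st[length(st)] <- clamp(st[length(st)] + rnorm(1, 0, 0.05), 0, 0.4)
    }
    fit <- tryCatch(
      optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed for variant ", variant)
  k <- length(best$par)
  par <- best$par
  structure(list(variant = variant,
                 sigma = exp(par[1]),
                 bias = if (has_bias) par[2] else 0,
                 lapse = if (has_lapse) par[length(par)] else 0,
                 loglik = -best$value,
                 aic = 2 * k + 2 * best$value,
                 n = length(y)),
            class = "psychometric_fit")
}

#' Akaike-weighted combination of the four psychometric variants
#'
#' Weights `w_i` are proportional to `exp(-dAIC_i / 2)` and normalized to
#' sum to 1; combined parameters are weight-averaged, with parameters
#' absent from a variant entering as 0.
#'
#' @param fits List of four `psychometric_fit` objects fit to the same
#'   data.
#' @return A list with combined `sigma`, `bias`, `lapse`, the `weights`,
#'   and the per-variant fits.
#' @export
akaike_combine <- function(fits) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "psychometric_fit")))
  aic <- vapply(fits, `[[`, 0, "aic")
  w <- exp(-(aic - min(aic)) / 2)
  w <- w / sum(w)
  comb <- function(fld) sum(w * vapply(fits, `[[`, 0, fld))
  list(sigma = comb("sigma"), bias = comb("bias"), lapse = comb("lapse"),
       weights = setNames(w, vapply(fits, `[[`, "", "variant")),
       fits = fits)
}

#' Calibrate internal noise and decision bias per participant
#'
#' Pools each participant's prior-free decisions (the control task plus the
#' lead decision of every main-task trial), fits the four psychometric
#' variants and combines them by Akaike weights.
#'
#' @param main Main-task trial tibble (or `NULL` to calibrate from control
#'   data only).
#' @param control Control-task tibble.
#' @return Tibble with one row per participant: `sigma`, `bias`, `lapse`
#'   and the four Akaike weights.
#' @export
calibrate_participants <- function(main, control) {
  ids <- unique(control$participant)
  if (!is.null(main)) ids <- union(ids, unique(main$participant))
  rows <- lapply(ids, function(id) {
    ctrl <- control[control$participant == id, ]
    if (nrow(ctrl) == 0)
      stop("missing control data for participant ", id)
    dec <- tibble::tibble(x = ctrl$dir * ctrl$coh,
                          chose_right = ctrl$choice == 1)
    if (!is.null(main)) {
      mm <- main[main$participant == id, ]
      dec <- dplyr::bind_rows(dec,
        tibble::tibble(x = mm$lead_dir * mm$lead_coh,
                       chose_right = mm$lead_choice == 1))
    }
    fits <- lapply(c("noise_only", "noise_bias", "noise_lapse",
                     "noise_bias_lapse"),
                   function(v) fit_psychometric(dec, v))
    cmb <- akaike_combine(fits)
    tibble::tibble(participant = id, sigma = cmb$sigma, bias = cmb$bias,
                   lapse = cmb$lapse,
                   w_noise_only = cmb$weights[["noise_only"]],
                   w_noise_bias = cmb$weights[["noise_bias"]],
                   w_noise_lapse = cmb$weights[["noise_lapse"]],
                   w_noise_bias_lapse = cmb$weights[["noise_bias_lapse"]])
  })
  dplyr::bind_rows(rows)
}

#' Attach normalized stimulus strengths to a trial table
#'
#' Adds `s_lead` and `s_target` (signed strengths in internal-noise units)
#' using each participant's calibrated `sigma` and `bias`, so that internal
#' noise is 1 in all downstream model code.
#'
#' @param trials Main-task trial tibble.
#' @param calibration Calibration tibble from [calibrate_participants()],
#'   or a single-row list with `sigma` and `bias` applied to everyone.
#' @return The trial tibble with `s_lead` and `s_target` columns.
#' @export
normalize_dataset <- function(trials, calibration) {
  if (is.data.frame(calibration)) {
    idx <- match(trials$participant, calibration$participant)
    if (anyNA(idx)) stop("calibration missing for some participants")
    sigma <- calibration$sigma[idx]; bias <- calibration$bias[idx]
  } else {
    sigma <- calibration$sigma; bias <- calibration$bias
  }
  if (any(sigma <= 0)) stop("sigma must be > 0")
  trials$s_lead <- (trials$lead_dir * trials$lead_coh - bias) / sigma
  trials$s_target <- (trials$target_dir * trials$target_coh - bias) / sigma
  trials
}
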