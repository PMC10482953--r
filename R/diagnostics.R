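#' Split R-hat convergence diagnostic
#'
#' Classic split-\eqn{\widehat{R}}: each chain is split in half and the
#' between/within variance ratio is computed across the resulting
#' half-chains. Values near 1 indicate convergence; fits are flagged when
#' any parameter exceeds 1.1.
#'
#' @param chains List of numeric vectors (one per chain, equal length) or
#'   a list of matrices (draws x parameters).
#' @return A scalar (vector input) or named vector (matrix input).
#' @export
split_rhat <- function(chains) {
  if (is.matrix(chains[[1]])) {
    p <- ncol(chains[[1]])
    out <- vapply(seq_len(p), function(j)
      split_rhat(lapply(chains, function(m) m[, j])), 0)
    names(out) <- colnames(chains[[1]])
    return(out)
  }
  halves <- list()
  for (ch in chains) {
    n <- length(ch); h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h)], ch[(n - h + 1):n]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W < 1e-12) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via Geyer's initial positive sequence on the
# pooled, per-chain-centered draws.
ess_basic <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  centered <- lapply(chains, function(x) x - mean(x))
  acfs <- sapply(centered, function(x)
    as.numeric(stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE,
                          demean = FALSE)$acf))
  rho <- rowMeans(acfs)
  tot <- 0
  t <- 2
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tot <- tot + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * tot)
  max(1, min(ess, m * n))
}

# Posterior summaries: mean, sd, MCSE of the mean, 89% equal-tailed CI,
# split R-hat.
summarize_chains <- function(chains_mat_list, natural = identity) {
  pnames <- colnames(chains_mat_list[[1]])
  rows <- lapply(seq_along(pnames), function(j) {
    raw <- lapply(chains_mat_list, function(m) m[, j])
    nat <- lapply(raw, natural)
    all_nat <- unlist(nat)
    ess <- ess_basic(nat)
    tibble::tibble(parameter = pnames[j],
                   mean = mean(all_nat), sd = sd(all_nat),
                   mcse = sd(all_nat) / sqrt(ess),
                   ci89_lower = unname(quantile(all_nat, 0.055)),
                   ci89_upper = unname(quantile(all_nat, 0.945)),
                   ess = ess,
                   rhat = split_rhat(raw))
  })
  dplyr::bind_rows(rows)
}
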