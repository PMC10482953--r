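#' Model variant specification
#'
#' The four observer-model variants: `flexible` frees `w_choice`, `w_conf`
#' and `b`; `flat_prior` fixes the rightward prior at exactly 0.5 (the lead
#' stimulus is ignored) and frees only `b`; `optimal` fixes
#' `w_choice = w_conf = 1` and frees `b`; `equal` forces
#' `w_choice = w_conf = w` and frees `w` and `b`. All variants additionally
#' fit a report-noise SD.
#'
#' @param name One of `"flexible"`, `"flat_prior"`, `"optimal"`, `"equal"`.
#' @return A `model_spec` list with `name`, `code`, `free` and `hier_free`.
#' @export
model_spec <- function(name = c("flexible", "flat_prior", "optimal", "equal")) {
  name <- match.arg(name)
  code <- match(name, c("flexible", "flat_prior", "optimal", "equal")) - 1L
  free <- switch(name,
    flexible = c("w_choice", "w_conf", "b", "sd_report"),
    flat_prior = c("b", "sd_report"),
    optimal = c("b", "sd_report"),
    equal = c("w", "b", "sd_report"))
  hier_free <- setdiff(free, "sd_report")
  structure(list(name = name, code = code, free = free,
                 hier_free = hier_free),
            class = "model_spec")
}

# Map trials (with s_lead, s_target) to the flat data list the C++
# likelihood code consumes. m_lead / rbar_target are the per-participant
# level-mean strengths used by the hierarchical simplification.
pc_model_data <- function(trials) {
  need <- c("participant", "s_lead", "s_target", "lead_level", "target_level",
            "target_dir", "lead_choice", "target_choice", "conf_report")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop("trials is missing columns: ", paste(missing, collapse = ", "))
  ids <- unique(trials$participant)
  part <- match(trials$participant, ids) - 1L
  # mean |s| per participant x level, separately for the lead and target
  # roles, so that models ignoring the lead stimulus stay exactly
  # invariant to it
  key_lead <- paste(trials$participant, trials$lead_level)
  key_target <- paste(trials$participant, trials$target_level)
  mu_lead <- tapply(abs(trials$s_lead), key_lead, mean)
  mu_target <- tapply(abs(trials$s_target), key_target, mean)
  list(s_lead = trials$s_lead,
       s_target = trials$s_target,
       d_lead = as.integer(trials$lead_choice),
       d_target = as.integer(trials$target_choice),
       conf = clamp(trials$conf_report, 0.5, 1),
       m_lead = as.numeric(mu_lead[key_lead]),
       rbar_target = as.integer(trials$target_dir) *
         as.numeric(mu_target[key_target]),
       part = part,
       ids = ids)
}
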