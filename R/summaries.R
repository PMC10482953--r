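#' Behaviour summaries by posterior level and condition
#'
#' Per-participant then group summaries of target accuracy and mean
#' confidence by (posterior level x condition), confidence split by target
#' accuracy, and the folded-X summary (confidence against posterior level
#' split by accuracy, collapsed over condition). Empty cells are reported
#' as missing, not zero.
#'
#' @param trials Labeled trial tibble (synthetic or read from files).
#' @return List of tibbles: `accuracy`, `confidence`, `folded`.
#' @export
condition_summaries <- function(trials) {
  per_acc <- dplyr::summarise(
    dplyr::group_by(trials, participant, posterior_level, condition),
    accuracy = mean(target_correct), n = dplyr::n(), .groups = "drop")
  acc <- dplyr::summarise(
    dplyr::group_by(per_acc, posterior_level, condition),
    mean_accuracy = mean(accuracy), sd_accuracy = sd(accuracy),
    n_participants = dplyr::n(), .groups = "drop")

  per_conf <- dplyr::summarise(
    dplyr::group_by(trials, participant, posterior_level, condition,
                    target_correct),
    confidence = mean(conf_report), n = dplyr::n(), .groups = "drop")
  conf <- dplyr::summarise(
    dplyr::group_by(per_conf, posterior_level, condition, target_correct),
    mean_confidence = mean(confidence), sd_confidence = sd(confidence),
    n_participants = dplyr::n(), .groups = "drop")

  per_fold <- dplyr::summarise(
    dplyr::group_by(trials, participant, posterior_level, target_correct),
    confidence = mean(conf_report), .groups = "drop")
  folded <- dplyr::summarise(
    dplyr::group_by(per_fold, posterior_level, target_correct),
    mean_confidence = mean(confidence), sd_confidence = sd(confidence),
    .groups = "drop")

  lv <- c("L", "M", "H")
  acc$posterior_level <- factor(acc$posterior_level, levels = lv)
  conf$posterior_level <- factor(conf$posterior_level, levels = lv)
  folded$posterior_level <- factor(folded$posterior_level, levels = lv)
  list(accuracy = dplyr::arrange(acc, posterior_level, condition),
       confidence = dplyr::arrange(conf, posterior_level, condition,
                                   target_correct),
       folded = dplyr::arrange(folded, posterior_level, target_correct))
}
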