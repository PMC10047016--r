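#' Filter a cohort down to one classification task
#'
#' For the malignant-vs-benign task, keeps benign findings (negative class)
#' and malignant findings (positive class), dropping high-risk and atypia
#' findings from the analysis. For the invasive-vs-noninvasive task, keeps
#' malignant findings only, with invasive disease as the positive class.
#' Case content is never altered, only membership.
#'
#' @param cases list of `cem_case` objects (or a metadata data.frame with
#'   `class` and `invasive_flag` columns)
#' @param task `"malignant_vs_benign"` or `"invasive_vs_noninvasive"`
#' @param include_atypia_as_benign if TRUE, atypia findings are retained in
#'   the negative class of the malignant-vs-benign task (high-risk findings
#'   are always excluded)
#' @return list with `cases` (filtered, same type as the input), `labels`
#'   (integer 0/1, positive class = 1), and `exclusion_log` (data.frame of
#'   dropped case ids and reasons)
#' @export
exclusion_filter <- function(cases, task = c("malignant_vs_benign",
                                             "invasive_vs_noninvasive"),
                             include_atypia_as_benign = FALSE) {
  task <- match.arg(task)
  is_df <- is.data.frame(cases)
  cls <- if (is_df) cases$class else
    vapply(cases, `[[`, "", "class_label")
  inv <- if (is_df) cases$invasive_flag else
    vapply(cases, function(cs) {
      v <- cs$invasive_flag
      if (is.null(v) || is.na(v)) NA else as.logical(v)
    }, NA)
  ids <- if (is_df) cases$case_id else vapply(cases, `[[`, "", "case_id")

  if (task == "malignant_vs_benign") {
    negative <- c("benign", if (include_atypia_as_benign) "atypia")
    keep <- cls %in% c(negative, "malignant")
    labels <- as.integer(cls[keep] == "malignant")
    reason <- ifelse(cls == "high_risk", "high-risk finding",
                     "atypia finding")
  } else {
    keep <- cls == "malignant"
    labels <- as.integer(inv[keep])
    reason <- rep("non-malignant finding", length(cls))
  }
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("fewer than 2 cases per class after task filtering", call. = FALSE)

  exclusion_log <- data.frame(case_id = ids[!keep],
                              class = cls[!keep],
                              reason = reason[!keep],
                              stringsAsFactors = FALSE)
  filtered <- if (is_df) cases[keep, , drop = FALSE] else cases[keep]
  list(cases = filtered, labels = labels, exclusion_log = exclusion_log)
}
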