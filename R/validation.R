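# Validation: label match results against ground truth (the stand-in for
# an external probabilistic-review pass), tabulate precision by score
# band, and choose a sharing threshold from the bands.

#' Label match results against ground truth
#'
#' @param results Match results from [run_match()].
#' @param truth Ground truth: a data frame with `cohort_id` and `person_id`
#'   (`NA` for records with no registry person), e.g. the `truth` element
#'   of [simulate_feeds()]. Every result's `cohort_id` must be covered.
#' @return `results` with a `label` column: `"true_match"` when the
#'   matched person is the true person, otherwise `"false_match"`.
#'   Ground-truth labels are never `"uncertain"`; that category exists for
#'   externally supplied labels.
#' @export
label_against_truth <- function(results, truth) {
  idx <- match(results$cohort_id, truth$cohort_id)
  if (anyNA(idx)) {
    condition_stop("linkbox_config_error",
                   sprintf("cohort_id absent from ground truth: %s",
                           paste(utils::head(results$cohort_id[is.na(idx)], 5),
                                 collapse = ", ")))
  }
  true_pid <- truth$person_id[idx]
  out <- results
  out$label <- ifelse(!is.na(true_pid) & results$person_id == true_pid,
                      "true_match", "false_match")
  out
}

#' Precision by score band
#'
#' Tabulates labeled matches per score, in descending score order, with
#' band precision and cumulative precision at or above each score.
#' Uncertain labels are excluded from precision denominators by default;
#' `uncertain_as_false = TRUE` applies the stricter review convention that
#' an unresolvable pair counts as a false match.
#'
#' @param labeled Output of [label_against_truth()] (or any results table
#'   with a `label` column in `true_match`/`false_match`/`uncertain`).
#' @param uncertain_as_false Count uncertain labels as false matches.
#' @return Data frame with columns `score`, `n`, `n_true`, `n_false`,
#'   `n_uncertain`, `precision`, `cum_n`, `cum_true`, `cum_false`,
#'   `cum_precision`, plus formatted percentage columns `precision_pct`
#'   and `cum_precision_pct` (round-half-up, one decimal).
#' @export
score_band_metrics <- function(labeled, uncertain_as_false = FALSE) {
  if (nrow(labeled) == 0)
    condition_stop("linkbox_config_error", "no labeled matches to tabulate")
  lab <- labeled$label
  if (uncertain_as_false) lab[lab == "uncertain"] <- "false_match"
  scores <- sort(unique(labeled$score), decreasing = TRUE)
  n <- n_true <- n_false <- n_unc <- integer(length(scores))
  for (i in seq_along(scores)) {
    sel <- labeled$score == scores[i]
    n[i] <- sum(sel)
    n_true[i] <- sum(sel & lab == "true_match")
    n_false[i] <- sum(sel & lab == "false_match")
    n_unc[i] <- sum(sel & lab == "uncertain")
  }
  denom <- n_true + n_false
  precision <- ifelse(denom > 0, n_true / denom, NA_real_)
  cum_true <- cumsum(n_true); cum_false <- cumsum(n_false)
  cum_denom <- cum_true + cum_false
  cum_precision <- ifelse(cum_denom > 0, cum_true / cum_denom, NA_real_)
  data.frame(
    score = scores, n = n, n_true = n_true, n_false = n_false,
    n_uncertain = n_unc, precision = precision,
    cum_n = cumsum(n), cum_true = cum_true, cum_false = cum_false,
    cum_precision = cum_precision,
    precision_pct = ifelse(denom > 0, format_pct(n_true, denom),
                           NA_character_),
    cum_precision_pct = ifelse(cum_denom > 0,
                               format_pct(cum_true, cum_denom),
                               NA_character_),
    stringsAsFactors = FALSE)
}

#' Select a sharing threshold from score-band metrics
#'
#' Returns the smallest observed score whose cumulative precision (over
#' all matches at or above it) meets the target. If no score qualifies,
#' the maximum observed score is returned with attribute
#' `warning = TRUE`.
#'
#' @param metrics Output of [score_band_metrics()].
#' @param target_precision Required cumulative precision (default 0.99).
#' @return Integer score, possibly with a `warning` attribute.
#' @export
select_threshold <- function(metrics, target_precision = 0.99) {
  if (nrow(metrics) == 0)
    condition_stop("linkbox_config_error", "empty metrics table")
  ok <- !is.na(metrics$cum_precision) &
    metrics$cum_precision >= target_precision
  if (!any(ok)) {
    out <- max(metrics$score)
    attr(out, "warning") <- TRUE
    return(out)
  }
  # metrics are in descending score order; the last qualifying row is the
  # smallest qualifying score
  metrics$score[max(which(ok))]
}
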