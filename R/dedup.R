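# Cross-site deduplication: cohort records that matched (at or above the
# sharing threshold) to the same surveillance person represent one person
# enrolled under several Cohort IDs, typically at several sites.

#' Cluster shared matches by surveillance person
#'
#' Partitions the shared (score >= threshold) match results into one
#' cluster per distinct surveillance person. The cluster count is the
#' number of unique persons after deduplication across sites.
#'
#' @param results Match results from [run_match()]; only rows with
#'   `shared = TRUE` are clustered (sub-threshold matches never merge
#'   persons).
#' @param site_map Optional data frame `cohort_id`, `site_id` (e.g. the
#'   `site_rows` of a [reconcile()] outcome) used to annotate each cluster
#'   with its enrollment sites.
#' @return Data frame sorted by `person_id` with columns `person_id`,
#'   `n_cohort_ids`, `cohort_ids` (list column, sorted), `sites` (list
#'   column of distinct site IDs) and `best_score`.
#' @export
cluster_by_person <- function(results, site_map = NULL) {
  shared <- results[results$shared, , drop = FALSE]
  if (nrow(shared) == 0) {
    return(data.frame(person_id = character(), n_cohort_ids = integer(),
                      cohort_ids = I(list()), sites = I(list()),
                      best_score = integer(), stringsAsFactors = FALSE))
  }
  if (anyDuplicated(shared$cohort_id))
    condition_stop("linkbox_key_error",
                   "multiple results for one cohort_id; run_match output expected")
  grp <- split(seq_len(nrow(shared)), shared$person_id)
  pid <- sort(names(grp), method = "radix")
  cohort_ids <- lapply(pid, function(p)
    sort(shared$cohort_id[grp[[p]]], method = "radix"))
  sites <- lapply(pid, function(p) {
    ids <- shared$cohort_id[grp[[p]]]
    if (is.null(site_map)) return(character())
    sort(unique(site_map$site_id[site_map$cohort_id %in% ids]),
         method = "radix")
  })
  data.frame(
    person_id = pid,
    n_cohort_ids = lengths(cohort_ids),
    cohort_ids = I(cohort_ids),
    sites = I(sites),
    best_score = vapply(pid, function(p) max(shared$score[grp[[p]]]), 1L),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Summarize multi-site enrollment
#'
#' @param clusters Output of [cluster_by_person()].
#' @return List with `n_unique` (number of clusters, i.e. unique persons),
#'   `n_multi` (clusters holding two or more Cohort IDs) and `histogram`
#'   (named integer vector, cluster size -> count).
#' @export
multi_site_summary <- function(clusters) {
  sizes <- clusters$n_cohort_ids
  hist <- table(factor(sizes, levels = sort(unique(sizes))))
  list(
    n_unique = nrow(clusters),
    n_multi = sum(sizes >= 2L),
    histogram = stats::setNames(as.integer(hist), names(hist))
  )
}
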