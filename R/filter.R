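# Cohort-ID filter stage: only records present in BOTH the central cohort
# file and the site files proceed to matching; the exclusive remainders
# become the two filter reports delivered to both recipients.

#' Reconcile Cohort IDs between the central file and the site files
#'
#' Computes the eligible set (Cohort IDs present in both feeds, merged into
#' one record carrying the site identifiers and the central payload) and
#' the two filter report lists. A Cohort ID enrolled at several sites
#' enters eligibility once — the first-seen site row supplies the matching
#' identifiers, all site rows are retained for per-site reporting, and
#' rows whose identifiers disagree are listed in `conflicts`.
#'
#' @param central_records Central feed records (one row per `cohort_id`).
#' @param site_records Site feed records (concatenated across sites; one
#'   row per `cohort_id` x `site_id`).
#' @return A `filter_outcome`: list with `eligible` (merged data frame,
#'   sorted by `cohort_id`), `central_only` and `site_only` (sorted
#'   character vectors), `site_rows` (all site rows for eligible IDs) and
#'   `conflicts` (data frame of cross-site identifier disagreements).
#' @export
reconcile <- function(central_records, site_records) {
  central_ids <- central_records$cohort_id
  if (anyDuplicated(central_ids))
    condition_stop("linkbox_key_error", "duplicate cohort_id in central file")
  site_key <- paste(site_records$cohort_id, site_records$site_id, sep = "\x1F")
  if (anyDuplicated(site_key))
    condition_stop("linkbox_key_error",
                   "duplicate cohort_id within one site file")
  site_ids <- unique(site_records$cohort_id)

  eligible_ids <- sort(intersect(central_ids, site_ids), method = "radix")
  central_only <- sort(setdiff(central_ids, site_ids), method = "radix")
  site_only <- sort(setdiff(site_ids, central_ids), method = "radix")

  srows <- site_records[site_records$cohort_id %in% eligible_ids, ,
                        drop = FALSE]
  # first-seen site row (input order) wins for matching identifiers
  first_rows <- srows[!duplicated(srows$cohort_id), , drop = FALSE]

  id_cols <- c("first_name", "last_name", "dob", "ssn", "birth_sex")
  dup_ids <- unique(srows$cohort_id[duplicated(srows$cohort_id)])
  conf <- character()
  for (id in dup_ids) {
    rows <- srows[srows$cohort_id == id, id_cols, drop = FALSE]
    sig <- apply(rows, 1, function(r) paste(ifelse(is.na(r), "", r),
                                            collapse = "\x1F"))
    if (length(unique(sig)) > 1L) conf <- c(conf, id)
  }
  conflicts <- data.frame(cohort_id = sort(conf, method = "radix"),
                          issue = rep("conflicting identifiers across site files",
                                      length(conf)),
                          stringsAsFactors = FALSE)

  cidx <- match(first_rows$cohort_id, central_records$cohort_id)
  central_payload <- central_records[cidx,
                                     setdiff(names(central_records), "cohort_id"),
                                     drop = FALSE]
  merged <- cbind(first_rows, central_payload)
  merged <- merged[order(merged$cohort_id, method = "radix"), , drop = FALSE]
  rownames(merged) <- NULL

  structure(list(eligible = merged, central_only = central_only,
                 site_only = site_only, site_rows = srows,
                 conflicts = conflicts),
            class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat(sprintf(paste0("<filter_outcome> eligible=%d central_only=%d ",
                     "site_only=%d conflicts=%d\n"),
              nrow(x$eligible), length(x$central_only), length(x$site_only),
              nrow(x$conflicts)))
  invisible(x)
}
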