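# The report suite. Every report exists in a recipient-specific form: the
# cohort study team may never receive protected identifiers (name, DOB,
# SSN) or the registry person identifier; the health department receives
# the full versions. Redaction is structural — identifier columns are
# simply never placed in a cohort-recipient table.

REPORT_KINDS <- c("match", "unmatched", "cohort_unmatched", "multi_site",
                  "demographics", "labs", "lab_site", "oi", "treatment",
                  "filter")

#' @rdname build_report
#' @export
recipient_values <- function() c("cohort", "health_dept")

surv_lookup <- function(surveillance_records, person_ids) {
  match(person_ids, surveillance_records$person_id)
}

#' Build one report table
#'
#' Assembles one of the report kinds from the artifacts of a linkage run,
#' redacted for the requested recipient. Identifier columns (names, DOB,
#' SSN, person ID) appear only in health-department versions; requesting
#' the treatment report for the cohort recipient is a redaction error.
#'
#' @param kind One of `"match"`, `"unmatched"`, `"cohort_unmatched"`,
#'   `"multi_site"`, `"demographics"`, `"labs"`, `"lab_site"`, `"oi"`,
#'   `"treatment"`, `"filter"`.
#' @param recipient `"cohort"` or `"health_dept"`.
#' @param inputs Named list of run artifacts. Used elements, by kind:
#'   `filter` (a [reconcile()] outcome), `results` ([run_match()] output),
#'   `surveillance` (surveillance records), `clusters`
#'   ([cluster_by_person()] output), `threshold` (integer).
#' @return A data frame (reports are plain tables, one CSV each on disk).
#' @export
build_report <- function(kind, recipient, inputs) {
  kind <- match.arg(kind, REPORT_KINDS)
  recipient <- match.arg(recipient, recipient_values())
  res <- inputs$results
  elig <- inputs$filter$eligible
  surv <- inputs$surveillance

  switch(kind,
    filter = {
      data.frame(
        cohort_id = c(inputs$filter$central_only, inputs$filter$site_only),
        missing_from = rep(c("site_files", "central_file"),
                           c(length(inputs$filter$central_only),
                             length(inputs$filter$site_only))),
        stringsAsFactors = FALSE)
    },
    match = {
      if (recipient == "cohort") {
        res[, c("cohort_id", "score"), drop = FALSE]
      } else {
        ei <- match(res$cohort_id, elig$cohort_id)
        si <- surv_lookup(surv, res$person_id)
        data.frame(
          cohort_id = res$cohort_id, person_id = res$person_id,
          score = res$score, level_description = res$level_description,
          name_source = res$name_source, tie_flag = res$tie_flag,
          cohort_first_name = elig$first_name[ei],
          cohort_last_name = elig$last_name[ei],
          cohort_dob = iso(elig$dob[ei]), cohort_ssn = elig$ssn[ei],
          cohort_birth_sex = elig$birth_sex[ei],
          surv_first_name = surv$first_name[si],
          surv_last_name = surv$last_name[si],
          surv_dob = iso(surv$dob[si]), surv_ssn = surv$ssn[si],
          surv_birth_sex = surv$birth_sex[si],
          stringsAsFactors = FALSE)
      }
    },
    unmatched = {
      ids <- sort(setdiff(elig$cohort_id, res$cohort_id), method = "radix")
      data.frame(cohort_id = ids, stringsAsFactors = FALSE)
    },
    cohort_unmatched = {
      filtered <- inputs$filter$central_only
      unmatched <- sort(setdiff(elig$cohort_id, res$cohort_id),
                        method = "radix")
      out <- data.frame(
        cohort_id = c(filtered, unmatched),
        reason = rep(c("not_in_site_files", "no_surveillance_match"),
                     c(length(filtered), length(unmatched))),
        stringsAsFactors = FALSE)
      out[order(out$cohort_id, method = "radix"), , drop = FALSE]
    },
    multi_site = {
      cl <- inputs$clusters
      multi <- cl[cl$n_cohort_ids >= 2L, , drop = FALSE]
      out <- data.frame(
        cohort_ids = vapply(multi$cohort_ids, paste, "", collapse = ";"),
        n_cohort_ids = multi$n_cohort_ids,
        sites = vapply(multi$sites, paste, "", collapse = ";"),
        stringsAsFactors = FALSE)
      if (recipient == "health_dept") {
        out <- cbind(data.frame(person_id = multi$person_id,
                                stringsAsFactors = FALSE), out)
      }
      rownames(out) <- NULL
      out
    },
    demographics = {
      shared <- res[res$shared, , drop = FALSE]
      ei <- match(shared$cohort_id, elig$cohort_id)
      si <- surv_lookup(surv, shared$person_id)
      rows <- lapply(seq_len(nrow(shared)), function(i) {
        d <- compare_demographics(elig[ei[i], , drop = FALSE],
                                  surv[si[i], , drop = FALSE])
        if (nrow(d) == 0) return(NULL)
        cbind(data.frame(cohort_id = shared$cohort_id[i],
                         stringsAsFactors = FALSE), d)
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (!length(rows)) {
        return(data.frame(cohort_id = character(), field = character(),
                          cohort_value = character(),
                          surveillance_value = character(),
                          kind = character(), stringsAsFactors = FALSE))
      }
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    },
    labs = {
      lab_report(res, elig, surv)
    },
    lab_site = {
      shared <- res[res$shared, , drop = FALSE]
      si <- surv_lookup(surv, shared$person_id)
      rows <- lapply(seq_len(nrow(shared)), function(i) {
        labs <- surv$labs[[si[i]]]
        fac <- sort(unique(labs$facility[!is.na(labs$facility)]),
                    method = "radix")
        if (!length(fac)) return(NULL)
        data.frame(cohort_id = shared$cohort_id[i], facility = fac,
                   stringsAsFactors = FALSE)
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (!length(rows)) {
        return(data.frame(cohort_id = character(), facility = character(),
                          stringsAsFactors = FALSE))
      }
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    },
    oi = {
      shared <- res[res$shared, , drop = FALSE]
      si <- surv_lookup(surv, shared$person_id)
      rows <- lapply(seq_len(nrow(shared)), function(i) {
        ois <- surv$opportunistic_infections[[si[i]]]
        if (is.null(ois) || nrow(ois) == 0) return(NULL)
        data.frame(cohort_id = shared$cohort_id[i], condition = ois$condition,
                   date = iso(ois$date), stringsAsFactors = FALSE)
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (!length(rows)) {
        return(data.frame(cohort_id = character(), condition = character(),
                          date = character(), stringsAsFactors = FALSE))
      }
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    },
    treatment = {
      if (recipient == "cohort") {
        condition_stop("linkbox_redaction_error",
                       "treatment report is restricted to the health department")
      }
      shared <- res[res$shared, , drop = FALSE]
      ei <- match(shared$cohort_id, elig$cohort_id)
      rows <- lapply(seq_len(nrow(shared)), function(i) {
        tx <- elig$treatments[[ei[i]]]
        if (is.null(tx) || nrow(tx) == 0) return(NULL)
        data.frame(cohort_id = shared$cohort_id[i],
                   person_id = shared$person_id[i], drug = tx$drug,
                   start_date = iso(tx$start_date), end_date = iso(tx$end_date),
                   stringsAsFactors = FALSE)
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (!length(rows)) {
        return(data.frame(cohort_id = character(), person_id = character(),
                          drug = character(), start_date = character(),
                          end_date = character(), stringsAsFactors = FALSE))
      }
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    }
  )
}

lab_report <- function(res, elig, surv) {
  shared <- res[res$shared, , drop = FALSE]
  ei <- match(shared$cohort_id, elig$cohort_id)
  si <- surv_lookup(surv, shared$person_id)
  rows <- lapply(seq_len(nrow(shared)), function(i) {
    cmp <- compare_labs(elig$labs[[ei[i]]], surv$labs[[si[i]]],
                        elig$consent_date[ei[i]])
    parts <- list()
    if (nrow(cmp$coded)) {
      parts$coded <- data.frame(
        cohort_id = shared$cohort_id[i],
        sample_date = iso(cmp$coded$sample_date),
        lab_type = cmp$coded$lab_type,
        cohort_result = cmp$coded$cohort_result,
        cohort_interpretation = cmp$coded$cohort_interpretation,
        surv_result = cmp$coded$surv_result,
        surv_interpretation = cmp$coded$surv_interpretation,
        lab_group = cmp$coded$lab_group,
        new_to = "", stringsAsFactors = FALSE)
    }
    if (nrow(cmp$new_to_cohort)) {
      parts$nc <- data.frame(
        cohort_id = shared$cohort_id[i],
        sample_date = iso(cmp$new_to_cohort$sample_date),
        lab_type = cmp$new_to_cohort$lab_type,
        cohort_result = NA_real_, cohort_interpretation = NA_character_,
        surv_result = cmp$new_to_cohort$result,
        surv_interpretation = cmp$new_to_cohort$interpretation,
        lab_group = "NEW", new_to = "cohort", stringsAsFactors = FALSE)
    }
    if (nrow(cmp$new_to_surveillance)) {
      parts$ns <- data.frame(
        cohort_id = shared$cohort_id[i],
        sample_date = iso(cmp$new_to_surveillance$sample_date),
        lab_type = cmp$new_to_surveillance$lab_type,
        cohort_result = cmp$new_to_surveillance$result,
        cohort_interpretation = cmp$new_to_surveillance$interpretation,
        surv_result = NA_real_, surv_interpretation = NA_character_,
        lab_group = "NEW", new_to = "surveillance", stringsAsFactors = FALSE)
    }
    if (!length(parts)) return(NULL)
    do.call(rbind, parts)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(cohort_id = character(), sample_date = character(),
                      lab_type = character(), cohort_result = numeric(),
                      cohort_interpretation = character(),
                      surv_result = numeric(),
                      surv_interpretation = character(),
                      lab_group = character(), new_to = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
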