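# Candidate blocking, pair scoring and best-match selection.
#
# Every level of the cascade requires at least one of Cohort ID, DOB or SSN
# (full or partial), so blocking on those three keys is lossless: any pair
# the scorer could score shares at least one blocking key. Scoring is
# vectorized over candidate pairs; the cascade is walked once per level,
# assigning each still-unscored pair the first level it satisfies, in
# strictly descending score order (person-view before alias within a
# full-name level).

SEP <- "\x1F"

ssn_last4 <- function(ssn) {
  out <- rep(NA_character_, length(ssn))
  n9 <- !is.na(ssn) & nchar(ssn) == 9L
  n4 <- !is.na(ssn) & nchar(ssn) == 4L
  out[n9] <- substr(ssn[n9], 6L, 9L)
  out[n4] <- ssn[n4]
  out
}

prep_cohort_features <- function(rec) {
  list(
    cohort_id = rec$cohort_id,
    first = normalize_name(rec$first_name),
    last = normalize_name(rec$last_name),
    dob = as.character(rec$dob),
    ssn = rec$ssn,
    last4 = ssn_last4(rec$ssn),
    sex = rec$birth_sex
  )
}

prep_surv_features <- function(rec) {
  alias_keys <- lapply(seq_len(nrow(rec)), function(i) {
    a <- rec$aliases[[i]]
    if (is.null(a) || nrow(a) == 0) return(character())
    f <- normalize_name(a$first_name)
    l <- normalize_name(a$last_name)
    ok <- !is.na(f) & !is.na(l)
    unique(paste(f[ok], l[ok], sep = SEP))
  })
  list(
    person_id = rec$person_id,
    first = normalize_name(rec$first_name),
    last = normalize_name(rec$last_name),
    alias_keys = alias_keys,
    dob = as.character(rec$dob),
    ssn = rec$ssn,
    last4 = ssn_last4(rec$ssn),
    sex = rec$birth_sex,
    prior = rec$prior_cohort_id
  )
}

# index pairs (ci, si) sharing a key value; a and b are key vectors
key_pairs <- function(a, b) {
  ai <- split(seq_along(a), a)
  bi <- split(seq_along(b), b)
  common <- intersect(names(ai), names(bi))
  if (!length(common)) {
    return(data.frame(ci = integer(), si = integer()))
  }
  pieces <- lapply(common, function(k) {
    expand.grid(ci = ai[[k]], si = bi[[k]], KEEP.OUT.ATTRS = FALSE)
  })
  do.call(rbind, pieces)
}

candidate_idx <- function(cf, sf) {
  p <- rbind(
    key_pairs(cf$cohort_id, sf$prior),
    key_pairs(cf$dob, sf$dob),
    key_pairs(cf$last4, sf$last4)
  )
  p <- p[!duplicated(p[c("ci", "si")]), , drop = FALSE]
  p[order(p$ci, p$si), , drop = FALSE]
}

# vectorized cascade over index pairs; returns score / level / name_source
score_idx <- function(ci, si, cf, sf, alg) {
  n <- length(ci)
  both <- function(a, b) !is.na(a) & !is.na(b) & a == b
  crit <- list(
    COHORT_ID = both(cf$cohort_id[ci], sf$prior[si]),
    DOB = both(cf$dob[ci], sf$dob[si]),
    SSN_FULL = both(cf$ssn[ci], sf$ssn[si]) &
      !is.na(cf$ssn[ci]) & nchar(cf$ssn[ci]) == 9L &
      !is.na(sf$ssn[si]) & nchar(sf$ssn[si]) == 9L,
    SSN_PARTIAL = both(cf$last4[ci], sf$last4[si]),
    BIRTH_SEX = both(cf$sex[ci], sf$sex[si])
  )
  name_pv <- both(cf$first[ci], sf$first[si]) & both(cf$last[ci], sf$last[si])
  last_pv <- both(cf$last[ci], sf$last[si])
  first6 <- last_pv & both(substr(cf$first[ci], 1L, 6L),
                           substr(sf$first[si], 1L, 6L))
  # alias lookup: flatten each surveillance record's alias keys once
  alias_ok <- rep(FALSE, n)
  has_name <- !is.na(cf$first[ci]) & !is.na(cf$last[ci])
  if (any(lengths(sf$alias_keys) > 0) && any(has_name)) {
    flat <- unlist(sf$alias_keys, use.names = FALSE)
    owner <- rep(seq_along(sf$alias_keys), lengths(sf$alias_keys))
    keyset <- paste(owner, flat, sep = SEP)
    query <- paste(si, cf$first[ci], cf$last[ci], sep = SEP)
    alias_ok <- has_name & (query %in% keyset)
  }

  score <- rep(NA_integer_, n)
  level <- rep(NA_integer_, n)
  source <- rep(NA_character_, n)
  unassigned <- rep(TRUE, n)
  for (k in seq_along(alg$levels)) {
    if (!any(unassigned)) break
    l <- alg$levels[[k]]
    req <- rep(TRUE, n)
    for (v in l$required) req <- req & crit[[v]]
    if (l$name_rule == "FULL_NAME") {
      hit <- unassigned & req & name_pv
      score[hit] <- l$score_pv; level[hit] <- k; source[hit] <- "person_view"
      unassigned[hit] <- FALSE
      if (!is.na(l$score_alias)) {
        hit <- unassigned & req & alias_ok
        score[hit] <- l$score_alias; level[hit] <- k; source[hit] <- "alias"
        unassigned[hit] <- FALSE
      }
    } else {
      name_ok <- switch(l$name_rule,
        LAST_ONLY = last_pv,
        LAST_PLUS_FIRST6 = first6,
        NONE = rep(TRUE, n)
      )
      hit <- unassigned & req & name_ok
      score[hit] <- l$score_pv; level[hit] <- k
      source[hit] <- if (l$name_rule == "NONE") "none" else "person_view"
      unassigned[hit] <- FALSE
    }
  }
  list(score = score, level = level, name_source = source)
}

#' Score one cohort/surveillance record pair
#'
#' Walks the scoring cascade from the top and returns the highest level
#' whose criteria the pair satisfies. Name agreement against the registry
#' person-view name takes the level's full score; agreement against an
#' alias name takes the one-point-lower alias score. Criteria over a field
#' missing on either side are unsatisfied (missing data yields no-match,
#' never an error).
#'
#' @param cohort_record One-row data frame with the merged cohort-side
#'   identifiers (`cohort_id`, `first_name`, `last_name`, `dob`, `ssn`,
#'   `birth_sex`).
#' @param surv_record One-row data frame of a surveillance record
#'   (person-view names, `aliases` list column, `dob`, `ssn`, `birth_sex`,
#'   `prior_cohort_id`).
#' @param alg A [match_algorithm()]; defaults to the shipped cascade.
#' @return `NULL` when no level is satisfied, otherwise a list with
#'   `score`, `level_description`, `name_source` and `shared`
#'   (`score >= threshold`).
#' @export
score_pair <- function(cohort_record, surv_record, alg = default_algorithm()) {
  cf <- prep_cohort_features(cohort_record)
  sf <- prep_surv_features(surv_record)
  res <- score_idx(1L, 1L, cf, sf, alg)
  if (is.na(res$score)) return(NULL)
  list(score = res$score[1],
       level_description = level_description(alg$levels[[res$level[1]]]),
       name_source = res$name_source[1],
       shared = res$score[1] >= alg$threshold)
}

#' Generate candidate pairs by blocking
#'
#' A pair is a candidate iff it shares at least one blocking key among
#' Cohort ID (against the registry's prior Cohort ID), DOB, or the last 4
#' SSN digits. Because every cascade level requires at least one of those
#' variables, the candidate set is a superset of every pair the scorer
#' could score: matching over candidates is exactly equivalent to matching
#' over the full cross product.
#'
#' @param cohort_records Merged cohort records (one row per Cohort ID).
#' @param surveillance_records Surveillance records.
#' @return Data frame with columns `cohort_id`, `person_id`.
#' @export
generate_candidates <- function(cohort_records, surveillance_records) {
  cf <- prep_cohort_features(cohort_records)
  sf <- prep_surv_features(surveillance_records)
  p <- candidate_idx(cf, sf)
  data.frame(cohort_id = cf$cohort_id[p$ci], person_id = sf$person_id[p$si],
             stringsAsFactors = FALSE)
}

#' Run the matching stage
#'
#' Scores all candidate pairs and keeps, per Cohort ID, the single
#' best-scoring surveillance person. Equal-score ties between distinct
#' persons are broken toward the lexicographically smallest `person_id`
#' and flagged. Sub-threshold matches are reported with `shared = FALSE`;
#' cohort records with no scorable pair are absent from the result (they
#' populate the unmatched reports).
#'
#' @inheritParams generate_candidates
#' @param alg A [match_algorithm()].
#' @param exhaustive Score the full cross product instead of blocked
#'   candidates (for cross-checking; identical results by construction).
#' @return Data frame of match results sorted by `cohort_id`: columns
#'   `cohort_id`, `person_id`, `score`, `level_description`,
#'   `name_source`, `shared`, `tie_flag`.
#' @export
run_match <- function(cohort_records, surveillance_records,
                      alg = default_algorithm(), exhaustive = FALSE) {
  cf <- prep_cohort_features(cohort_records)
  sf <- prep_surv_features(surveillance_records)
  empty <- data.frame(cohort_id = character(), person_id = character(),
                      score = integer(), level_description = character(),
                      name_source = character(), shared = logical(),
                      tie_flag = logical(), stringsAsFactors = FALSE)
  nc <- length(cf$cohort_id); ns <- length(sf$person_id)
  if (nc == 0 || ns == 0) return(empty)
  p <- if (exhaustive) {
    expand.grid(ci = seq_len(nc), si = seq_len(ns), KEEP.OUT.ATTRS = FALSE)
  } else {
    candidate_idx(cf, sf)
  }
  if (nrow(p) == 0) return(empty)
  sc <- score_idx(p$ci, p$si, cf, sf, alg)
  keep <- !is.na(sc$score)
  if (!any(keep)) return(empty)
  d <- data.frame(ci = p$ci[keep], si = p$si[keep], score = sc$score[keep],
                  level = sc$level[keep], name_source = sc$name_source[keep],
                  stringsAsFactors = FALSE)
  d$person_id <- sf$person_id[d$si]
  # best score per cohort record; person_id ascending breaks ties
  o <- order(d$ci, -d$score, d$person_id, method = "radix")
  d <- d[o, , drop = FALSE]
  first <- !duplicated(d$ci)
  best <- d[first, , drop = FALSE]
  # a tie exists when another distinct person reaches the same top score;
  # pairs are unique and person_id unique per record, so rows in one
  # (ci, score) group are distinct persons
  top_key <- paste(d$ci, d$score, sep = SEP)
  grp_n <- ave(rep(1L, nrow(d)), top_key, FUN = length)
  tie <- grp_n[first] > 1L
  out <- data.frame(
    cohort_id = cf$cohort_id[best$ci],
    person_id = best$person_id,
    score = best$score,
    level_description = vapply(best$level, function(k)
      level_description(alg$levels[[k]]), ""),
    name_source = best$name_source,
    shared = best$score >= alg$threshold,
    tie_flag = tie,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$cohort_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
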