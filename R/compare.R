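# Post-match data comparison: demographics discrepancies and lab
# reconciliation with lab-group coding. Both run only on pairs matched at
# or above the sharing threshold.

#' Compare demographic profiles of a matched pair
#'
#' Emits one row per field whose canonicalized values are missing on one
#' side or unequal; concordant fields (and fields missing on both sides)
#' produce no row. Comparison canonicalizes case and surrounding
#' whitespace for categories and renders dates as ISO strings; the emitted
#' values are the original ones, so each recipient receives the
#' counterpart's value.
#'
#' @param cohort_profile,surv_profile One-row data frames (or lists)
#'   carrying demographic fields.
#' @param fields Ordered character vector of field names to compare;
#'   defaults to the standard profile (vital status, gender, sex at birth,
#'   race, HIV transmission risk, state of residence, HIV and AIDS
#'   diagnosis dates).
#' @return Data frame with columns `field`, `cohort_value`,
#'   `surveillance_value`, `kind` (`missing_in_cohort`,
#'   `missing_in_surveillance`, `conflict`, `absent_field`).
#' @export
compare_demographics <- function(cohort_profile, surv_profile,
                                 fields = DEMOG_FIELDS) {
  known <- union(DEMOG_FIELDS, union(names(cohort_profile), names(surv_profile)))
  if (length(bad <- setdiff(fields, known)))
    condition_stop("linkbox_config_error",
                   sprintf("unknown demographic field '%s'", bad[1]))
  canon <- function(v) {
    if (length(v) == 0 || is.null(v)) return(NA_character_)
    if (inherits(v, "Date")) return(iso(v))
    v <- as.character(v)
    v <- trimws(v)
    v[!is.na(v) & v == ""] <- NA_character_
    toupper(v)
  }
  as_chr <- function(v) {
    if (length(v) == 0 || is.null(v)) return(NA_character_)
    if (inherits(v, "Date")) iso(v) else as.character(v)
  }
  out <- list()
  for (f in fields) {
    in_c <- f %in% names(cohort_profile)
    in_s <- f %in% names(surv_profile)
    cv <- if (in_c) as_chr(cohort_profile[[f]]) else NA_character_
    sv <- if (in_s) as_chr(surv_profile[[f]]) else NA_character_
    kind <- if (!in_c || !in_s) {
      "absent_field"
    } else {
      cc <- canon(cohort_profile[[f]]); sc <- canon(surv_profile[[f]])
      if (is.na(cc) && is.na(sc)) NA_character_
      else if (is.na(cc)) "missing_in_cohort"
      else if (is.na(sc)) "missing_in_surveillance"
      else if (cc != sc) "conflict"
      else NA_character_
    }
    if (!is.na(kind)) {
      out[[length(out) + 1L]] <- data.frame(
        field = f, cohort_value = cv, surveillance_value = sv, kind = kind,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(field = character(), cohort_value = character(),
                      surveillance_value = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

canon_result <- function(x) {
  # trailing-zero differences (200 vs 200.0) disappear under numeric equality
  as.numeric(x)
}

#' Compare lab records of a matched pair
#'
#' Labs dated on or before the cohort consent date are excluded from the
#' comparison entirely (the sharing agreement covers post-consent data
#' only; "after" is read strictly). Remaining labs are paired greedily by
#' `(sample_date, lab_type)` — within a key group both sides are taken in
#' result-sorted order — and each pair is coded into a lab group:
#' `DUPLICATE` (result and interpretation agree), `RESULT_INTERP_DIFF`
#' (result agrees, interpretation differs), `RESULT_DIFF` (result
#' differs). Unpaired labs are `NEW` to the side lacking them. Result
#' equality is exact after canonicalization (numeric, so trailing zeros
#' are immaterial); no numeric tolerance is applied.
#'
#' @param cohort_labs,surv_labs Lab data frames (`sample_date`,
#'   `lab_type`, `result`, `interpretation`, optional `facility`).
#' @param consent_date The cohort consent date (`Date`).
#' @return List with `coded` (paired labs with `lab_group`),
#'   `new_to_cohort` (surveillance-only labs) and `new_to_surveillance`
#'   (cohort-only labs).
#' @export
compare_labs <- function(cohort_labs, surv_labs, consent_date) {
  fix <- function(df) {
    if (is.null(df)) df <- empty_labs()
    if (!"facility" %in% names(df)) df$facility <- NA_character_
    if (!is.na(consent_date) && nrow(df))
      df <- df[df$sample_date > consent_date, , drop = FALSE]
    df
  }
  cl <- fix(cohort_labs)
  sl <- fix(surv_labs)
  key <- function(df) paste(iso(df$sample_date), df$lab_type, sep = "\x1F")
  ck <- key(cl); sk <- key(sl)
  coded <- list()
  new_c <- list(); new_s <- list()
  for (k in sort(unique(c(ck, sk)), method = "radix")) {
    a <- cl[ck == k, , drop = FALSE]
    b <- sl[sk == k, , drop = FALSE]
    a <- a[order(a$result, a$interpretation, method = "radix",
                 na.last = TRUE), , drop = FALSE]
    b <- b[order(b$result, b$interpretation, method = "radix",
                 na.last = TRUE), , drop = FALSE]
    m <- min(nrow(a), nrow(b))
    if (m > 0) {
      for (i in seq_len(m)) {
        res_eq <- isTRUE(canon_result(a$result[i]) == canon_result(b$result[i]))
        interp_eq <- identical(a$interpretation[i], b$interpretation[i]) ||
          (is.na(a$interpretation[i]) && is.na(b$interpretation[i]))
        grp <- if (res_eq && interp_eq) "DUPLICATE"
               else if (res_eq) "RESULT_INTERP_DIFF"
               else "RESULT_DIFF"
        coded[[length(coded) + 1L]] <- data.frame(
          sample_date = a$sample_date[i], lab_type = a$lab_type[i],
          cohort_result = a$result[i],
          cohort_interpretation = a$interpretation[i],
          surv_result = b$result[i],
          surv_interpretation = b$interpretation[i],
          facility = b$facility[i], lab_group = grp,
          stringsAsFactors = FALSE)
      }
    }
    if (nrow(a) > m) new_s[[length(new_s) + 1L]] <- a[(m + 1):nrow(a), ,
                                                      drop = FALSE]
    if (nrow(b) > m) new_c[[length(new_c) + 1L]] <- b[(m + 1):nrow(b), ,
                                                      drop = FALSE]
  }
  empty_coded <- data.frame(
    sample_date = as.Date(character()), lab_type = character(),
    cohort_result = numeric(), cohort_interpretation = character(),
    surv_result = numeric(), surv_interpretation = character(),
    facility = character(), lab_group = character(), stringsAsFactors = FALSE)
  list(
    coded = if (length(coded)) do.call(rbind, coded) else empty_coded,
    new_to_cohort = if (length(new_c)) do.call(rbind, new_c) else empty_labs(),
    new_to_surveillance = if (length(new_s)) do.call(rbind, new_s)
                          else empty_labs()
  )
}
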