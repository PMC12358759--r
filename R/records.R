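# Feed schemas, typed readers/writers and template verification.
#
# Three delimited feeds flow into a linkage run:
#   * site        -- identifying records submitted by each clinic site
#   * central     -- the de-identified cohort repository (demographics, labs,
#                    treatments, consent date), keyed by Cohort ID
#   * surveillance-- the registry person view (names + alias names, DOB, SSN,
#                    demographics, labs with facility, OIs, vital status)
#
# All files are RFC 4180 CSV (UTF-8, header row, comma separator). Dates are
# ISO 8601. The missing token on disk is the empty cell; internally it is NA,
# never the empty string. Nested payloads (aliases, labs, treatments, OIs)
# live in one CSV cell as semicolon-joined entries; aliases use the
# "LAST,FIRST;LAST,FIRST" convention, the others pipe-delimited fields.

DEMOG_FIELDS <- c(
  "vital_status", "gender", "sex_at_birth", "race",
  "hiv_transmission_risk", "state_of_residence",
  "hiv_diagnosis_date", "aids_diagnosis_date"
)

LAB_TYPES <- c("CD4_count", "CD4_percent", "viral_load")
LAB_INTERPS <- c("EQ", "LT", "GT", "UNDETECTABLE")

#' Feed schemas
#'
#' Column layout of the three input feeds. `feed_columns()` returns the
#' canonical column names for a schema; `feed_key()` the columns forming the
#' within-file unique key.
#'
#' @param schema_name One of `"site"`, `"central"`, `"surveillance"`.
#' @return Character vector of column names.
#' @export
feed_columns <- function(schema_name) {
  switch(match.arg(schema_name, c("site", "central", "surveillance")),
    site = c("cohort_id", "site_id", "first_name", "last_name", "dob",
             "ssn", "birth_sex"),
    central = c("cohort_id", "consent_date", DEMOG_FIELDS, "labs",
                "treatments"),
    surveillance = c("person_id", "first_name", "last_name", "aliases",
                     "dob", "ssn", "birth_sex", "prior_cohort_id",
                     DEMOG_FIELDS, "labs", "opportunistic_infections",
                     "death_date", "cause_of_death")
  )
}

#' @rdname feed_columns
#' @export
feed_key <- function(schema_name) {
  switch(match.arg(schema_name, c("site", "central", "surveillance")),
    site = c("cohort_id", "site_id"),
    central = "cohort_id",
    surveillance = "person_id"
  )
}

# ---- field-level parsers (each returns list(value, issues)) ----------------

new_issues <- function() {
  data.frame(row = integer(), field = character(), issue = character(),
             stringsAsFactors = FALSE)
}

add_issue <- function(issues, row, field, issue) {
  rbind(issues, data.frame(row = row, field = field, issue = issue,
                           stringsAsFactors = FALSE))
}

parse_ssn_vec <- function(x) {
  x <- blank_to_na(x)
  x <- gsub("[ -]", "", x)
  bad <- !is.na(x) & !grepl("^(\\d{9}|\\d{4})$", x)
  x[bad] <- NA_character_
  list(value = x, bad = bad)
}

parse_date_col <- function(x, allow_future = TRUE) {
  raw <- blank_to_na(x)
  d <- parse_iso_date(raw)
  bad_format <- !is.na(raw) & is.na(d)
  future <- !is.na(d) & d > Sys.Date() & !allow_future
  d[future] <- as.Date(NA)
  list(value = d, bad_format = bad_format, future = future)
}

parse_sex_col <- function(x) {
  raw <- blank_to_na(x)
  v <- toupper(raw)
  v[v %in% c("MALE")] <- "M"
  v[v %in% c("FEMALE")] <- "F"
  v[v %in% c("U", "UNKNOWN")] <- NA_character_
  bad <- !is.na(raw) & !is.na(v) & !(v %in% c("M", "F"))
  v[bad] <- NA_character_
  list(value = v, bad = bad)
}

parse_vital_col <- function(x) {
  raw <- blank_to_na(x)
  v <- tolower(raw)
  v[v %in% "unknown"] <- NA_character_
  bad <- !is.na(raw) & !is.na(v) & !(v %in% c("alive", "deceased"))
  v[bad] <- NA_character_
  list(value = v, bad = bad)
}

# "LAST1,FIRST1;LAST2,FIRST2" -> data.frame(first, last); entries with both
# parts blank are invalid and reported by the caller
parse_alias_cell <- function(cell) {
  cell <- blank_to_na(cell)
  if (is.na(cell)) {
    return(list(aliases = data.frame(first_name = character(),
                                     last_name = character(),
                                     stringsAsFactors = FALSE),
                n_bad = 0L))
  }
  entries <- strsplit(cell, ";", fixed = TRUE)[[1]]
  parts <- lapply(entries, function(e) {
    p <- strsplit(e, ",", fixed = TRUE)[[1]]
    c(last = if (length(p) >= 1) trimws(p[1]) else "",
      first = if (length(p) >= 2) trimws(p[2]) else "")
  })
  first <- blank_to_na(vapply(parts, `[[`, "", "first"))
  last <- blank_to_na(vapply(parts, `[[`, "", "last"))
  bad <- is.na(first) & is.na(last)
  list(aliases = data.frame(first_name = first[!bad], last_name = last[!bad],
                            stringsAsFactors = FALSE),
       n_bad = sum(bad))
}

format_alias_cell <- function(df) {
  if (is.null(df) || nrow(df) == 0) return("")
  paste(paste(na_to_blank(df$last_name), na_to_blank(df$first_name),
              sep = ","), collapse = ";")
}

empty_labs <- function() {
  data.frame(sample_date = as.Date(character()), lab_type = character(),
             result = numeric(), interpretation = character(),
             facility = character(), stringsAsFactors = FALSE)
}

# "date|type|result|interp|facility;..." -> lab data.frame + issue strings
parse_lab_cell <- function(cell) {
  cell <- blank_to_na(cell)
  if (is.na(cell)) return(list(labs = empty_labs(), issues = character()))
  entries <- strsplit(cell, ";", fixed = TRUE)[[1]]
  issues <- character()
  rows <- lapply(entries, function(e) {
    p <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(p) < 4) {
      issues <<- c(issues, sprintf("malformed lab entry '%s'", e))
      return(NULL)
    }
    d <- parse_iso_date(p[1])
    if (is.na(d)) {
      issues <<- c(issues, sprintf("invalid lab sample date '%s'", p[1]))
      return(NULL)
    }
    type <- p[2]
    if (!type %in% LAB_TYPES) {
      issues <<- c(issues, sprintf("unknown lab type '%s'", type))
      return(NULL)
    }
    res <- suppressWarnings(as.numeric(p[3]))
    if (is.na(res) || res < 0) {
      issues <<- c(issues, sprintf("invalid lab result '%s'", p[3]))
      return(NULL)
    }
    if (type == "CD4_percent" && res > 100) {
      issues <<- c(issues, sprintf("CD4 percent out of range '%s'", p[3]))
      return(NULL)
    }
    interp <- toupper(trimws(p[4]))
    if (interp == "" || is.na(interp)) interp <- NA_character_
    else if (!interp %in% LAB_INTERPS) {
      issues <<- c(issues, sprintf("unknown result interpretation '%s'", p[4]))
      interp <- NA_character_
    }
    fac <- if (length(p) >= 5) blank_to_na(p[5]) else NA_character_
    data.frame(sample_date = d, lab_type = type, result = res,
               interpretation = interp, facility = fac,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  labs <- if (length(rows)) do.call(rbind, rows) else empty_labs()
  list(labs = labs, issues = issues)
}

format_lab_cell <- function(df) {
  if (is.null(df) || nrow(df) == 0) return("")
  paste(sprintf("%s|%s|%s|%s|%s", iso(df$sample_date), df$lab_type,
                vapply(df$result, function(r) format(r, scientific = FALSE), ""),
                na_to_blank(df$interpretation), na_to_blank(df$facility)),
        collapse = ";")
}

empty_treatments <- function() {
  data.frame(drug = character(), start_date = as.Date(character()),
             end_date = as.Date(character()), stringsAsFactors = FALSE)
}

parse_treatment_cell <- function(cell) {
  cell <- blank_to_na(cell)
  if (is.na(cell)) return(list(treatments = empty_treatments(),
                               issues = character()))
  entries <- strsplit(cell, ";", fixed = TRUE)[[1]]
  issues <- character()
  rows <- lapply(entries, function(e) {
    p <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(p) < 2 || is.na(blank_to_na(p[1]))) {
      issues <<- c(issues, sprintf("malformed treatment entry '%s'", e))
      return(NULL)
    }
    start <- parse_iso_date(p[2])
    if (is.na(start)) {
      issues <<- c(issues, sprintf("invalid treatment start date '%s'", p[2]))
      return(NULL)
    }
    end <- if (length(p) >= 3 && !is.na(blank_to_na(p[3])))
      parse_iso_date(p[3]) else as.Date(NA)
    data.frame(drug = p[1], start_date = start, end_date = end,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  tx <- if (length(rows)) do.call(rbind, rows) else empty_treatments()
  list(treatments = tx, issues = issues)
}

format_treatment_cell <- function(df) {
  if (is.null(df) || nrow(df) == 0) return("")
  paste(sprintf("%s|%s|%s", df$drug, iso(df$start_date),
                na_to_blank(iso(df$end_date))), collapse = ";")
}

empty_ois <- function() {
  data.frame(condition = character(), date = as.Date(character()),
             stringsAsFactors = FALSE)
}

parse_oi_cell <- function(cell) {
  cell <- blank_to_na(cell)
  if (is.na(cell)) return(list(ois = empty_ois(), issues = character()))
  entries <- strsplit(cell, ";", fixed = TRUE)[[1]]
  issues <- character()
  rows <- lapply(entries, function(e) {
    p <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(p) < 2 || is.na(blank_to_na(p[1]))) {
      issues <<- c(issues, sprintf("malformed OI entry '%s'", e))
      return(NULL)
    }
    d <- parse_iso_date(p[2])
    if (is.na(d)) {
      issues <<- c(issues, sprintf("invalid OI date '%s'", p[2]))
      return(NULL)
    }
    data.frame(condition = p[1], date = d, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  ois <- if (length(rows)) do.call(rbind, rows) else empty_ois()
  list(ois = ois, issues = issues)
}

format_oi_cell <- function(df) {
  if (is.null(df) || nrow(df) == 0) return("")
  paste(sprintf("%s|%s", df$condition, iso(df$date)), collapse = ";")
}

# ---- feed parsing ----------------------------------------------------------

parse_feed <- function(raw, schema_name) {
  cols <- feed_columns(schema_name)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    condition_stop("linkbox_schema_error",
                   sprintf("missing required column(s): %s",
                           paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(raw)
  issues <- new_issues()
  rec <- data.frame(row = seq_len(n))

  key_cols <- feed_key(schema_name)
  for (k in key_cols) rec[[k]] <- blank_to_na(raw[[k]])
  bad_key <- is.na(rec[[key_cols[1]]])
  if (any(bad_key)) {
    issues <- add_issue(issues, which(bad_key), key_cols[1],
                        sprintf("%s must be non-empty", key_cols[1]))
  }
  keys <- do.call(paste, c(rec[key_cols], sep = "\x1F"))
  dup <- keys[!bad_key][duplicated(keys[!bad_key])]
  if (length(dup)) {
    condition_stop("linkbox_key_error",
                   sprintf("duplicate %s within file: %s",
                           paste(key_cols, collapse = "+"),
                           paste(unique(gsub("\x1F", "/", dup)),
                                 collapse = ", ")),
                   keys = unique(dup))
  }

  if (schema_name == "site") {
    rec$first_name <- blank_to_na(raw$first_name)
    rec$last_name <- blank_to_na(raw$last_name)
    d <- parse_date_col(raw$dob, allow_future = FALSE)
    rec$dob <- d$value
    for (i in which(d$bad_format))
      issues <- add_issue(issues, i, "dob", "not a valid ISO date (YYYY-MM-DD)")
    for (i in which(d$future))
      issues <- add_issue(issues, i, "dob", "date of birth is in the future")
    s <- parse_ssn_vec(raw$ssn)
    rec$ssn <- s$value
    for (i in which(s$bad))
      issues <- add_issue(issues, i, "ssn",
                          "SSN must be 9 digits (full) or 4 digits (partial)")
    bs <- parse_sex_col(raw$birth_sex)
    rec$birth_sex <- bs$value
    for (i in which(bs$bad))
      issues <- add_issue(issues, i, "birth_sex",
                          "birth sex must be M, F or blank")
  } else if (schema_name == "central") {
    d <- parse_date_col(raw$consent_date, allow_future = FALSE)
    rec$consent_date <- d$value
    for (i in which(d$bad_format))
      issues <- add_issue(issues, i, "consent_date",
                          "not a valid ISO date (YYYY-MM-DD)")
    for (i in which(d$future))
      issues <- add_issue(issues, i, "consent_date",
                          "consent date is in the future")
    res <- parse_demographics(raw, issues)
    rec <- cbind(rec, res$rec)
    issues <- res$issues
    labs <- vector("list", n); tx <- vector("list", n)
    for (i in seq_len(n)) {
      pl <- parse_lab_cell(raw$labs[i])
      labs[[i]] <- pl$labs
      for (msg in pl$issues) issues <- add_issue(issues, i, "labs", msg)
      pt <- parse_treatment_cell(raw$treatments[i])
      tx[[i]] <- pt$treatments
      for (msg in pt$issues) issues <- add_issue(issues, i, "treatments", msg)
    }
    rec$labs <- I(labs)
    rec$treatments <- I(tx)
  } else { # surveillance
    rec$first_name <- blank_to_na(raw$first_name)
    rec$last_name <- blank_to_na(raw$last_name)
    ali <- vector("list", n)
    for (i in seq_len(n)) {
      pa <- parse_alias_cell(raw$aliases[i])
      ali[[i]] <- pa$aliases
      if (pa$n_bad > 0)
        issues <- add_issue(issues, i, "aliases",
                            "alias entry with no non-empty name part")
    }
    rec$aliases <- I(ali)
    d <- parse_date_col(raw$dob, allow_future = FALSE)
    rec$dob <- d$value
    for (i in which(d$bad_format))
      issues <- add_issue(issues, i, "dob", "not a valid ISO date (YYYY-MM-DD)")
    for (i in which(d$future))
      issues <- add_issue(issues, i, "dob", "date of birth is in the future")
    s <- parse_ssn_vec(raw$ssn)
    rec$ssn <- s$value
    for (i in which(s$bad))
      issues <- add_issue(issues, i, "ssn",
                          "SSN must be 9 digits (full) or 4 digits (partial)")
    bs <- parse_sex_col(raw$birth_sex)
    rec$birth_sex <- bs$value
    for (i in which(bs$bad))
      issues <- add_issue(issues, i, "birth_sex",
                          "birth sex must be M, F or blank")
    rec$prior_cohort_id <- blank_to_na(raw$prior_cohort_id)
    res <- parse_demographics(raw, issues)
    rec <- cbind(rec, res$rec)
    issues <- res$issues
    labs <- vector("list", n); ois <- vector("list", n)
    for (i in seq_len(n)) {
      pl <- parse_lab_cell(raw$labs[i])
      labs[[i]] <- pl$labs
      for (msg in pl$issues) issues <- add_issue(issues, i, "labs", msg)
      po <- parse_oi_cell(raw$opportunistic_infections[i])
      ois[[i]] <- po$ois
      for (msg in po$issues)
        issues <- add_issue(issues, i, "opportunistic_infections", msg)
    }
    rec$labs <- I(labs)
    rec$opportunistic_infections <- I(ois)
    dd <- parse_date_col(raw$death_date, allow_future = TRUE)
    rec$death_date <- dd$value
    for (i in which(dd$bad_format))
      issues <- add_issue(issues, i, "death_date",
                          "not a valid ISO date (YYYY-MM-DD)")
    rec$cause_of_death <- blank_to_na(raw$cause_of_death)
    # death_date implies deceased; blank the date otherwise
    viol <- !is.na(rec$death_date) &
      (is.na(rec$vital_status) | rec$vital_status != "deceased")
    if (any(viol)) {
      for (i in which(viol))
        issues <- add_issue(issues, i, "death_date",
                            "death date present but vital status is not deceased")
      rec$death_date[viol] <- as.Date(NA)
    }
  }
  rec$row <- NULL
  issues <- issues[order(issues$row, issues$field), , drop = FALSE]
  rownames(issues) <- NULL
  list(records = rec, warnings = issues)
}

parse_demographics <- function(raw, issues) {
  n <- nrow(raw)
  rec <- data.frame(row = seq_len(n))
  vs <- parse_vital_col(raw$vital_status)
  rec$vital_status <- vs$value
  for (i in which(vs$bad))
    issues <- add_issue(issues, i, "vital_status",
                        "vital status must be alive, deceased or unknown")
  for (f in c("gender", "sex_at_birth", "race", "hiv_transmission_risk",
              "state_of_residence")) {
    rec[[f]] <- blank_to_na(raw[[f]])
  }
  for (f in c("hiv_diagnosis_date", "aids_diagnosis_date")) {
    d <- parse_date_col(raw[[f]], allow_future = FALSE)
    rec[[f]] <- d$value
    for (i in which(d$bad_format))
      issues <- add_issue(issues, i, f, "not a valid ISO date (YYYY-MM-DD)")
    for (i in which(d$future))
      issues <- add_issue(issues, i, f, "date is in the future")
  }
  rec$row <- NULL
  list(rec = rec, issues = issues)
}

# ---- public readers/writers ------------------------------------------------

read_raw_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    condition_stop("linkbox_io_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0), stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    # col_map: named list/vector, external name -> canonical name
    idx <- match(names(raw), names(col_map))
    names(raw)[!is.na(idx)] <- unlist(col_map)[idx[!is.na(idx)]]
  }
  raw
}

#' Read a feed file into typed records
#'
#' Parses one of the three CSV feeds into a typed record table. Unparseable
#' or invariant-violating fields become `NA` and are reported in the
#' `warnings` element; structural problems (missing required column,
#' duplicate key within the file) are errors.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema_name One of `"site"`, `"central"`, `"surveillance"`.
#' @param col_map Optional named character vector mapping external column
#'   names to the canonical names of [feed_columns()].
#' @return An object of class `linkbox_feed`: a list with elements
#'   `records` (data frame, one row per input row; nested payloads as list
#'   columns), `warnings` (data frame with `row`, `field`, `issue`) and
#'   `schema`.
#' @seealso [verify_file()], [write_table()]
#' @export
read_table <- function(path, schema_name, col_map = NULL) {
  schema_name <- match.arg(schema_name, c("site", "central", "surveillance"))
  raw <- read_raw_csv(path, col_map)
  parsed <- parse_feed(raw, schema_name)
  structure(list(records = parsed$records, warnings = parsed$warnings,
                 schema = schema_name, path = path),
            class = "linkbox_feed")
}

#' @export
print.linkbox_feed <- function(x, ...) {
  cat(sprintf("<linkbox_feed> schema=%s records=%d warnings=%d\n",
              x$schema, nrow(x$records), nrow(x$warnings)))
  invisible(x)
}

#' Write typed records back to a feed CSV
#'
#' Inverse of [read_table()]: serializes a typed record table to RFC 4180
#' CSV with ISO dates, empty cells for missing values, and the documented
#' subfield encodings for aliases, labs, treatments and opportunistic
#' infections. `read_table(write_table(x))` reproduces `x` field for field.
#'
#' @param x A `linkbox_feed` or a records data frame as produced by
#'   [read_table()].
#' @param path Output path.
#' @param schema_name Feed schema; inferred from a `linkbox_feed` input.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema_name = NULL) {
  if (inherits(x, "linkbox_feed")) {
    schema_name <- x$schema
    rec <- x$records
  } else {
    rec <- x
    if (is.null(schema_name)) stop("schema_name required for plain records")
  }
  schema_name <- match.arg(schema_name, c("site", "central", "surveillance"))
  out <- data.frame(row.names = seq_len(max(nrow(rec), 0)))
  for (col in feed_columns(schema_name)) {
    v <- rec[[col]]
    out[[col]] <- if (col == "aliases") {
      vapply(v, format_alias_cell, "")
    } else if (col == "labs") {
      vapply(v, format_lab_cell, "")
    } else if (col == "treatments") {
      vapply(v, format_treatment_cell, "")
    } else if (col == "opportunistic_infections") {
      vapply(v, format_oi_cell, "")
    } else if (inherits(v, "Date")) {
      na_to_blank(iso(v))
    } else {
      na_to_blank(v)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Verify a feed file against its template
#'
#' The pre-upload check: validates a file against the schema template and
#' returns every issue found, without stopping at the first. The report is
#' empty exactly when [read_table()] would succeed with zero warnings.
#' Structural problems (unparseable file, missing column, duplicate keys)
#' appear as schema-level rows with `row = NA`.
#'
#' @inheritParams read_table
#' @return Data frame with columns `row`, `field`, `issue`, ordered by
#'   `(row, field)`; zero rows for a clean file.
#' @export
verify_file <- function(path, schema_name, col_map = NULL) {
  schema_name <- match.arg(schema_name, c("site", "central", "surveillance"))
  if (!file.exists(path)) {
    condition_stop("linkbox_io_error", sprintf("file not found: %s", path))
  }
  res <- tryCatch(
    read_table(path, schema_name, col_map)$warnings,
    linkbox_schema_error = function(e) {
      data.frame(row = NA_integer_, field = "(schema)",
                 issue = conditionMessage(e), stringsAsFactors = FALSE)
    },
    linkbox_key_error = function(e) {
      data.frame(row = NA_integer_, field = "(key)",
                 issue = conditionMessage(e), stringsAsFactors = FALSE)
    }
  )
  res <- res[order(res$row, res$field), , drop = FALSE]
  rownames(res) <- NULL
  res
}
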