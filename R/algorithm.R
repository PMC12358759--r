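# The deterministic scoring cascade.
#
# A match algorithm is an ordered list of levels. Each level pairs a name
# rule with a set of required non-name variables and carries an integer
# score; levels that accept alias names carry a second score, one point
# lower, used when the cohort name agrees with an alias rather than the
# registry person-view name. Scoring a pair walks the cascade from the top
# and returns the first (highest) level whose criteria all hold.

NAME_RULES <- c("FULL_NAME", "LAST_ONLY", "LAST_PLUS_FIRST6", "NONE")
MATCH_VARS <- c("COHORT_ID", "DOB", "SSN_FULL", "SSN_PARTIAL", "BIRTH_SEX")

#' Normalize a personal name for comparison
#'
#' Upper-cases and strips whitespace, hyphens, apostrophes and periods, so
#' that "O'Brien-Smith " and "OBRIENSMITH" compare equal. Punctuation-only
#' or empty input yields `NA` (the missing token), which never satisfies a
#' name criterion.
#'
#' @param raw Character vector of names.
#' @return Character vector of normalized tokens, `NA` where degenerate.
#' @examples
#' normalize_name("O'Brien-Smith ") # "OBRIENSMITH"
#' @export
normalize_name <- function(raw) {
  x <- toupper(as.character(raw))
  x <- gsub("[[:space:]'.’-]", "", x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

match_level <- function(name_rule, required, score_pv, score_alias = NA_integer_) {
  list(name_rule = name_rule, required = required,
       score_pv = as.integer(score_pv), score_alias = as.integer(score_alias))
}

#' The default matching algorithm
#'
#' Returns the shipped 28-level cascade with its sharing threshold of 61.
#' Scores range from 20 (Cohort ID only) to 100 (person-view first and last
#' name, DOB, full SSN and birth sex, plus Cohort ID). The sixteen
#' full-name levels accept alias names at a one-point penalty.
#'
#' @return A `match_algorithm` object.
#' @seealso [score_pair()], [run_match()], [read_algorithm()]
#' @export
default_algorithm <- function() {
  fn <- function(required, pv) match_level("FULL_NAME", required, pv, pv - 1L)
  lv <- list(
    fn(c("COHORT_ID", "DOB", "SSN_FULL", "BIRTH_SEX"), 100),
    fn(c("DOB", "SSN_FULL", "BIRTH_SEX"), 98),
    fn(c("COHORT_ID", "DOB", "SSN_PARTIAL", "BIRTH_SEX"), 95),
    fn(c("DOB", "SSN_PARTIAL", "BIRTH_SEX"), 93),
    fn(c("COHORT_ID", "DOB", "SSN_FULL"), 90),
    fn(c("DOB", "SSN_FULL"), 88),
    fn(c("COHORT_ID", "DOB", "SSN_PARTIAL"), 86),
    fn(c("DOB", "SSN_PARTIAL"), 84),
    fn(c("COHORT_ID", "DOB", "BIRTH_SEX"), 82),
    fn(c("DOB", "BIRTH_SEX"), 80),
    fn(c("COHORT_ID", "DOB"), 78),
    fn(c("COHORT_ID", "SSN_FULL"), 76),
    fn(c("DOB"), 74),
    fn(c("SSN_FULL"), 72),
    fn(c("COHORT_ID", "SSN_PARTIAL"), 70),
    fn(c("SSN_PARTIAL"), 68),
    match_level("LAST_ONLY", c("COHORT_ID", "DOB", "SSN_FULL"), 66),
    match_level("LAST_ONLY", c("DOB", "SSN_FULL"), 65),
    match_level("LAST_PLUS_FIRST6", c("COHORT_ID", "DOB"), 64),
    match_level("LAST_PLUS_FIRST6", c("DOB"), 63),
    match_level("NONE", c("COHORT_ID", "DOB", "SSN_FULL"), 62),
    match_level("NONE", c("DOB", "SSN_FULL"), 61),
    match_level("LAST_ONLY", c("DOB"), 59),
    match_level("LAST_ONLY", c("COHORT_ID"), 58),
    match_level("NONE", c("COHORT_ID", "DOB", "SSN_PARTIAL"), 40),
    match_level("NONE", c("DOB", "SSN_PARTIAL"), 38),
    match_level("NONE", c("COHORT_ID", "DOB"), 30),
    match_level("NONE", c("COHORT_ID"), 20)
  )
  match_algorithm(lv, threshold = 61L)
}

#' Construct and validate a match algorithm
#'
#' @param levels List of levels, each a list with `name_rule`, `required`,
#'   `score_pv` and optional `score_alias`.
#' @param threshold Integer sharing threshold; scores at or above it are
#'   eligible for data sharing.
#' @return A validated `match_algorithm`.
#' @export
match_algorithm <- function(levels, threshold = 61L) {
  alg <- structure(list(levels = levels, threshold = as.integer(threshold)),
                   class = "match_algorithm")
  validate_algorithm(alg)
  alg
}

validate_algorithm <- function(alg) {
  lv <- alg$levels
  if (!length(lv)) condition_stop("linkbox_config_error", "algorithm has no levels")
  pv <- vapply(lv, function(l) l$score_pv, 1L)
  al <- vapply(lv, function(l) as.integer(l$score_alias), 1L)
  for (l in lv) {
    if (!l$name_rule %in% NAME_RULES)
      condition_stop("linkbox_config_error",
                     sprintf("unknown name rule '%s'", l$name_rule))
    if (length(bad <- setdiff(l$required, MATCH_VARS)))
      condition_stop("linkbox_config_error",
                     sprintf("unknown match variable '%s'", bad[1]))
    if (!is.na(l$score_alias)) {
      if (l$name_rule != "FULL_NAME")
        condition_stop("linkbox_config_error",
                       "alias scores are only defined for FULL_NAME levels")
      if (l$score_alias != l$score_pv - 1L)
        condition_stop("linkbox_config_error",
                       "alias score must be person-view score minus 1")
    }
  }
  scores <- c(pv, al[!is.na(al)])
  if (anyDuplicated(scores))
    condition_stop("linkbox_config_error", "duplicate scores across levels")
  if (any(scores < 20L | scores > 100L))
    condition_stop("linkbox_config_error", "scores must lie in [20, 100]")
  if (is.unsorted(rev(pv), strictly = TRUE))
    condition_stop("linkbox_config_error",
                   "levels must be in strictly descending score order")
  if (!alg$threshold %in% scores && !alg$threshold %in% (scores + 1L))
    warning("threshold does not coincide with a defined score")
  invisible(alg)
}

#' @export
print.match_algorithm <- function(x, ...) {
  cat(sprintf("<match_algorithm> %d levels, threshold %d\n",
              length(x$levels), x$threshold))
  for (l in x$levels) {
    cat(sprintf("  %3d%s  %-16s %s\n", l$score_pv,
                if (!is.na(l$score_alias)) sprintf("/%d", l$score_alias) else "   ",
                l$name_rule, paste(l$required, collapse = "+")))
  }
  invisible(x)
}

level_description <- function(level) {
  paste0(level$name_rule, " / ",
         if (length(level$required)) paste(level$required, collapse = "+")
         else "none")
}

#' Read or write an algorithm as JSON
#'
#' The editable on-disk form of the cascade:
#' `{"threshold": 61, "levels": [{"name_rule": ..., "required": [...],
#' "score_pv": ..., "score_alias": ...}, ...]}`.
#'
#' @param path JSON file path.
#' @return `read_algorithm()` a `match_algorithm`; `write_algorithm()` the
#'   path, invisibly.
#' @export
read_algorithm <- function(path) {
  if (!file.exists(path))
    condition_stop("linkbox_config_error",
                   sprintf("algorithm file not found: %s", path))
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lv <- lapply(j$levels, function(l) {
    match_level(l$name_rule, unlist(l$required), l$score_pv,
                if (is.null(l$score_alias)) NA_integer_ else l$score_alias)
  })
  match_algorithm(lv, threshold = j$threshold)
}

#' @rdname read_algorithm
#' @param alg A `match_algorithm`.
#' @export
write_algorithm <- function(alg, path) {
  lv <- lapply(alg$levels, function(l) {
    out <- list(name_rule = l$name_rule, required = as.list(l$required),
                score_pv = l$score_pv)
    if (!is.na(l$score_alias)) out$score_alias <- l$score_alias
    out
  })
  jsonlite::write_json(list(threshold = alg$threshold, levels = lv), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' All scores defined by an algorithm
#' @param alg A `match_algorithm`.
#' @return Sorted integer vector of every defined score (alias scores included).
#' @export
algorithm_scores <- function(alg) {
  pv <- vapply(alg$levels, function(l) l$score_pv, 1L)
  al <- vapply(alg$levels, function(l) as.integer(l$score_alias), 1L)
  sort(unique(c(pv, al[!is.na(al)])))
}
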