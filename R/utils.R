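#' Format a percentage as the reports print it
#'
#' Computes `100 * num / den` and formats it with one decimal place using
#' round-half-up (so 92.95 prints as "93.0", not banker's rounding). This is
#' the convention used throughout the summary outputs.
#'
#' @param num Numerator (count).
#' @param den Denominator (count); must be positive.
#' @return Character scalar such as `"93.0"`.
#' @examples
#' format_pct(9060, 9744) # "93.0"
#' format_pct(4315, 8028) # "53.7"
#' @export
format_pct <- function(num, den) {
  stopifnot(length(num) == length(den), all(den > 0))
  x <- 100 * num / den
  # round half up at one decimal; nudge by an epsilon to defeat binary
  # representation artifacts (e.g. 53.75 stored as 53.74999...)
  r <- floor(x * 10 + 0.5 + 1e-9) / 10
  sprintf("%.1f", r)
}

#' @rdname format_pct
#' @return `pct_value()` returns the rounded numeric value instead of a string.
#' @export
pct_value <- function(num, den) {
  as.numeric(format_pct(num, den))
}

# strict ISO-8601 date parser: returns Date, NA where invalid
parse_iso_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y-%m-%d")
    # as.Date("2020-02-31") -> NA already; keep NA for those
    out[ok] <- d
  }
  out
}

iso <- function(d) {
  ifelse(is.na(d), NA_character_, format(d, "%Y-%m-%d"))
}

# empty cell -> NA; everything internal uses NA as the single missing token
blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}

na_to_blank <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

condition_stop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "linkbox_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
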