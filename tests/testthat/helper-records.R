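# Builders for minimal typed records, used across the suite.

mk_cohort <- function(cohort_id = "C000001", first = "John", last = "Smith",
                      dob = "1970-01-15", ssn = "912345678",
                      birth_sex = "M", site_id = "S01") {
  data.frame(cohort_id = cohort_id, site_id = site_id, first_name = first,
             last_name = last, dob = as.Date(dob), ssn = ssn,
             birth_sex = birth_sex, stringsAsFactors = FALSE)
}

mk_surv <- function(person_id = "P000001", first = "John", last = "Smith",
                    dob = "1970-01-15", ssn = "912345678", birth_sex = "M",
                    prior_cohort_id = NA_character_, aliases = NULL) {
  if (is.null(aliases)) {
    aliases <- data.frame(first_name = character(), last_name = character(),
                          stringsAsFactors = FALSE)
  }
  out <- data.frame(person_id = person_id, first_name = first,
                    last_name = last, stringsAsFactors = FALSE)
  out$aliases <- I(list(aliases))
  out$dob <- as.Date(dob)
  out$ssn <- ssn
  out$birth_sex <- birth_sex
  out$prior_cohort_id <- prior_cohort_id
  out
}

# a pair disagreeing on every matching variable relative to mk_cohort()
mk_surv_disjoint <- function(person_id = "P000009") {
  mk_surv(person_id = person_id, first = "Xavier", last = "Quintero",
          dob = "1955-06-06", ssn = "987650000", birth_sex = "F")
}

write_feed_csv <- function(lines, path) {
  writeLines(lines, path)
  path
}

site_csv_lines <- function(rows) {
  c("cohort_id,site_id,first_name,last_name,dob,ssn,birth_sex", rows)
}

surv_csv_lines <- function(rows) {
  c(paste0("person_id,first_name,last_name,aliases,dob,ssn,birth_sex,",
           "prior_cohort_id,vital_status,gender,sex_at_birth,race,",
           "hiv_transmission_risk,state_of_residence,hiv_diagnosis_date,",
           "aids_diagnosis_date,labs,opportunistic_infections,death_date,",
           "cause_of_death"), rows)
}

mk_labs <- function(dates, types, results, interps = NULL, facility = NA) {
  n <- length(dates)
  if (is.null(interps)) interps <- rep("EQ", n)
  data.frame(sample_date = as.Date(dates), lab_type = types,
             result = results, interpretation = interps,
             facility = rep_len(facility, n), stringsAsFactors = FALSE)
}
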