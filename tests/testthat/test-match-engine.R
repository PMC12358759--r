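# Name normalization, the default cascade, pair scoring and best-match
# selection.

test_that("name normalization folds case and strips punctuation", {
  expect_equal(normalize_name("O'Brien-Smith "), "OBRIENSMITH")
  expect_equal(normalize_name("smith"), normalize_name("SMITH"))
  expect_equal(normalize_name("St. John"), "STJOHN")
  expect_true(is.na(normalize_name("---")))
  expect_true(is.na(normalize_name("")))
})

test_that("the default cascade has 28 levels with the published scores", {
  alg <- default_algorithm()
  expect_length(alg$levels, 28L)
  expect_equal(alg$threshold, 61L)
  pv <- vapply(alg$levels, function(l) l$score_pv, 1L)
  expect_equal(range(pv), c(20L, 100L))
  expect_equal(pv[1:5], c(100L, 98L, 95L, 93L, 90L))
  expect_equal(sort(pv[pv < 61]), c(20L, 30L, 38L, 40L, 58L, 59L))
  # alias score = person-view score - 1, on full-name levels only
  for (l in alg$levels) {
    if (l$name_rule == "FULL_NAME") expect_equal(l$score_alias, l$score_pv - 1L)
    else expect_true(is.na(l$score_alias))
  }
  # every level requires at least one blocking variable, so blocking on
  # cohort ID / DOB / last-4 SSN loses nothing
  for (l in alg$levels) {
    expect_true(any(c("COHORT_ID", "DOB", "SSN_FULL", "SSN_PARTIAL")
                    %in% l$required))
  }
})

test_that("algorithm JSON round trip preserves the cascade", {
  p <- withr::local_tempfile(fileext = ".json")
  alg <- default_algorithm()
  write_algorithm(alg, p)
  back <- read_algorithm(p)
  expect_equal(back$threshold, alg$threshold)
  expect_equal(back$levels, alg$levels)
})

test_that("invalid cascades are rejected", {
  lv <- default_algorithm()$levels
  lv[[2]]$score_pv <- 100L  # duplicate score
  expect_error(match_algorithm(lv), class = "linkbox_config_error")
  lv <- default_algorithm()$levels
  lv[[1]]$score_alias <- 95L  # wrong alias spacing
  expect_error(match_algorithm(lv), class = "linkbox_config_error")
})

test_that("scoring endpoints: full agreement 100, cohort-ID only 20, DOB+SSN 61", {
  co <- mk_cohort()
  full <- mk_surv(prior_cohort_id = "C000001")
  r <- score_pair(co, full)
  expect_equal(r$score, 100L)
  expect_equal(r$name_source, "person_view")
  expect_true(r$shared)

  id_only <- mk_surv_disjoint()
  id_only$prior_cohort_id <- "C000001"
  r <- score_pair(co, id_only)
  expect_equal(r$score, 20L)
  expect_false(r$shared)

  dob_ssn <- mk_surv_disjoint()
  dob_ssn$dob <- as.Date("1970-01-15")
  dob_ssn$ssn <- "912345678"
  dob_ssn$birth_sex <- NA_character_
  r <- score_pair(co, dob_ssn)
  expect_equal(r$score, 61L)
  expect_true(r$shared)
  expect_equal(r$name_source, "none")
})

test_that("alias agreement scores one point below person view", {
  co <- mk_cohort(first = "Jon", last = "Smyth")
  sv <- mk_surv(first = "John", last = "Smith", prior_cohort_id = "C000001",
                aliases = data.frame(first_name = "Jon", last_name = "Smyth",
                                     stringsAsFactors = FALSE))
  r <- score_pair(co, sv)
  expect_equal(r$score, 99L)
  expect_equal(r$name_source, "alias")
  # person view checked first and wins at equal level
  sv_pv <- mk_surv(first = "Jon", last = "Smyth", prior_cohort_id = "C000001",
                   aliases = data.frame(first_name = "Jon",
                                        last_name = "Smyth",
                                        stringsAsFactors = FALSE))
  r <- score_pair(co, sv_pv)
  expect_equal(r$score, 100L)
  expect_equal(r$name_source, "person_view")
})

test_that("alias penalty is exactly one point at every full-name level", {
  # drop agreeing variables one at a time and compare pv vs alias variant
  variable_sets <- list(
    c("dob", "ssn", "sex", "cid"), c("dob", "ssn", "sex"),
    c("dob", "ssn", "cid"), c("dob", "ssn"), c("dob", "sex", "cid"),
    c("dob", "sex"), c("dob", "cid"), c("dob"), c("ssn", "cid"), c("ssn"))
  for (vars in variable_sets) {
    build <- function(alias) {
      sv <- mk_surv_disjoint()
      if (alias) {
        sv$aliases <- I(list(data.frame(first_name = "John",
                                        last_name = "Smith",
                                        stringsAsFactors = FALSE)))
      } else {
        sv$first_name <- "John"; sv$last_name <- "Smith"
      }
      if ("dob" %in% vars) sv$dob <- as.Date("1970-01-15")
      if ("ssn" %in% vars) sv$ssn <- "912345678"
      if ("sex" %in% vars) sv$birth_sex <- "M" else sv$birth_sex <- NA
      if ("cid" %in% vars) sv$prior_cohort_id <- "C000001"
      sv
    }
    co <- mk_cohort()
    r_pv <- score_pair(co, build(alias = FALSE))
    r_al <- score_pair(co, build(alias = TRUE))
    expect_equal(r_al$score, r_pv$score - 1L,
                 info = paste(vars, collapse = "+"))
    expect_equal(r_al$name_source, "alias")
  }
})

test_that("adding an agreeing field never lowers the score", {
  co <- mk_cohort()
  base <- mk_surv_disjoint()
  base$dob <- as.Date("1970-01-15")   # start from DOB-only agreement
  adds <- list(
    function(s) { s$ssn <- "912345678"; s },
    function(s) { s$birth_sex <- "M"; s },
    function(s) { s$prior_cohort_id <- "C000001"; s },
    function(s) { s$first_name <- "John"; s$last_name <- "Smith"; s })
  sc <- function(sv) {
    r <- score_pair(co, sv)
    if (is.null(r)) 0L else r$score   # no-match sits below every level
  }
  for (ord in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    sv <- base
    prev <- sc(sv)
    for (k in ord) {
      sv <- adds[[k]](sv)
      cur <- sc(sv)
      expect_gte(cur, prev)
      prev <- cur
    }
    expect_equal(prev, 100L)
  }
})

test_that("partial SSN rules: last-4 equality, 4-digit stores, full dominates", {
  co <- mk_cohort(ssn = "5678")                   # partial store
  sv <- mk_surv(ssn = "912345678", prior_cohort_id = "C000001")
  r <- score_pair(co, sv)
  expect_equal(r$score, 95L)                      # partial SSN level, not full
  co9 <- mk_cohort(ssn = "912345678")
  expect_equal(score_pair(co9, sv)$score, 100L)   # full-SSN row dominates
  # different 9-digit SSNs sharing last 4 satisfy partial only
  co_diff <- mk_cohort(ssn = "990005678")
  expect_equal(score_pair(co_diff, sv)$score, 95L)
  # missing SSN on one side satisfies neither
  co_na <- mk_cohort(ssn = NA_character_)
  expect_equal(score_pair(co_na, sv)$score, 82L)  # name+CID+DOB+sex
})

test_that("last-name-only and first-6 levels use the person view only", {
  # last name agrees, first differs beyond 6 letters, DOB+SSN agree
  co <- mk_cohort(first = "Walter")
  sv <- mk_surv(first = "Gregory", prior_cohort_id = "C000001")
  expect_equal(score_pair(co, sv)$score, 66L)
  # first 6 letters agree: ROBERT vs ROBERTA
  co6 <- mk_cohort(first = "Roberta", ssn = NA_character_)
  sv6 <- mk_surv(first = "Robert", ssn = NA_character_,
                 prior_cohort_id = "C000001")
  expect_equal(score_pair(co6, sv6)$score, 64L)
  # an alias never feeds the last-only rule: alias last name match + DOB+SSN
  co_al <- mk_cohort(first = "Walter", last = "Jonson")
  sv_al <- mk_surv(first = "Gregory", last = "Smith",
                   aliases = data.frame(first_name = "Henry",
                                        last_name = "Jonson",
                                        stringsAsFactors = FALSE))
  expect_equal(score_pair(co_al, sv_al)$score, 61L)  # DOB+SSN, no name
})

test_that("records sharing nothing (or only a name) are unscorable", {
  co <- mk_cohort()
  expect_null(score_pair(co, mk_surv_disjoint()))
  name_only <- mk_surv_disjoint()
  name_only$first_name <- "John"; name_only$last_name <- "Smith"
  expect_null(score_pair(co, name_only))
})

test_that("candidate generation blocks on cohort ID, DOB and SSN last-4", {
  co <- rbind(mk_cohort("C1", dob = "1970-01-15", ssn = NA_character_),
              mk_cohort("C2", dob = "1980-02-02", ssn = "911112222"),
              mk_cohort("C3", dob = "1990-03-03", ssn = NA_character_))
  sv <- rbind(mk_surv("P1", dob = "1970-01-15", ssn = "955554444"),
              mk_surv("P2", dob = "1999-09-09", ssn = "900002222"),
              mk_surv("P3", dob = "1955-05-05", ssn = NA_character_,
                      prior_cohort_id = "C3"))
  cand <- generate_candidates(co, sv)
  expect_setequal(paste(cand$cohort_id, cand$person_id),
                  c("C1 P1", "C2 P2", "C3 P3"))
  # sharing only a last name is not a candidate -- and provably unscorable
  co_n <- mk_cohort("C9", last = "Zeta", dob = "1960-01-01",
                    ssn = NA_character_)
  sv_n <- mk_surv("P9", last = "Zeta", dob = "1961-01-01",
                  ssn = NA_character_)
  expect_equal(nrow(generate_candidates(co_n, sv_n)), 0L)
  expect_null(score_pair(co_n, sv_n))
  # disjoint key sets give an empty candidate set
  expect_equal(nrow(generate_candidates(mk_cohort(ssn = NA_character_),
                                        mk_surv_disjoint())), 0L)
})

test_that("best match is kept per cohort record; ties flagged deterministically", {
  co <- mk_cohort("C1")
  sv <- rbind(mk_surv("P1", first = "Other", last = "Name"),  # DOB+SSN+sex
              mk_surv("P2"))                                  # full name too
  res <- run_match(co, sv)
  expect_equal(nrow(res), 1L)
  expect_equal(res$person_id, "P2")
  expect_equal(res$score, 98L)
  expect_false(res$tie_flag)
  # identical twins in the registry: equal scores, smallest person_id wins
  sv_tie <- rbind(mk_surv("P2"), mk_surv("P1"))
  res <- run_match(co, sv_tie)
  expect_equal(res$person_id, "P1")
  expect_true(res$tie_flag)
  # two cohort records may map to one person
  co2 <- rbind(mk_cohort("C1"), mk_cohort("C2", site_id = "S02"))
  res <- run_match(co2, rbind(mk_surv("P1")))
  expect_equal(res$person_id, c("P1", "P1"))
  expect_equal(res$cohort_id, c("C1", "C2"))
})

test_that("blocked matching equals exhaustive matching on simulated feeds", {
  for (s in c(2, 5)) {
    sim <- simulate_feeds(sim_config(n_persons = 120, seed = s))
    flt <- reconcile(sim$central, sim$site)
    blocked <- run_match(flt$eligible, sim$surveillance)
    full <- run_match(flt$eligible, sim$surveillance, exhaustive = TRUE)
    expect_identical(blocked, full)
  }
})

test_that("matching output is deterministic across repeated runs", {
  sim <- simulate_feeds(sim_config(n_persons = 80, seed = 13))
  flt <- reconcile(sim$central, sim$site)
  r1 <- run_match(flt$eligible, sim$surveillance)
  r2 <- run_match(flt$eligible, sim$surveillance)
  expect_identical(r1, r2)
})
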