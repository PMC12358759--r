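# Demographics discrepancy rules, lab-group coding and percentage
# formatting.

prof <- function(...) {
  defaults <- list(vital_status = "alive", gender = "male",
                   sex_at_birth = "M", race = "Black",
                   hiv_transmission_risk = "MSM", state_of_residence = "DC",
                   hiv_diagnosis_date = as.Date("2010-03-01"),
                   aids_diagnosis_date = as.Date(NA))
  mod <- list(...)
  defaults[names(mod)] <- mod
  as.data.frame(defaults, stringsAsFactors = FALSE)
}

test_that("identical profiles yield no discrepancy rows", {
  expect_equal(nrow(compare_demographics(prof(), prof())), 0L)
})

test_that("conflicting values produce one row carrying both values", {
  d <- compare_demographics(prof(hiv_diagnosis_date = as.Date("2010-03-01")),
                            prof(hiv_diagnosis_date = as.Date("2009-11-15")))
  expect_equal(nrow(d), 1L)
  expect_equal(d$field, "hiv_diagnosis_date")
  expect_equal(d$kind, "conflict")
  expect_equal(d$cohort_value, "2010-03-01")
  expect_equal(d$surveillance_value, "2009-11-15")
})

test_that("one-sided missingness is typed by the missing side", {
  d <- compare_demographics(prof(race = NA_character_), prof())
  expect_equal(d$kind, "missing_in_cohort")
  d <- compare_demographics(prof(), prof(race = NA_character_))
  expect_equal(d$kind, "missing_in_surveillance")
  # missing on both sides is not a discrepancy
  expect_equal(nrow(compare_demographics(prof(race = NA_character_),
                                         prof(race = NA_character_))), 0L)
})

test_that("comparison canonicalizes case and whitespace, not the report", {
  d <- compare_demographics(prof(race = " black "), prof(race = "Black"))
  expect_equal(nrow(d), 0L)
  d <- compare_demographics(prof(gender = "Male"), prof(gender = "male"))
  expect_equal(nrow(d), 0L)
})

test_that("unknown field names are a configuration error; absent fields typed", {
  expect_error(compare_demographics(prof(), prof(), fields = "shoe_size"),
               class = "linkbox_config_error")
  p <- prof(); p$race <- NULL
  d <- compare_demographics(p, prof(), fields = "race")
  expect_equal(d$kind, "absent_field")
})

test_that("lab pairs are coded by which variables agree", {
  consent <- as.Date("2015-01-01")
  cl <- mk_labs("2016-01-05", "CD4_count", 200)
  # identical record both sides -> DUPLICATE, in neither new list
  cmp <- compare_labs(cl, mk_labs("2016-01-05", "CD4_count", 200), consent)
  expect_equal(cmp$coded$lab_group, "DUPLICATE")
  expect_equal(nrow(cmp$new_to_cohort), 0L)
  expect_equal(nrow(cmp$new_to_surveillance), 0L)
  # same date/type, results 200 vs 210
  cmp <- compare_labs(cl, mk_labs("2016-01-05", "CD4_count", 210), consent)
  expect_equal(cmp$coded$lab_group, "RESULT_DIFF")
  # result agrees, interpretation differs
  cmp <- compare_labs(cl, mk_labs("2016-01-05", "CD4_count", 200, "LT"),
                      consent)
  expect_equal(cmp$coded$lab_group, "RESULT_INTERP_DIFF")
  # trailing zeros are immaterial: 200 vs 200.0
  cmp <- compare_labs(cl, mk_labs("2016-01-05", "CD4_count", 200.0), consent)
  expect_equal(cmp$coded$lab_group, "DUPLICATE")
})

test_that("labs on or before the consent date are excluded entirely", {
  consent <- as.Date("2015-01-01")
  sv <- mk_labs(c("2014-12-31", "2015-01-01", "2015-01-02"),
                rep("viral_load", 3), c(500, 600, 700))
  cmp <- compare_labs(empty_cohort_labs <- mk_labs(character(0),
                                                   character(0), numeric(0)),
                      sv, consent)
  # strictly-after rule: only the Jan 2 lab survives, as new to the cohort
  expect_equal(nrow(cmp$new_to_cohort), 1L)
  expect_equal(cmp$new_to_cohort$result, 700)
})

test_that("unpaired labs are NEW to the side lacking them", {
  consent <- as.Date("2015-01-01")
  cl <- mk_labs(c("2016-01-05", "2016-02-01"), c("CD4_count", "viral_load"),
                c(300, 1000))
  sv <- mk_labs("2016-01-05", "CD4_count", 300)
  cmp <- compare_labs(cl, sv, consent)
  expect_equal(cmp$coded$lab_group, "DUPLICATE")
  expect_equal(nrow(cmp$new_to_surveillance), 1L)
  expect_equal(cmp$new_to_surveillance$lab_type, "viral_load")
})

test_that("same-day duplicates pair greedily in result order; leftovers NEW", {
  consent <- as.Date("2015-01-01")
  cl <- mk_labs(rep("2016-01-05", 2), rep("CD4_count", 2), c(250, 200))
  sv <- mk_labs(rep("2016-01-05", 3), rep("CD4_count", 3), c(200, 260, 250))
  cmp <- compare_labs(cl, sv, consent)
  expect_equal(nrow(cmp$coded), 2L)
  expect_equal(cmp$coded$cohort_result, c(200, 250))
  expect_equal(cmp$coded$surv_result, c(200, 250))
  expect_equal(cmp$coded$lab_group, c("DUPLICATE", "DUPLICATE"))
  expect_equal(cmp$new_to_cohort$result, 260)
})

test_that("lab conservation holds on simulated matched pairs", {
  sim <- simulate_feeds(sim_config(n_persons = 120, seed = 41))
  flt <- reconcile(sim$central, sim$site)
  res <- run_match(flt$eligible, sim$surveillance)
  shared <- res[res$shared, ][1:20, ]
  for (i in seq_len(nrow(shared))) {
    ei <- match(shared$cohort_id[i], flt$eligible$cohort_id)
    si <- match(shared$person_id[i], sim$surveillance$person_id)
    consent <- flt$eligible$consent_date[ei]
    cl <- flt$eligible$labs[[ei]]
    sl <- sim$surveillance$labs[[si]]
    cmp <- compare_labs(cl, sl, consent)
    n_cl_after <- sum(cl$sample_date > consent)
    n_sl_after <- sum(sl$sample_date > consent)
    expect_equal(n_cl_after, nrow(cmp$coded) + nrow(cmp$new_to_surveillance))
    expect_equal(n_sl_after, nrow(cmp$coded) + nrow(cmp$new_to_cohort))
  }
})

test_that("percentages format round-half-up to one decimal", {
  expect_equal(format_pct(9060, 9744), "93.0")
  expect_equal(format_pct(9257, 9378), "98.7")
  expect_equal(format_pct(105, 121), "86.8")
  expect_equal(format_pct(4315, 8028), "53.7")
  expect_equal(format_pct(1, 16), "6.3")     # 6.25 rounds up, not to even
  expect_equal(format_pct(1, 1), "100.0")
})
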