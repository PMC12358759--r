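# Report construction, recipient redaction and the end-to-end pipeline.

run_small <- function(seed = 61, n = 100, cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(n_persons = n, seed = seed)
  sim <- simulate_feeds(cfg)
  flt <- reconcile(sim$central, sim$site)
  res <- run_match(flt$eligible, sim$surveillance)
  list(sim = sim, flt = flt, res = res,
       clusters = cluster_by_person(res, flt$site_rows),
       inputs = list(filter = flt, results = res,
                     surveillance = sim$surveillance,
                     clusters = cluster_by_person(res, flt$site_rows),
                     threshold = 61L))
}

test_that("match report redacts identifiers for the cohort recipient", {
  rs <- run_small()
  cohort_tab <- build_report("match", "cohort", rs$inputs)
  expect_equal(names(cohort_tab), c("cohort_id", "score"))
  hd_tab <- build_report("match", "health_dept", rs$inputs)
  expect_true(all(c("person_id", "surv_ssn", "cohort_dob") %in% names(hd_tab)))
  expect_equal(nrow(cohort_tab), nrow(rs$res))  # any score level, even < 61
})

test_that("cohort_unmatched combines filter exclusions with non-matches", {
  rs <- run_small()
  tab <- build_report("cohort_unmatched", "cohort", rs$inputs)
  expect_setequal(tab$cohort_id,
                  c(rs$flt$central_only,
                    setdiff(rs$flt$eligible$cohort_id, rs$res$cohort_id)))
  expect_setequal(unique(tab$reason),
                  intersect(c("not_in_site_files", "no_surveillance_match"),
                            tab$reason))
  expect_true(all(tab$cohort_id[tab$reason == "not_in_site_files"]
                  %in% rs$flt$central_only))
})

test_that("multi-site report lists clusters; person_id only for health dept", {
  rs <- run_small()
  ct <- build_report("multi_site", "cohort", rs$inputs)
  hd <- build_report("multi_site", "health_dept", rs$inputs)
  expect_false("person_id" %in% names(ct))
  expect_true("person_id" %in% names(hd))
  expect_equal(nrow(ct), sum(rs$clusters$n_cohort_ids >= 2))
  expect_equal(nrow(ct), nrow(hd))
})

test_that("treatment report is refused for the cohort recipient", {
  rs <- run_small()
  expect_error(build_report("treatment", "cohort", rs$inputs),
               class = "linkbox_redaction_error")
  hd <- build_report("treatment", "health_dept", rs$inputs)
  expect_true(all(c("cohort_id", "person_id", "drug") %in% names(hd)))
  expect_true(all(hd$cohort_id %in% rs$res$cohort_id[rs$res$shared]))
})

test_that("demographics report covers shared matches only, one row per finding", {
  rs <- run_small()
  tab <- build_report("demographics", "cohort", rs$inputs)
  shared_ids <- rs$res$cohort_id[rs$res$shared]
  expect_true(all(tab$cohort_id %in% shared_ids))
  expect_true(all(tab$kind %in% c("missing_in_cohort",
                                  "missing_in_surveillance", "conflict",
                                  "absent_field")))
  # no identifier fields ever compared
  expect_false(any(tab$field %in% c("first_name", "last_name", "dob", "ssn")))
})

test_that("oi and lab_site reports carry registry payloads per cohort id", {
  rs <- run_small()
  oi <- build_report("oi", "cohort", rs$inputs)
  shared_ids <- rs$res$cohort_id[rs$res$shared]
  expect_true(all(oi$cohort_id %in% shared_ids))
  ls <- build_report("lab_site", "cohort", rs$inputs)
  expect_true(all(ls$cohort_id %in% shared_ids))
  expect_true(all(ls$facility %in% paste("Facility", LETTERS[1:12])))
})

test_that("pipeline runs end to end, writes a manifest, and is deterministic", {
  td <- withr::local_tempdir()
  sim <- simulate_feeds(sim_config(n_persons = 80, seed = 71),
                        out_dir = file.path(td, "data"))
  tpl <- list(inputs = list(site = file.path(td, "data", "site.csv"),
                            central = file.path(td, "data", "central.csv"),
                            surveillance = file.path(td, "data",
                                                     "surveillance.csv")),
              truth = file.path(td, "data", "ground_truth.csv"),
              out_dir = file.path(td, "out1"))
  m1 <- run_pipeline(tpl, quiet = TRUE)
  expect_true(file.exists(file.path(td, "out1", "manifest.json")))
  expect_equal(m1$counts$eligible, nrow(reconcile(sim$central, sim$site)$eligible))
  expect_gt(length(m1$reports), 10)
  # rerun into a second directory: byte-identical reports
  tpl$out_dir <- file.path(td, "out2")
  run_pipeline(tpl, quiet = TRUE)
  rels <- grep("\\.csv$",
               list.files(file.path(td, "out1"), recursive = TRUE),
               value = TRUE)
  for (f in rels) {
    expect_identical(readLines(file.path(td, "out1", f)),
                     readLines(file.path(td, "out2", f)), info = f)
  }
})

test_that("pipeline aborts on verification failure unless forced", {
  td <- withr::local_tempdir()
  simulate_feeds(sim_config(n_persons = 20, seed = 73),
                 out_dir = file.path(td, "data"))
  # corrupt one site SSN to 8 digits
  sp <- file.path(td, "data", "site.csv")
  lines <- readLines(sp)
  lines[2] <- sub("\"9(\\d{8})\"", "\"\\1\"", lines[2])
  writeLines(lines, sp)
  tpl <- list(inputs = list(site = sp,
                            central = file.path(td, "data", "central.csv"),
                            surveillance = file.path(td, "data",
                                                     "surveillance.csv")),
              out_dir = file.path(td, "out"))
  err <- expect_error(run_pipeline(tpl, quiet = TRUE),
                      class = "linkbox_verify_error")
  expect_match(conditionMessage(err), "site.csv")
  expect_silent(run_pipeline(tpl, force = TRUE, quiet = TRUE))
})

test_that("empty surveillance feed completes with an empty match report", {
  td <- withr::local_tempdir()
  sim <- simulate_feeds(sim_config(n_persons = 30, seed = 79,
                                   surveillance_coverage = 0),
                        out_dir = file.path(td, "data"))
  tpl <- list(inputs = list(site = file.path(td, "data", "site.csv"),
                            central = file.path(td, "data", "central.csv"),
                            surveillance = file.path(td, "data",
                                                     "surveillance.csv")),
              out_dir = file.path(td, "out"))
  m <- run_pipeline(tpl, quiet = TRUE)
  expect_equal(m$counts$shared, 0L)
  match_tab <- utils::read.csv(file.path(td, "out", "cohort", "match.csv"))
  expect_equal(nrow(match_tab), 0L)
  um <- utils::read.csv(file.path(td, "out", "cohort", "unmatched.csv"))
  expect_equal(nrow(um), m$counts$eligible)
})

test_that("a missing algorithm file aborts with a config error", {
  td <- withr::local_tempdir()
  simulate_feeds(sim_config(n_persons = 10, seed = 83),
                 out_dir = file.path(td, "data"))
  tpl <- list(inputs = list(site = file.path(td, "data", "site.csv"),
                            central = file.path(td, "data", "central.csv"),
                            surveillance = file.path(td, "data",
                                                     "surveillance.csv")),
              algorithm = file.path(td, "nope.json"),
              out_dir = file.path(td, "out"))
  expect_error(run_pipeline(tpl, quiet = TRUE), class = "linkbox_config_error")
})

test_that("threshold override must be a defined score and changes sharing", {
  td <- withr::local_tempdir()
  simulate_feeds(sim_config(n_persons = 40, seed = 89),
                 out_dir = file.path(td, "data"))
  tpl <- list(inputs = list(site = file.path(td, "data", "site.csv"),
                            central = file.path(td, "data", "central.csv"),
                            surveillance = file.path(td, "data",
                                                     "surveillance.csv")),
              threshold = 95, out_dir = file.path(td, "out"))
  m <- run_pipeline(tpl, quiet = TRUE)
  expect_equal(m$algorithm$threshold, 95L)
  expect_lte(m$counts$shared, m$counts$scored)
  tpl$threshold <- 60  # not a defined score
  tpl$out_dir <- file.path(td, "out2")
  expect_error(run_pipeline(tpl, quiet = TRUE), class = "linkbox_config_error")
})
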