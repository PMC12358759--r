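# End-to-end orchestration: verify -> filter -> match -> dedup -> reports
# (-> optional validation), driven by a project template. Stage outputs
# are materialized to disk so a run can be audited file by file; recipient
# directories contain only what that recipient may see, and the log never
# prints identifier values.

# Table of report kinds and who receives them
default_report_plan <- function() {
  data.frame(
    kind = c("filter", "match", "unmatched", "cohort_unmatched",
             "multi_site", "demographics", "labs", "lab_site", "oi",
             "match", "unmatched", "multi_site", "demographics", "labs",
             "treatment", "filter"),
    recipient = c(rep("cohort", 9), rep("health_dept", 7)),
    stringsAsFactors = FALSE)
}

#' Read a project template
#'
#' A template is a YAML (or in-memory list) analog of the administrator's
#' project file: it binds input paths (and optional column-name mappings),
#' names the algorithm file, may override the sharing threshold, selects
#' reports, and sets the output directory.
#'
#' Fields: `inputs` (`site`: one path or a list, `central`,
#' `surveillance`), optional `columns` (per-feed name mappings),
#' optional `algorithm` (JSON path; shipped default when absent), optional
#' `threshold` (must be a score the algorithm defines), optional `truth`
#' (ground-truth CSV; enables the validation stage), `out_dir`, optional
#' `reports` (list of `{kind, recipient}`; Table-of-reports default).
#'
#' @param path YAML file path.
#' @return The template as a list.
#' @export
read_template <- function(path) {
  if (!file.exists(path))
    condition_stop("linkbox_config_error",
                   sprintf("template not found: %s", path))
  yaml::read_yaml(path)
}

check_template <- function(tpl) {
  for (f in c("inputs", "out_dir")) {
    if (is.null(tpl[[f]]))
      condition_stop("linkbox_config_error",
                     sprintf("template field '%s' is required", f))
  }
  for (f in c("site", "central", "surveillance")) {
    if (is.null(tpl$inputs[[f]]))
      condition_stop("linkbox_config_error",
                     sprintf("template input '%s' is required", f))
  }
  invisible(tpl)
}

write_report_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  path
}

#' Run the full linkage pipeline
#'
#' Executes verify, filter reconciliation, matching, deduplication, report
#' generation and (when ground truth is bound) validation, materializing
#' every stage to disk under the template's output directory:
#' `out/cohort/` and `out/health_dept/` hold the recipient reports,
#' `out/stage/` the operator-side artifacts (merged eligible set, match
#' results, validation bands), and `out/manifest.json` the run manifest
#' with input digests and per-report row counts. Reruns on identical
#' inputs produce byte-identical reports.
#'
#' @param template Template list or YAML path (see [read_template()]).
#' @param force Proceed despite verification issues (they are still
#'   reported in the manifest).
#' @param quiet Suppress progress messages.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(template, force = FALSE, quiet = FALSE) {
  tpl <- if (is.character(template)) read_template(template) else template
  check_template(tpl)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  site_paths <- unlist(tpl$inputs$site)
  central_path <- tpl$inputs$central
  surv_path <- tpl$inputs$surveillance
  cmap <- tpl$columns

  # ---- verify --------------------------------------------------------------
  verification <- list()
  for (fd in list(list(p = site_paths, s = "site"),
                  list(p = central_path, s = "central"),
                  list(p = surv_path, s = "surveillance"))) {
    for (p in fd$p) {
      vrep <- verify_file(p, fd$s, cmap[[fd$s]])
      verification[[p]] <- nrow(vrep)
      if (nrow(vrep) > 0 && !force) {
        condition_stop("linkbox_verify_error",
                       sprintf("verification failed for %s: row %s, %s: %s",
                               p, vrep$row[1], vrep$field[1], vrep$issue[1]))
      }
      say("verify %-12s %s: %d issue(s)", fd$s, basename(p), nrow(vrep))
    }
  }
  tick("verify")

  # ---- read + filter -------------------------------------------------------
  site_recs <- do.call(rbind, lapply(site_paths, function(p)
    read_table(p, "site", cmap$site)$records))
  central_recs <- read_table(central_path, "central", cmap$central)$records
  surv_recs <- read_table(surv_path, "surveillance",
                          cmap$surveillance)$records
  flt <- reconcile(central_recs, site_recs)
  say("filter: %d eligible, %d central-only, %d site-only",
      nrow(flt$eligible), length(flt$central_only), length(flt$site_only))
  tick("filter")

  # ---- algorithm -----------------------------------------------------------
  alg <- if (!is.null(tpl$algorithm)) read_algorithm(tpl$algorithm)
         else default_algorithm()
  if (!is.null(tpl$threshold)) {
    thr <- as.integer(tpl$threshold)
    if (!thr %in% algorithm_scores(alg))
      condition_stop("linkbox_config_error",
                     sprintf("threshold override %d is not a defined score",
                             thr))
    alg$threshold <- thr
  }

  # ---- match + dedup -------------------------------------------------------
  results <- run_match(flt$eligible, surv_recs, alg)
  n_shared <- sum(results$shared)
  say("match: %d scored, %d shared at threshold %d",
      nrow(results), n_shared, alg$threshold)
  clusters <- cluster_by_person(results, flt$site_rows)
  ms <- multi_site_summary(clusters)
  say("dedup: %d unique persons, %d multi-site", ms$n_unique, ms$n_multi)
  tick("match")

  # ---- reports -------------------------------------------------------------
  out_dir <- tpl$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list(filter = flt, results = results, surveillance = surv_recs,
                 clusters = clusters, threshold = alg$threshold)
  plan <- if (!is.null(tpl$reports)) {
    do.call(rbind, lapply(tpl$reports, function(r)
      data.frame(kind = r$kind, recipient = r$recipient,
                 stringsAsFactors = FALSE)))
  } else default_report_plan()
  report_manifest <- list()
  for (i in seq_len(nrow(plan))) {
    kind <- plan$kind[i]; rcp <- plan$recipient[i]
    if (!kind %in% REPORT_KINDS)
      condition_stop("linkbox_config_error",
                     sprintf("unknown report kind '%s'", kind))
    if (kind == "filter") {
      # the two single-column filter report files, per the interface
      p1 <- write_report_csv(
        data.frame(cohort_id = flt$central_only, stringsAsFactors = FALSE),
        file.path(out_dir, rcp, "filter_central_only.csv"))
      p2 <- write_report_csv(
        data.frame(cohort_id = flt$site_only, stringsAsFactors = FALSE),
        file.path(out_dir, rcp, "filter_site_only.csv"))
      report_manifest[[paste(rcp, "filter_central_only", sep = "/")]] <-
        list(path = p1, rows = length(flt$central_only))
      report_manifest[[paste(rcp, "filter_site_only", sep = "/")]] <-
        list(path = p2, rows = length(flt$site_only))
    } else {
      tab <- build_report(kind, rcp, inputs)
      p <- write_report_csv(tab, file.path(out_dir, rcp,
                                           paste0(kind, ".csv")))
      report_manifest[[paste(rcp, kind, sep = "/")]] <-
        list(path = p, rows = nrow(tab))
    }
  }
  # operator-side stage artifacts
  stage_dir <- file.path(out_dir, "stage")
  dir.create(stage_dir, showWarnings = FALSE)
  res_out <- results
  write_report_csv(res_out, file.path(stage_dir, "match_results.csv"))
  if (nrow(flt$conflicts))
    write_report_csv(flt$conflicts, file.path(stage_dir, "conflicts.csv"))
  tick("reports")

  # ---- optional validation -------------------------------------------------
  validation <- NULL
  if (!is.null(tpl$truth)) {
    truth <- utils::read.csv(tpl$truth, colClasses = "character")
    truth$person_id[truth$person_id == ""] <- NA_character_
    labeled <- label_against_truth(results, truth)
    bands <- score_band_metrics(labeled)
    write_report_csv(bands, file.path(stage_dir, "validation.csv"))
    validation <- list(
      n_labeled = nrow(labeled),
      n_true = sum(labeled$label == "true_match"),
      overall_precision_pct = format_pct(
        sum(labeled$label == "true_match"), nrow(labeled)))
    say("validation: %s%% of %d matches are true",
        validation$overall_precision_pct, validation$n_labeled)
  }
  tick("validate")

  manifest <- list(
    inputs = lapply(stats::setNames(nm = c(site_paths, central_path,
                                           surv_path)),
                    function(p) list(md5 = unname(tools::md5sum(p)),
                                     verify_issues = verification[[p]])),
    algorithm = list(threshold = alg$threshold,
                     n_levels = length(alg$levels),
                     scores = algorithm_scores(alg)),
    counts = list(eligible = nrow(flt$eligible),
                  central_only = length(flt$central_only),
                  site_only = length(flt$site_only),
                  scored = nrow(results), shared = n_shared,
                  unique_persons = ms$n_unique, multi_site = ms$n_multi,
                  matched_pct = if (nrow(flt$eligible) > 0)
                    format_pct(n_shared, nrow(flt$eligible)) else NA),
    reports = report_manifest,
    validation = validation,
    timings = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
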