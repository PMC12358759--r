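# Seeded generator of linked site/central/surveillance feeds with
# ground-truth labels. It emulates the error phenomena a document-based
# surveillance registry accumulates: misspellings of first and last names,
# reversed name order captured as alias entries, DOB typos, missing or
# partial (last-4) SSNs, and Cohort IDs remembered from earlier linkage
# rounds. Identities are synthetic throughout: names come from packaged
# word pools and SSNs are drawn from the 900-prefixed range that real
# allocation never uses.

FIRST_NAMES_M <- c(
  "JAMES", "ROBERT", "JOHN", "MICHAEL", "DAVID", "WILLIAM", "RICHARD",
  "JOSEPH", "THOMAS", "CHARLES", "CHRISTOPHER", "DANIEL", "MATTHEW",
  "ANTHONY", "MARK", "DONALD", "STEVEN", "PAUL", "ANDREW", "JOSHUA",
  "KENNETH", "KEVIN", "BRIAN", "GEORGE", "TIMOTHY", "RONALD", "EDWARD",
  "JASON", "JEFFREY", "RYAN", "JACOB", "GARY", "NICHOLAS", "ERIC",
  "JONATHAN", "STEPHEN", "LARRY", "JUSTIN", "SCOTT", "BRANDON",
  "BENJAMIN", "SAMUEL", "GREGORY", "ALEXANDER", "PATRICK", "FRANK",
  "RAYMOND", "JACK", "DENNIS", "JERRY", "TYLER", "AARON", "JOSE",
  "ADAM", "NATHAN", "HENRY", "ZACHARY", "DOUGLAS", "PETER", "KYLE")

FIRST_NAMES_F <- c(
  "MARY", "PATRICIA", "JENNIFER", "LINDA", "ELIZABETH", "BARBARA",
  "SUSAN", "JESSICA", "SARAH", "KAREN", "LISA", "NANCY", "BETTY",
  "SANDRA", "MARGARET", "ASHLEY", "KIMBERLY", "EMILY", "DONNA",
  "MICHELLE", "CAROL", "AMANDA", "DOROTHY", "MELISSA", "DEBORAH",
  "STEPHANIE", "REBECCA", "SHARON", "LAURA", "CYNTHIA", "KATHLEEN",
  "AMY", "ANGELA", "SHIRLEY", "ANNA", "BRENDA", "PAMELA", "EMMA",
  "NICOLE", "HELEN", "SAMANTHA", "KATHERINE", "CHRISTINE", "DEBRA",
  "RACHEL", "CAROLYN", "JANET", "CATHERINE", "MARIA", "HEATHER",
  "DIANE", "RUTH", "JULIE", "OLIVIA", "JOYCE", "VIRGINIA", "VICTORIA",
  "KELLY", "LAUREN", "CHRISTINA")

LAST_NAMES <- c(
  "SMITH", "JOHNSON", "WILLIAMS", "BROWN", "JONES", "GARCIA", "MILLER",
  "DAVIS", "RODRIGUEZ", "MARTINEZ", "HERNANDEZ", "LOPEZ", "GONZALEZ",
  "WILSON", "ANDERSON", "THOMAS", "TAYLOR", "MOORE", "JACKSON",
  "MARTIN", "LEE", "PEREZ", "THOMPSON", "WHITE", "HARRIS", "SANCHEZ",
  "CLARK", "RAMIREZ", "LEWIS", "ROBINSON", "WALKER", "YOUNG", "ALLEN",
  "KING", "WRIGHT", "SCOTT", "TORRES", "NGUYEN", "HILL", "FLORES",
  "GREEN", "ADAMS", "NELSON", "BAKER", "HALL", "RIVERA", "CAMPBELL",
  "MITCHELL", "CARTER", "ROBERTS", "GOMEZ", "PHILLIPS", "EVANS",
  "TURNER", "DIAZ", "PARKER", "CRUZ", "EDWARDS", "COLLINS", "REYES",
  "STEWART", "MORRIS", "MORALES", "MURPHY", "COOK", "ROGERS",
  "GUTIERREZ", "ORTIZ", "MORGAN", "COOPER", "PETERSON", "BAILEY",
  "REED", "KELLY", "HOWARD", "RAMOS", "KIM", "COX", "WARD",
  "RICHARDSON", "WATSON", "BROOKS", "CHAVEZ", "WOOD", "JAMES",
  "BENNETT", "GRAY", "MENDOZA", "RUIZ", "HUGHES", "PRICE", "ALVAREZ",
  "CASTILLO", "SANDERS", "PATEL", "MYERS", "LONG", "ROSS", "FOSTER",
  "JIMENEZ")

RACE_POOL <- c("Black", "White", "Hispanic", "Asian", "Multiracial", "Other")
RISK_POOL <- c("MSM", "heterosexual", "IDU", "MSM_IDU", "other")
STATE_POOL <- c("DC", "MD", "VA")
OI_POOL <- c("Pneumocystis pneumonia", "Candidiasis", "Tuberculosis",
             "Kaposi sarcoma", "MAC", "Toxoplasmosis", "CMV retinitis")
ART_POOL <- c("TDF/FTC/DTG", "TAF/FTC/BIC", "ABC/3TC/DTG", "DRV/c/TAF/FTC",
              "EFV/TDF/FTC", "CAB/RPV")
FACILITY_POOL <- paste("Facility", LETTERS[1:12])

#' Simulation configuration
#'
#' Parameters of the synthetic feed generator. The defaults are the study
#' conditions the generator emulates: registry coverage of 0.93 (the
#' matched fraction observed at the sharing threshold), multi-site
#' enrollment probabilities of about 0.053 (two sites) and 0.002 (three
#' sites), and mild identity corruption.
#'
#' @param n_persons Number of distinct persons enrolled in the cohort.
#' @param n_sites Number of clinic sites (default 14).
#' @param surveillance_coverage Probability a person has a registry record.
#' @param multi_enroll_2,multi_enroll_3 Probability of enrollment at 2 / 3
#'   sites (distinct Cohort IDs mapping to one person).
#' @param p_name_typo Probability the site file carries a misspelling of
#'   the first or last name (one single-character edit).
#' @param p_typo_captured Probability that such a misspelling also exists
#'   among the registry's alias names (a document-based registry usually
#'   receives the same misspelled clinic document).
#' @param p_name_reversed_alias Probability the registry carries a
#'   reversed-order (last/first swapped) alias.
#' @param p_alias_extra Geometric parameter for additional misspelling
#'   aliases on the registry side (mean `p/(1-p)` extra aliases).
#' @param p_ssn_missing Probability the site file has no SSN.
#' @param p_ssn_partial_only Probability the site file stores only the
#'   last 4 SSN digits.
#' @param p_dob_typo Probability the site file DOB carries a typo.
#' @param p_prior_cohort_id Probability the registry remembers the Cohort
#'   ID from an earlier linkage round.
#' @param labs_per_person Mean number of cohort lab records per Cohort ID.
#' @param p_lab_shared Probability a cohort lab also exists in the registry.
#' @param p_demog_discrepant Per-field probability the cohort demographic
#'   value disagrees with the registry value.
#' @param p_death Probability the person is deceased in the registry.
#' @param p_central_only,p_site_only Probability a Cohort ID appears in
#'   only one feed (excluded by the filter stage).
#' @param seed Integer seed; identical configs yield identical feeds.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_persons = 1000L, n_sites = 14L,
                       surveillance_coverage = 0.93,
                       multi_enroll_2 = 0.053, multi_enroll_3 = 0.002,
                       p_name_typo = 0.05, p_typo_captured = 0.8,
                       p_name_reversed_alias = 0.02, p_alias_extra = 0.3,
                       p_ssn_missing = 0.05, p_ssn_partial_only = 0.05,
                       p_dob_typo = 0.01, p_prior_cohort_id = 0.30,
                       labs_per_person = 4, p_lab_shared = 0.5,
                       p_demog_discrepant = 0.08, p_death = 0.05,
                       p_central_only = 0.034, p_site_only = 0.022,
                       seed = 1L) {
  cfg <- list(n_persons = as.integer(n_persons), n_sites = as.integer(n_sites),
              surveillance_coverage = surveillance_coverage,
              multi_enroll_2 = multi_enroll_2, multi_enroll_3 = multi_enroll_3,
              p_name_typo = p_name_typo, p_typo_captured = p_typo_captured,
              p_name_reversed_alias = p_name_reversed_alias,
              p_alias_extra = p_alias_extra, p_ssn_missing = p_ssn_missing,
              p_ssn_partial_only = p_ssn_partial_only, p_dob_typo = p_dob_typo,
              p_prior_cohort_id = p_prior_cohort_id,
              labs_per_person = labs_per_person, p_lab_shared = p_lab_shared,
              p_demog_discrepant = p_demog_discrepant, p_death = p_death,
              p_central_only = p_central_only, p_site_only = p_site_only,
              seed = as.integer(seed))
  probs <- cfg[grep("^(p_|surveillance_coverage|multi_enroll)", names(cfg))]
  for (nm in names(probs)) {
    if (!is.numeric(probs[[nm]]) || probs[[nm]] < 0 || probs[[nm]] > 1)
      condition_stop("linkbox_config_error",
                     sprintf("%s must be a probability in [0, 1]", nm))
  }
  if (cfg$multi_enroll_2 + cfg$multi_enroll_3 > 1)
    condition_stop("linkbox_config_error",
                   "multi_enroll_2 + multi_enroll_3 must not exceed 1")
  if (cfg$n_sites < 3 && cfg$multi_enroll_3 > 0)
    condition_stop("linkbox_config_error",
                   "three-site enrollment requires at least 3 sites")
  if (cfg$n_sites < 2 && cfg$multi_enroll_2 > 0)
    condition_stop("linkbox_config_error",
                   "two-site enrollment requires at least 2 sites")
  if (cfg$n_persons < 1)
    condition_stop("linkbox_config_error", "n_persons must be positive")
  structure(cfg, class = "sim_config")
}

#' Apply one typographical corruption to a name
#'
#' Produces a string differing from the input in exactly one edit:
#' `typo_swap` transposes two adjacent (unequal) characters, `typo_sub`
#' substitutes one character, `truncate` drops the final character. Modes
#' that cannot change the input (single-character swap, repeated-letter
#' swap, single-character truncate) fall back to substitution. Consumes
#' the current RNG stream.
#'
#' @param name Non-empty character scalar.
#' @param mode One of `"typo_swap"`, `"typo_sub"`, `"truncate"`.
#' @return The corrupted name, never equal to the input.
#' @export
corrupt_name <- function(name, mode = c("typo_swap", "typo_sub", "truncate")) {
  mode <- match.arg(mode)
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      nchar(name) == 0)
    condition_stop("linkbox_config_error", "name must be a non-empty string")
  n <- nchar(name)
  ch <- strsplit(name, "")[[1]]
  if (mode == "typo_swap") {
    pos <- which(ch[-n] != ch[-1])
    if (n < 2L || !length(pos)) {
      mode <- "typo_sub"
    } else {
      i <- if (length(pos) == 1L) pos else sample(pos, 1L)
      ch[c(i, i + 1L)] <- ch[c(i + 1L, i)]
      return(paste(ch, collapse = ""))
    }
  }
  if (mode == "truncate") {
    if (n < 2L) mode <- "typo_sub"
    else return(substr(name, 1L, n - 1L))
  }
  i <- sample.int(n, 1L)
  repl <- sample(setdiff(LETTERS, ch[i]), 1L)
  ch[i] <- repl
  paste(ch, collapse = "")
}

corrupt_dob <- function(dob) {
  # month/day transposition when valid and different, else a one- or
  # ten-day slip (digit-level typo analog)
  m <- as.integer(format(dob, "%m")); d <- as.integer(format(dob, "%d"))
  if (stats::runif(1) < 0.3 && d <= 12L && d != m) {
    swapped <- as.Date(sprintf("%s-%02d-%02d", format(dob, "%Y"), d, m))
    if (!is.na(swapped)) return(swapped)
  }
  dob + sample(c(-10L, -1L, 1L, 10L), 1L)
}

rand_date <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

gen_labs <- function(n, from, to) {
  if (n == 0L) return(empty_labs())
  type <- sample(LAB_TYPES, n, replace = TRUE)
  result <- numeric(n); interp <- character(n)
  for (i in seq_len(n)) {
    if (type[i] == "CD4_count") {
      result[i] <- round(stats::runif(1, 50, 1400)); interp[i] <- "EQ"
    } else if (type[i] == "CD4_percent") {
      result[i] <- round(stats::runif(1, 4, 55), 1); interp[i] <- "EQ"
    } else if (stats::runif(1) < 0.4) {
      result[i] <- 0; interp[i] <- "UNDETECTABLE"
    } else {
      result[i] <- round(10^stats::runif(1, 1.5, 6)); interp[i] <- "EQ"
    }
  }
  data.frame(sample_date = rand_date(n, from, to), lab_type = type,
             result = result, interpretation = interp,
             facility = NA_character_, stringsAsFactors = FALSE)
}

#' Generate the three linked feeds with ground truth
#'
#' Simulates a cohort of persons enrolled at clinic sites, a central
#' de-identified repository, and a surveillance registry covering a
#' configurable fraction of them, then applies the configured corruption
#' phenomena. Identical configurations (including the seed) produce
#' byte-identical feeds; the global RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the three feed CSVs and
#'   `ground_truth.csv` are written there.
#' @return A `linkbox_sim`: list with `site`, `central`, `surveillance`
#'   record tables (the typed in-memory form of [read_table()]), `truth`
#'   (per-Cohort-ID ground truth and corruption provenance) and `config`.
#' @export
simulate_feeds <- function(config = sim_config(), out_dir = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  np <- config$n_persons
  person_id <- sprintf("P%06d", sample.int(np * 10L, np))
  birth_sex <- sample(c("M", "F"), np, replace = TRUE)
  first <- ifelse(birth_sex == "M",
                  sample(FIRST_NAMES_M, np, replace = TRUE),
                  sample(FIRST_NAMES_F, np, replace = TRUE))
  last <- sample(LAST_NAMES, np, replace = TRUE)
  dob <- rand_date(np, "1945-01-01", "2000-12-31")
  ssn <- sprintf("9%08d", sample.int(99999999L, np))
  race <- sample(RACE_POOL, np, replace = TRUE)
  risk <- sample(RISK_POOL, np, replace = TRUE)
  state <- sample(STATE_POOL, np, replace = TRUE, prob = c(0.8, 0.12, 0.08))
  # clinical dates all post-2001, strictly after the DOB era (1945-2000)
  hiv_dx <- rand_date(np, "2001-01-01", "2020-12-31")
  study_end <- as.Date("2023-06-30")
  has_aids <- stats::runif(np) < 0.3
  aids_dx <- as.Date(ifelse(has_aids,
                            pmin(hiv_dx + sample.int(2000L, np,
                                                     replace = TRUE),
                                 study_end - 900L),
                            NA), origin = "1970-01-01")
  dead <- stats::runif(np) < config$p_death
  death_date <- as.Date(ifelse(dead,
                               pmin(pmax(hiv_dx + sample.int(4000L, np,
                                                             replace = TRUE),
                                         as.Date("2012-01-01")),
                                    study_end),
                               NA), origin = "1970-01-01")
  in_surv <- stats::runif(np) < config$surveillance_coverage

  # enrollments: 1-3 sites per person
  u <- stats::runif(np)
  n_enroll <- ifelse(u < config$multi_enroll_3, 3L,
                     ifelse(u < config$multi_enroll_3 + config$multi_enroll_2,
                            2L, 1L))
  pe <- rep(seq_len(np), n_enroll)
  ne <- length(pe)
  cohort_id <- sprintf("C%06d", seq_len(ne))
  site_id <- character(ne)
  pos <- 1L
  for (i in seq_len(np)) {
    k <- n_enroll[i]
    site_id[pos:(pos + k - 1L)] <-
      sprintf("S%02d", sample.int(config$n_sites, k))
    pos <- pos + k
  }
  consent <- rand_date(ne, "2011-01-01", "2022-09-30")

  # feed membership: a few ids exist in only one feed
  uf <- stats::runif(ne)
  membership <- ifelse(uf < config$p_central_only, "central_only",
                       ifelse(uf < config$p_central_only + config$p_site_only,
                              "site_only", "both"))

  # ---- site records (with corruption) --------------------------------------
  s_first <- first[pe]; s_last <- last[pe]
  s_dob <- dob[pe]; s_ssn <- ssn[pe]
  name_typo <- stats::runif(ne) < config$p_name_typo
  typo_captured <- logical(ne)
  typo_field <- character(ne); typo_value <- character(ne)
  dob_typo <- stats::runif(ne) < config$p_dob_typo
  ssn_missing <- stats::runif(ne) < config$p_ssn_missing
  ssn_partial <- !ssn_missing & stats::runif(ne) < config$p_ssn_partial_only
  for (j in seq_len(ne)) {
    if (name_typo[j]) {
      fld <- sample(c("first", "last"), 1L)
      mode <- sample(c("typo_swap", "typo_sub", "truncate"), 1L)
      if (fld == "first") {
        s_first[j] <- corrupt_name(s_first[j], mode)
        typo_value[j] <- s_first[j]
      } else {
        s_last[j] <- corrupt_name(s_last[j], mode)
        typo_value[j] <- s_last[j]
      }
      typo_field[j] <- fld
      typo_captured[j] <- stats::runif(1) < config$p_typo_captured
    }
    if (dob_typo[j]) s_dob[j] <- corrupt_dob(s_dob[j])
  }
  s_ssn[ssn_missing] <- NA_character_
  s_ssn[ssn_partial] <- substr(s_ssn[ssn_partial], 6L, 9L)

  site <- data.frame(cohort_id = cohort_id, site_id = site_id,
                     first_name = s_first, last_name = s_last, dob = s_dob,
                     ssn = s_ssn, birth_sex = birth_sex[pe],
                     stringsAsFactors = FALSE)
  site <- site[membership != "central_only", , drop = FALSE]

  # ---- central records -----------------------------------------------------
  mutate_field <- function(value, pool) {
    alt <- setdiff(pool, value)
    if (!length(alt)) value else sample(alt, 1L)
  }
  c_race <- race[pe]; c_risk <- risk[pe]; c_state <- state[pe]
  c_vital <- ifelse(dead[pe], "deceased", "alive")
  c_gender <- ifelse(birth_sex[pe] == "M", "male", "female")
  c_hiv_dx <- hiv_dx[pe]
  for (j in seq_len(ne)) {
    if (stats::runif(1) < config$p_demog_discrepant)
      c_race[j] <- mutate_field(c_race[j], RACE_POOL)
    if (stats::runif(1) < config$p_demog_discrepant)
      c_risk[j] <- mutate_field(c_risk[j], RISK_POOL)
    if (stats::runif(1) < config$p_demog_discrepant)
      c_state[j] <- mutate_field(c_state[j], STATE_POOL)
    if (stats::runif(1) < config$p_demog_discrepant)
      c_hiv_dx[j] <- c_hiv_dx[j] + sample(c(-180L, -30L, 30L, 180L), 1L)
    # the cohort often has not heard of a death yet
    if (dead[pe[j]] && stats::runif(1) < 0.5) c_vital[j] <- "alive"
  }
  lab_end <- as.Date("2023-06-30")
  c_labs <- vector("list", ne)
  shared_flags <- vector("list", ne)
  for (j in seq_len(ne)) {
    n_lab <- stats::rpois(1, config$labs_per_person)
    labs <- gen_labs(n_lab, consent[j] + 1L, max(consent[j] + 2L, lab_end))
    c_labs[[j]] <- labs
    shared_flags[[j]] <- stats::runif(n_lab) < config$p_lab_shared
  }
  c_tx <- vector("list", ne)
  for (j in seq_len(ne)) {
    k <- sample(0:2, 1L, prob = c(0.2, 0.6, 0.2))
    c_tx[[j]] <- if (k == 0) empty_treatments() else {
      start <- rand_date(k, consent[j], lab_end)
      data.frame(drug = sample(ART_POOL, k), start_date = start,
                 end_date = as.Date(ifelse(stats::runif(k) < 0.3,
                                           start + sample.int(900L, k,
                                                              replace = TRUE),
                                           NA), origin = "1970-01-01"),
                 stringsAsFactors = FALSE)
    }
  }
  central <- data.frame(cohort_id = cohort_id, consent_date = consent,
                        vital_status = c_vital, gender = c_gender,
                        sex_at_birth = birth_sex[pe], race = c_race,
                        hiv_transmission_risk = c_risk,
                        state_of_residence = c_state,
                        hiv_diagnosis_date = c_hiv_dx,
                        aids_diagnosis_date = aids_dx[pe],
                        stringsAsFactors = FALSE)
  central$labs <- I(c_labs)
  central$treatments <- I(c_tx)
  central <- central[membership != "site_only", , drop = FALSE]

  # ---- surveillance records ------------------------------------------------
  sv_idx <- which(in_surv)
  nsv <- length(sv_idx)
  aliases <- vector("list", nsv)
  sv_labs <- vector("list", nsv)
  sv_ois <- vector("list", nsv)
  prior_id <- rep(NA_character_, nsv)
  enroll_of <- split(seq_len(ne), pe)
  n_new_to_cohort <- integer(ne)
  for (r in seq_len(nsv)) {
    i <- sv_idx[r]
    ali <- empty_alias_df()
    n_extra <- stats::rgeom(1, 1 - config$p_alias_extra)
    for (k in seq_len(n_extra)) {
      fld <- sample(c("first", "last"), 1L)
      mode <- sample(c("typo_swap", "typo_sub", "truncate"), 1L)
      ali <- rbind(ali, data.frame(
        first_name = if (fld == "first") corrupt_name(first[i], mode)
                     else first[i],
        last_name = if (fld == "last") corrupt_name(last[i], mode)
                    else last[i],
        stringsAsFactors = FALSE))
    }
    if (stats::runif(1) < config$p_name_reversed_alias) {
      ali <- rbind(ali, data.frame(first_name = last[i], last_name = first[i],
                                   stringsAsFactors = FALSE))
    }
    js <- enroll_of[[as.character(i)]]
    for (j in js) {
      if (name_typo[j] && typo_captured[j]) {
        ali <- rbind(ali, data.frame(
          first_name = if (typo_field[j] == "first") typo_value[j]
                       else first[i],
          last_name = if (typo_field[j] == "last") typo_value[j] else last[i],
          stringsAsFactors = FALSE))
      }
    }
    ali <- ali[!duplicated(ali), , drop = FALSE]
    rownames(ali) <- NULL
    aliases[[r]] <- ali
    if (stats::runif(1) < config$p_prior_cohort_id) {
      eligible_js <- js[membership[js] == "both"]
      pick <- if (length(eligible_js)) eligible_js[1] else js[1]
      prior_id[r] <- cohort_id[pick]
    }
    # registry labs: shared copies of cohort labs + registry-only labs
    labs <- empty_labs()
    for (j in js) {
      cl <- c_labs[[j]]
      if (nrow(cl)) {
        sh <- cl[shared_flags[[j]], , drop = FALSE]
        if (nrow(sh)) labs <- rbind(labs, sh)
      }
    }
    n_only <- stats::rpois(1, config$labs_per_person / 2)
    if (n_only > 0) {
      extra <- gen_labs(n_only, max(dob[i] + 6000L, as.Date("2001-01-01")),
                        lab_end)
      labs <- rbind(labs, extra)
    }
    if (nrow(labs)) {
      labs$facility <- sample(FACILITY_POOL, nrow(labs), replace = TRUE)
      labs <- labs[order(labs$sample_date, labs$lab_type, labs$result,
                         method = "radix"), , drop = FALSE]
      rownames(labs) <- NULL
    }
    sv_labs[[r]] <- labs
    # registry-only labs after each enrollment's consent are truly new
    for (j in js) {
      if (n_only > 0)
        n_new_to_cohort[j] <- n_new_to_cohort[j] +
          sum(extra$sample_date > consent[j])
    }
    sv_ois[[r]] <- if (has_aids[i] && stats::runif(1) < 0.6) {
      k <- sample(1:2, 1L)
      data.frame(condition = sample(OI_POOL, k),
                 date = rand_date(k, aids_dx[i], aids_dx[i] + 800L),
                 stringsAsFactors = FALSE)
    } else empty_ois()
  }
  surveillance <- data.frame(
    person_id = person_id[sv_idx], first_name = first[sv_idx],
    last_name = last[sv_idx], stringsAsFactors = FALSE)
  surveillance$aliases <- I(aliases)
  surveillance$dob <- dob[sv_idx]
  surveillance$ssn <- ssn[sv_idx]
  surveillance$birth_sex <- birth_sex[sv_idx]
  surveillance$prior_cohort_id <- prior_id
  surveillance$vital_status <- ifelse(dead[sv_idx], "deceased", "alive")
  surveillance$gender <- ifelse(birth_sex[sv_idx] == "M", "male", "female")
  surveillance$sex_at_birth <- birth_sex[sv_idx]
  surveillance$race <- race[sv_idx]
  surveillance$hiv_transmission_risk <- risk[sv_idx]
  surveillance$state_of_residence <- state[sv_idx]
  surveillance$hiv_diagnosis_date <- hiv_dx[sv_idx]
  surveillance$aids_diagnosis_date <- aids_dx[sv_idx]
  surveillance$labs <- I(sv_labs)
  surveillance$opportunistic_infections <- I(sv_ois)
  surveillance$death_date <- death_date[sv_idx]
  surveillance$cause_of_death <- ifelse(dead[sv_idx], "HIV disease",
                                        NA_character_)
  surveillance <- surveillance[order(surveillance$person_id,
                                     method = "radix"), , drop = FALSE]
  rownames(surveillance) <- NULL

  n_new_to_surv <- vapply(seq_len(ne), function(j)
    sum(!shared_flags[[j]]), 1L)
  truth <- data.frame(
    cohort_id = cohort_id,
    person_id = ifelse(in_surv[pe], person_id[pe], NA_character_),
    membership = membership,
    in_surveillance = in_surv[pe],
    site_id = site_id,
    name_typo = name_typo, typo_captured = typo_captured,
    dob_typo = dob_typo, ssn_missing = ssn_missing,
    ssn_partial_only = ssn_partial,
    n_true_new_to_cohort = n_new_to_cohort,
    n_true_new_to_surveillance = n_new_to_surv,
    stringsAsFactors = FALSE)

  sim <- structure(list(site = site, central = central,
                        surveillance = surveillance, truth = truth,
                        config = config),
                   class = "linkbox_sim")
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

empty_alias_df <- function() {
  data.frame(first_name = character(), last_name = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.linkbox_sim <- function(x, ...) {
  cat(sprintf(paste0("<linkbox_sim> persons=%d site_rows=%d central=%d ",
                     "surveillance=%d (seed %d)\n"),
              x$config$n_persons, nrow(x$site), nrow(x$central),
              nrow(x$surveillance), x$config$seed))
  invisible(x)
}

#' Write a simulation to disk as the three feed CSVs plus ground truth
#'
#' @param sim A `linkbox_sim`.
#' @param out_dir Directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(site = file.path(out_dir, "site.csv"),
             central = file.path(out_dir, "central.csv"),
             surveillance = file.path(out_dir, "surveillance.csv"),
             truth = file.path(out_dir, "ground_truth.csv"))
  write_table(sim$site, paths["site"], "site")
  write_table(sim$central, paths["central"], "central")
  write_table(sim$surveillance, paths["surveillance"], "surveillance")
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE, quote = TRUE)
  invisible(paths)
}
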