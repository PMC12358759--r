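---
title: "Deterministic cohort-to-registry linkage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic cohort-to-registry linkage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkbox)
```

## The problem

A clinical HIV cohort enrolls consenting patients at many clinic sites and
holds, centrally, only a de-identified payload (demographics, consent date,
CD4 and viral-load labs, treatment). The health department's surveillance
registry holds the identified person view — names with all recorded alias
variants, date of birth (DOB), Social Security number (SSN), labs with
reporting facility, opportunistic infections, vital status. Linking the two
enriches the cohort with labs and deaths it never saw and lets the study
detect participants enrolled at more than one site, while a strict privacy
wall keeps identifiers away from the study team.

`linkbox` implements that workflow at desk scale: feed verification,
Cohort-ID filter reconciliation, a deterministic multi-level matching
cascade with a sharing threshold, person-level deduplication,
recipient-redacted reports, lab and demographics discrepancy comparison, a
seeded synthetic identity generator, and validation metrics for threshold
selection.

## The matching cascade

Matching is deterministic: a pair either satisfies a level's criteria or it
does not. The shipped algorithm (`default_algorithm()`) is an ordered list
of 28 levels. Each level combines a *name rule* with a set of required
non-name variables:

* **FULL_NAME** — normalized first *and* last name agree, either against
  the registry person-view name (full level score) or against any recorded
  alias (one point lower). Sixteen levels use this rule, spanning scores
  100/99 (name + Cohort ID + DOB + SSN + birth sex) down to 68/67
  (name + partial SSN).
* **LAST_ONLY** — normalized last name agrees with the person view only
  (scores 66, 65, 59, 58). Aliases never feed this rule.
* **LAST_PLUS_FIRST6** — last name plus the first six characters of the
  normalized first name, person view only (64, 63).
* **NONE** — no name requirement (62, 61, 40, 38, 30, 20; the floor is a
  match on Cohort ID alone at 20, and 61 is DOB + SSN with no name).

Non-name variables are: Cohort ID (a registry record can carry the study ID
learned in an earlier linkage round), DOB (exact date equality), full SSN
(9 = 9 digit equality), partial SSN (last-4 equality; a 4-digit stored SSN
can satisfy only this), and birth sex. A criterion over a field missing on
either side is unsatisfied — missing data yields a lower level or no match,
never an error. Scoring walks the cascade from the top and returns the
first satisfied level, with person view checked before aliases inside a
level; by construction that is the globally highest attainable score.

The **sharing threshold** defaults to 61: results at or above it are
`shared` and drive every downstream exchange (deduplication, demographics,
labs, treatment). Sub-threshold levels are still scored and reported with
`shared = FALSE`, because threshold validation needs to see them. Both the
level table and the threshold are configuration (JSON via
`read_algorithm()`/`write_algorithm()`, or a `threshold` override in the
project template); the shipped table is the frozen default.

Design choices worth stating explicitly:

* **No fuzziness.** Name comparison is exact equality of normalized tokens
  (upper-cased; whitespace, hyphens, apostrophes and periods stripped).
  The cascade — and the registry's alias lists — provide the tolerance;
  there is no phonetic or edit-distance matching and no DOB transposition
  allowance. This is what makes results reproducible and auditable.
* **First-6 rule.** The two first-6 levels compare `substr(first, 1, 6)`
  on both sides after normalization, so names agreeing beyond their sixth
  character (ROBERT / ROBERTA) qualify. Names shorter than six characters
  participate with their full length.
* **Full SSN dominates partial.** Nine-digit equality implies last-4
  equality, so a full-SSN pair satisfies partial-SSN criteria too;
  highest-level-wins makes the full-SSN row take precedence.
* **Reversed name order** is handled only through alias entries with the
  parts swapped, never by a built-in swap rule, mirroring how a
  document-based registry actually records such variants.

## Blocking

`generate_candidates()` blocks on three keys: Cohort ID (against the
registry's prior Cohort ID), DOB, and SSN last-4. Every one of the 28
levels requires at least one of Cohort ID, DOB, or SSN agreement (full SSN
implies equal last-4), so a pair sharing none of the blocking keys is
provably unscorable. Blocked matching is therefore *exactly* equivalent to
scoring the full cross product — an invariant the test suite checks by
running both paths on simulated feeds of roughly 200 records per side over
20 seeds, and which holds by construction at any scale.

Best-match selection keeps one result per Cohort ID: the highest score,
with equal-score ties between distinct registry persons broken toward the
lexicographically smallest `person_id` and flagged (`tie_flag`), so reruns
are byte-identical. Several Cohort IDs may map to one person; that is the
multi-site enrollment signal, not an error.

## Filter stage, deduplication

Before matching, `reconcile()` intersects Cohort IDs between the central
file and the concatenated site files. Only IDs present in both proceed;
the two exclusive remainders become the filter reports delivered to both
recipients. A participant enrolled at several sites enters eligibility
once — the first-seen site row supplies the matching identifiers, a
conflict report lists cross-site identifier disagreements, and all site
rows are retained for per-site reporting.

After matching, `cluster_by_person()` partitions the shared results by
registry person. Cluster count is the unique-person count; clusters of two
or more Cohort IDs are the multi-site enrollees. Sub-threshold matches
never merge persons.

## Reports and redaction

Reports exist per recipient. The cohort study team's versions are
structurally redacted: identifier columns (names, DOB, SSN, registry
person ID) are never placed in a cohort-recipient table — its match report
is Cohort ID and score only, and the treatment report (cohort data flowing
to the health department) cannot be requested for the cohort recipient at
all. The health department receives full versions with all matching
variables. The suite verifies redaction by value: no identifier string
planted by the generator appears anywhere in a cohort-recipient file. The
generator supports this check by keeping clinical dates (diagnoses, labs,
deaths: 2001 onward) disjoint from the DOB era (1945–2000), so a date
collision cannot produce a false alarm.

Demographics comparison (`compare_demographics()`) emits one row per field
that is missing on one side or unequal after canonicalization (case and
whitespace folded for categories, dates rendered as ISO strings); both
recipients receive the counterpart's original value. Fields missing on
both sides produce no row — there is nothing to transfer. A fully
concordant match therefore contributes no rows; an all-blank placeholder
row per match would carry no information and was deliberately not adopted.

Lab comparison (`compare_labs()`) first discards labs dated on or before
the consent date on both sides — "after the consent date" is read
strictly. Remaining labs pair greedily by `(sample_date, lab_type)`,
taking both sides in result-sorted order within a key group (determinism;
the natural order when one side records duplicate draws). Pairs are coded:
`DUPLICATE` (result and interpretation agree), `RESULT_INTERP_DIFF`
(result agrees, interpretation differs), `RESULT_DIFF` (result differs);
unpaired labs are `NEW` to the side lacking them. Result equality is exact
after canonicalization (numeric comparison, so trailing zeros are
immaterial; interpretations normalized to EQ/LT/GT/UNDETECTABLE); no
numeric tolerance is applied — recording-convention differences are meant
to surface as codes, not vanish inside a tolerance. The four-code scheme
is this package's definition, chosen as the minimal set spanning "which
variables agreed".

Percentages in formatted outputs round half *up* to one decimal
(`format_pct()`); this is the convention that makes 9,060/9,744 print as
93.0 and 4,315/8,028 as 53.7.

## The synthetic feed generator

`simulate_feeds()` is first-class, tested code, not a fixture: it defines
the study conditions under which the engine's guarantees are demonstrated.
It draws persons from packaged name pools (SSNs come from the 9xx range
that real allocation never uses), enrolls them at 1–3 of 14 sites, and
emits the three feeds plus per-Cohort-ID ground truth with full corruption
provenance.

Default conditions, chosen once as the realistic regime for this kind of
cohort-to-registry linkage:

* `surveillance_coverage = 0.93` — the registry covers 93% of cohort
  participants; absence from the registry (out-of-jurisdiction residents,
  never-reported cases) is the dominant reason a record fails to match.
* `multi_enroll_2 = 0.053`, `multi_enroll_3 = 0.002` — roughly 5.5% of
  persons enroll at more than one site.
* Mild identity corruption: `p_name_typo = 0.05` (one single-character
  edit: adjacent transposition, substitution, or truncation),
  `p_dob_typo = 0.01` (month/day transposition or a one/ten-day slip),
  `p_ssn_missing = 0.05`, `p_ssn_partial_only = 0.05`. A site-file
  misspelling is also present among the registry's aliases with
  `p_typo_captured = 0.8`, because a document-based registry typically
  receives the same misspelled clinic document that the site file carries.
  These rates are set so that *joint* failure of both anchor variables
  (DOB and SSN) is negligible: in this workflow's intended operating
  regime, essentially all non-matches are registry absences rather than
  corruption-driven sub-threshold pairs, and the defaults encode that.
* `p_prior_cohort_id = 0.30` — the registry remembers the study ID from an
  earlier round for about a third of covered persons.
* `p_central_only = 0.034`, `p_site_only = 0.022` — a few percent of
  Cohort IDs appear in only one feed and are excluded by the filter stage.
* Labs: a Poisson number of cohort labs per Cohort ID
  (`labs_per_person = 4`), each also present in the registry with
  `p_lab_shared = 0.5`; registry-only labs (about half as many) may
  predate consent, exercising the exclusion rule. Per-field demographic
  discrepancies at `p_demog_discrepant = 0.08`; deaths at `p_death = 0.05`
  known to the registry and, half the time, not yet to the cohort.

The generator is seeded (`seed` in the config), restores the global RNG
state on exit, and is byte-reproducible: identical configs give identical
files.

What it does **not** emulate: realistic name-frequency skew (pool draws
are uniform, so accidental namesakes are rarer than in a real city-scale
registry, and validation precision on synthetic data runs close to 100%
rather than the high-90s a real review produces); nicknames and hyphenated
double surnames; registry-side DOB or SSN errors (corruption is applied to
the site feed only); document-level alias provenance; epidemic dynamics,
geography or care-seeking behaviour. Alias counts per person follow a
geometric distribution — the real distribution is unpublished, and this is
a modelling choice. Passing tests therefore demonstrate the engine's
correctness and calibration under these stated conditions, not performance
on any real registry.

## Validation and threshold selection

`label_against_truth()` marks each result `true_match` or `false_match`
against the generator's mapping (labels from ground truth are never
`uncertain`; that category exists for externally supplied review labels).
`score_band_metrics()` tabulates per-score counts and precision plus
cumulative precision at-or-above each score, in descending score order.
Uncertain labels are excluded from precision denominators by default;
`uncertain_as_false = TRUE` reproduces the stricter review convention
where an unresolvable pair counts against precision.

`select_threshold()` returns the smallest observed score whose cumulative
precision meets the target, defaulting to 0.99 — the level at which
sub-threshold bands in this kind of linkage begin to accumulate most of
the false matches while the bands at 61 and above stay above 99%
precision. If no score qualifies it returns the maximum observed score
with a `warning` attribute. The selector is monotone: raising the target
never lowers the returned score.

## Numerical and degenerate-input choices

* Dates are strict ISO 8601 (`YYYY-MM-DD`); any other dialect is a
  verification issue, and unparseable or future birth/consent dates
  become explicit `NA` with a row-level warning. The missing token on
  disk is the empty cell; internally it is always `NA`, never `""`.
* SSNs are stored digits-only (hyphens stripped on read); anything other
  than 9 or 4 digits becomes `NA` with a warning.
* A death date on a record not marked deceased is flagged and the date is
  blanked, restoring the record invariant.
* Ordering everywhere uses radix (C-locale) sorting, so outputs do not
  depend on the session locale; reruns of the pipeline on identical
  inputs produce byte-identical reports (the manifest's stage timings are
  the only varying values, and they live outside the report files).
* Empty feeds are legal: an empty surveillance file yields an empty match
  report and a full unmatched report.

## Problem sizes in the shipped tests

The suite demonstrates the blocking-equivalence invariant at about 200
records per side across 20 seeds, and parameter recovery (matched fraction
within three standard errors of configured coverage; no true pair below
the threshold once DOB and SSN corruption are disabled) at 2,000 persons
across 10 seeds — sizes chosen to exercise every code path with
comfortable statistical resolution. The engine itself is vectorized
and handles the full cohort scale (a ten-thousand-record linkage) in
seconds.

## Known limitations

* One best match per Cohort ID: registry-side duplicate persons are not
  merged; an equal-score tie is flagged for review rather than resolved.
* The demographics comparison treats free-text categories by exact
  canonicalized equality; semantically equal but differently coded values
  (e.g. two spellings of a transmission-risk category) surface as
  conflicts by design.
* Greedy same-day lab pairing is a deterministic convention, not a claim
  about which draw corresponds to which; only the code counts, not the
  pairing identity, should be interpreted.
* The generator's corruption model is site-sided and independent across
  fields; correlated corruption (a wholly garbled record) is not modelled.
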