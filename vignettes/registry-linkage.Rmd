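---
title: "Linking a surgical registry to an ICU registry with SLK-581: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking a surgical registry to an ICU registry with SLK-581: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regilink)
```

## The linkage problem

Two registries describe overlapping patients at one hospital. The surgical
registry is fully identified: surname, forename, medical record number
(MRN), date of birth, plus procedure date, hospital admission/discharge
dates, the post-operative ICU stay, and clinical covariates (age, sex,
urgency, procedure type, 30-day risk of death). The ICU registry is
deidentified before central collation but carries the AIHW statistical
linkage key **SLK-581** and the shared administrative fields (ICU and
hospital admission/discharge dates, age, sex). Nearly every cardiac
surgical patient goes to ICU immediately after the procedure, so the
target linkage is one-to-one: each procedure to its subsequent ICU
admission. The obstacles are the usual ones: a small fraction of ICU
records with names and MRN missing, single-digit data-entry errors,
patients admitted to ICU *before* their procedure (who have no post-op
admission to match), patients with several ICU episodes, and a handful of
procedures with no ICU episode at all.

`regilink` implements four linkage strategies over this structure and an
evaluation layer that scores any of them against a known gold standard.

## The SLK-581 key

`build_slk()` constructs the 14-character key: positions 1–3 are the 2nd,
3rd and 5th letters of the family name, 4–5 the 2nd and 3rd letters of the
given name, 6–13 the date of birth as `DDMMYYYY`, and 14 a sex code (1
male, 2 female, 9 other/unknown). Names are first normalized — uppercased,
with every non-alphabetic character removed — because hyphenation,
apostrophes and spacing variants are a recognized source of duplicate
keys; normalization must be byte-identical on both registries. A position
beyond the end of a short name is padded with the digit `2`; a wholly
missing family or given name contributes `999`/`99`. These padding and
missing-name conventions follow the national data-standard definition of
the key. A record without a valid date of birth cannot carry a key.

Key comparison (`slk_agree()`) is exact over the whole 14 characters;
a relaxed per-character mode (`max_mismatch > 0`) exists for exploration
but is excluded from every shipped strategy.

## Probabilistic linkage (strategies 1 and 3)

`score_pair()` sums per-field weights: agreement contributes the positive
weight, disagreement the negative, and a field missing on either side
contributes zero. The shipped weights are surname 7/−3, forename 5/−2,
MRN 15/−5, SLK-581 10/−2, and procedure-vs-ICU-admission date 2/−40 with a
two-sided caliper of 2 days; the acceptance cutoff is a total score of 1.
The date weight of −40 is deliberately overwhelming: no combination of
agreeing identity fields (maximum 37) survives an out-of-caliper date, so
the caliper doubles as the candidate-generation block — only pairs with
`|ICU admission − procedure| ≤ 2` days are scored at all, which is an
exact optimization, not an approximation. The caliper is two-sided because
pre-procedure ICU admissions are a real phenomenon; one-sided use is a
configuration choice.

Strategy 1 scores all five fields and serves as the in-silico
gold-standard-recovery check (on synthetic data the generator always knows
the identifiers). Strategy 3 restricts the field set to SLK-581 plus the
date.

**Assignment.** Accepted pairs must be one-to-one. `assign_pairs()` is
greedy best-first: pairs are taken in decreasing score order (ties broken
by smaller absolute date difference, then lexicographically by record
ids), skipping pairs whose records are already used. This realizes the
assignment whose descending sequence of accepted scores is
lexicographically maximal — an exchange argument shows the best-first
choice is always contained in that optimum, so greedy attains it exactly
whenever scores are distinct. It is *not* always the assignment maximizing
the number of accepted pairs: a single high-scoring pair can block two
lower-scoring ones. We consider best-first the right behaviour for
linkage — the most convincing pair should never be sacrificed to inflate
the match count — and it is deterministic and auditable. The test suite
verifies the greedy/exhaustive equivalence by brute force on small random
instances, and separately checks agreement with the
pairs-then-total-score optimum on the instances where the two objectives
coincide.

**EM-style weight estimation is out of scope.** The weights are fixed
inputs, as in the emulated workflow where they were settled by iterative
passes and clerical review before the final run.

## Staged deterministic linkage (strategies 2 and 4)

`run_stages()` runs an ordered hierarchy of passes over the not-yet-matched
records. The two shipped plans (`stage_plan("strategy2")`, 9 stages over
ICU admission/procedure date, ICU discharge, hospital admission and
discharge, age and sex; `stage_plan("strategy4")`, the same plus SLK-581,
12 stages) reproduce the published hierarchies verbatim. Three design
points needed decisions the source material leaves open:

* **Tolerance schedule.** Stage 1 requires exact agreement; every later
  stage loosens dates to ±2 days and age to ±2 years. The emulated
  description states that stage 1 is tight and criteria are subsequently
  loosened without printing a per-stage schedule; the flag is per-stage
  configuration with this default.
* **The ICU-admission field always carries the caliper.** `ICUAdmDt`
  compares the ICU admission date against the *procedure* date — a
  cross-field comparison with an intrinsic 0–2-day post-operative delay
  that is not a recording error. Requiring exact equality at the tight
  stage would push every patient with a 1–2-day delay (a fifth of the
  cohort) into the loosened stages even on error-free data, where
  near-twin ambiguity then strands a percent of them. The 2-day
  discrepancy is therefore allowed at every stage, matching how the
  SLK-plus-date strategy is described; exactness at stage 1 applies to the
  fields where both registries record the same quantity.
* **Ambiguity resolution: closest agreement wins, ties defer.** At each
  stage all agreeing pairs are formed; a pair is accepted only when it is,
  for *both* its records, the unique strict minimum of total discrepancy
  (summed day differences over the stage's date fields plus year
  differences in age). Records whose best candidates tie — in particular
  exact twins on every stage field — are deferred to later stages rather
  than dropped or arbitrarily assigned; a record matched at stage *k*
  is excluded from all later stages. The original implementation's
  within-stage disambiguation rule is not documented; pure deferral is the
  most conservative alternative but cannot recover a true pair whose
  competitor merely sits within the ±2 tolerance, which at registry scale
  happens to a handful of error-free records per run. The strict-minimum
  rule resolves those while still refusing genuinely irresolvable ties.

A missing field (for example, the surgical registry records no post-op ICU
discharge for a patient admitted to ICU pre-operatively) fails any stage
requiring it.

## The synthetic dual registry

`generate_registries(params, errors, seed)` emulates the study conditions;
it is deterministic given its arguments.

**Cohort (`cohort_params()`).** 1283 surgical procedures dated uniformly
over April 2017–December 2018, and 3842 non-surgical ICU admissions so the
ICU table totals about 5179 episodes once surgical episodes and
readmissions are added. Matchable patients draw age from N(63.5, 12.7²),
are 77.3% male, 22.0% urgent, with procedure mix 56.6/15.1/7.5/20.1%
(CABG/valve/combined/other) and log-normal 30-day risk of death with
median 1.08% and log-sd 0.85 (chosen to reproduce the reported IQR
0.67–2.10). Hard-to-match patients (below) use the unmatched-cohort
profile: age N(53.6, 15.1²), 80.5% male, 58.5% urgent, mix
26.8/17.1/4.9/51.2%, risk median 7.50% with log-sd 1.77 (IQR 1.33–14.5).
Exact distributional forms (normal ages, log-normal risk) are package
choices; only the summaries are constrained.

Hospital admission precedes the procedure by 0–14 days (elective) or 0–2
days (urgent); ICU admission follows the procedure by 0/1/2 days with
probabilities 0.80/0.15/0.05 (the within-caliper delay distribution is
unreported; this default is a package assumption and configurable); ICU
stay is 1–5 days; hospital discharge follows the last ICU discharge by
2–14 days. Dates of birth are drawn uniformly within the window giving
exactly the sampled age at hospital admission, so both registries agree on
age by construction. Non-surgical admissions use a disjoint name and MRN
pool and long-tailed stays (geometric ward-to-ICU lead, log-normal ICU and
post-ICU stays), the pattern of a general ICU population rather than the
tight post-operative cardiac signature.

**Pathologies (`error_model()`).** Defaults are calibrated to the emulated
registries:

* `p_no_icu = 10/1283` surgical records receive no ICU episode;
  `p_preop_icu = 31/1273` of the remainder are admitted to ICU 3–10 days
  *before* the procedure (their surgical record carries no post-op ICU
  discharge). Together these form the `hard` stratum (~41 patients) with
  the shifted covariate profile; neither has a gold partner, mirroring how
  the gold standard was restricted to procedure-matched admissions.
* `p_missing_identity = 47/5179` of ICU records have surname, forename and
  MRN blanked *after* key construction — deidentified records keep their
  SLK-581.
* Typographical errors are single-character (names) or single-digit (MRN,
  dates) substitutions on the ICU copy only; the surgical registry is
  treated as ground truth. Name fields err at 0.02 each, date of birth at
  0.018, MRN at 0.01. The key is always built from the identity *as
  recorded in the ICU registry*, so SLK errors arise only through upstream
  name/date-of-birth errors, never by direct injection.
* Administrative dates (hospital admission/discharge, ICU discharge) err
  independently at 0.02 per field, and additionally a `p_multi_error =
  0.055` correlated process corrupts each of the three with probability
  0.85 at once — the mis-assigned-stay/transfer-confusion pattern that
  makes records fail *every* staged pass. The calibration arithmetic: the
  9-stage plan tolerates any single broken field, so its misses come
  almost entirely from multi-field corruption, and 0.055 × 0.86 (the
  chance at least two of three fields break beyond ±2) ≈ 5.5% plus
  ambiguity losses lands near the observed ≈7% miss rate of deidentified
  staged matching, while the SLK error channels (0.018 + the ≈40% chance a
  name typo hits a key position) give the ≈3% miss rate of SLK-based
  matching. The ICU admission date itself is never perturbed: it anchors
  the episode, and in the emulated registries date mismatches concentrated
  in the other fields.
* `p_extra_icu = 0.05` surgical patients get a later second ICU episode in
  the same (extended) hospital stay.

**Identifiability guarantee.** The generator resamples any episode whose
admission-insensitive signature (ICU discharge, hospital
admission/discharge, age, sex) exactly duplicates a surgical episode's —
the admission date is excluded from the signature because, within the
2-day caliper, it cannot discriminate between candidates. Without this, a
few error-free runs per hundred contain either a background patient
byte-identical to a surgical stay or two surgical patients whose episodes
differ only in their post-operative delay — twins that *no* deidentified
strategy can resolve even in principle, which would make "error-free data
is recovered in full" a lottery rather than a designed property.
Arithmetic ties in total discrepancy between non-identical records remain
possible in principle and would defer; they are orders of magnitude
rarer. Real data offers no such guarantee; this is a stated idealization
of the generator, not a claim about registries.

**What the generator does not emulate.** Single-site structure only; no
seasonal casemix, no within-year drift, no correlation between clinical
severity and data quality beyond the hard stratum's covariate shift, name
frequencies from a fixed packaged pool rather than population statistics,
and dates-only resolution (no admission times). Consequently, passing
tests show the *strategies* behave as designed under the calibrated error
structure; they do not certify performance on any real registry.

## Evaluation

`evaluate_linkage()` scores a result against the gold standard: a pair is
a true match when it equals a gold pair, a false positive when its surgery
record has a different (or no) gold partner, a false negative when a gold
pair is absent. The match-rate denominator is the gold-eligible count
(the emulated cohort's 1242), not the registry size (1283); both are
reported. Percentages are rounded half away from zero to one decimal.
`compare_match_rates()` is the Pearson chi-square on the 2×2
matched/unmatched table, uncorrected by default (a Yates option exists).
`compare_cohorts()` emits the conventional characteristics table: age as
mean (sd) with Student's t (two groups, pooled variance) or one-way ANOVA;
sex, urgency and procedure mix as percent (n) with chi-square; risk of
death as median (IQR) with Wilcoxon rank-sum or Kruskal–Wallis. Degenerate
comparisons (zero variance) report `NA` rather than failing.

One note on expectations: under the calibrated error model the loosened
late stages of the deidentified plan *do* accept occasional coincidental
matches (a percent-scale false-positive rate concentrated in records whose
true partner is badly corrupted), whereas the emulated linkage exercise reported none
on its real data and itself attributed that to the cleanliness of the
source registries, anticipating false positives on noisier data. The
error-free condition, where zero false positives are a designed property,
is checked explicitly in the test suite.

## Problem sizes used in the checks

The test suite runs the full-scale generator (1283 × ~5190) for the
calibration, ordering and zero-noise checks — 20 seeds for the ordering
property, 5 for error-free recovery — and reduced cohorts (150–250
surgical records) for structural unit tests; the brute-force assignment
oracle enumerates all one-to-one assignments on instances up to 6×6. These
sizes keep the whole suite under a minute while leaving the headline
properties at the emulated scale.

## Known limitations

* Exact-equality text comparison: near-miss names or MRNs count as
  disagreement (the emulated workflow resolved these by clerical review,
  which is out of scope); the relaxed per-character key comparison is
  available but unused by the shipped strategies.
* Greedy assignment can accept fewer pairs than a cardinality-maximal
  assignment on adversarial score patterns (see above).
* The multi-part-surname convention (spaces stripped, concatenation
  indexed) is one defensible reading; source registries may index
  differently.
* The error-model calibration reproduces aggregate miss rates, not the
  joint error distribution of any real registry pair.
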