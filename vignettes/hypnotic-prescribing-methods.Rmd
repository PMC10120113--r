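---
title: "Methods: hypnotic prescribing cohorts, episodes and tabulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypnotic prescribing cohorts, episodes and tabulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypnorx)
```

hypnorx implements a drug-utilization analysis of hypnotic prescribing in
longitudinal health-insurance claims, of the kind run on Japanese
employment-based claims databases. This vignette is the package's account
of the method: the model and its assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
choices made where the design was genuinely open.

## The study design

The unit of analysis is the *patient-year*: a member's appearance in one
Japanese fiscal year (April 1 through March 31, labeled by its starting
calendar year). Within each fiscal year, a member's **index date** is the
date of their first bedtime-instruction outpatient hypnotic claim. Around
that index, the pipeline applies:

1. **Eligibility gates** — at least one outpatient insomnia diagnosis
   (ICD-10 G470) on or before the index date; age 20 to <75 at index;
   continuous enrollment over the full 12-month baseline window ending the
   day before the index date.
2. **Exclusions** — a narcolepsy/cataplexy (G474) diagnosis anywhere in
   the study window; any inpatient claim on the index date; any hypnotic
   claim with a missing dispense date; only as-needed (PRN) hypnotics on
   the index date; overlapping hypnotic coverage from two or more
   institutions at the index date.
3. **User-type classification** — *new* users have no hypnotic dispense
   date in the baseline window (a 12-month washout); *long-term* users
   have a same-MOA coverage episode that contains the index date and
   started at least 180 days before it. Member-years that are neither stay
   in the audit log but in no analysis cohort. The two definitions are
   disjoint by construction: new requires an empty baseline, long-term a
   covered one.

Every member-year with an index date receives exactly one audit decision,
so the flow identity *included + excluded = indexed member-years* holds by
construction and is asserted in the tests.

## The drug taxonomy

The formulary (`hypnotic_formulary()`) covers the 24 oral hypnotics
indicated for insomnia in Japan in the study window, in five
mechanism-of-action classes: 12 benzodiazepines (BZD), 3
non-benzodiazepine GABA-A agonists (z-drugs), the melatonin receptor
agonist ramelteon, the orexin receptor antagonist suvorexant, and 7 older
sedatives ("Others"). BZDs and z-drugs carry an action-duration subtype
(long / intermediate / short / ultrashort); the other classes do not and
never enter duration tabulations. Matching is case-insensitive on generic
name, never on ATC code — three older drugs have no ATC code at all.
Lemborexant is deliberately absent (not marketed in the window); looking
it up is an error, which is itself tested. Per-drug regulatory day caps
power an advisory QC flag (`check_rx_length()`) that reports but never
excludes; phenobarbital's 30–90-day range cap is stored at its permissive
bound 90 so the flag cannot false-positive.

## Episodes: what "continuous prescription" means here

The long-term rule needs an executable definition of continuity, which
the study description leaves open. hypnorx chains *supply-covered days*: a
claim covers the closed interval `[dispense_date, dispense_date +
days_supplied - 1]`; within one member and one MOA class (all generics of
a class pool into a single stream), a claim extends the running episode
whenever it starts no later than the covered end + `grace_days` + 1.

Three open choices, and how they were decided:

* **Grace period.** Default `grace_days = 30` — one missed refill under
  the 30-day caps that dominate the formulary, the conventional
  pharmacoepidemiology choice for drug-era construction; 0 and 7 are the
  natural sensitivity presets, and the value is always read from
  `analysis_config()` and echoed into the run manifest.
* **Early refills** extend coverage by interval union. No stockpiling
  (shifting unused supply forward): it is the simplest defensible rule,
  and stockpiling semantics are an explicit non-goal.
* **PRN claims count toward coverage.** The as-needed exclusion applies
  to *patients* at the index date, not to claims during continuity;
  callers wanting the stricter reading can drop PRN claims before
  `build_episodes()`.

The long-term rule is operationalized as *episode start on or before
index − 180 days, episode containing the index* — the closest executable
form of "continuous prescription of the same MOA for ≥180 days prior to
the index date". Because intervals are closed and day-granular, an
episode starting exactly 180 days before the index has 181 covered days
through the index and qualifies; this boundary is pinned in the tests.

Correctness does not rest on the interval algebra being convincing: the
test suite compares `build_episodes()` against an independent brute-force
oracle (a per-day coverage bitmap with maximal runs) on hundreds of
randomized claim sets per grace setting, exactly.

## Tabulation and intervals

Members are stratified by the MOA category at index: the set of distinct
classes among index-day claims, with all drugs of one class counting as a
single MOA (two benzodiazepines are "single BZD"), and `multiple` when
two or more classes co-occur. Combination labels use the fixed order BZD,
Z_DRUG, MRA, ORA, OTHER. Trend tables give the per-fiscal-year category
distribution; pattern tables pool a window of years (the study's final
two) and add two nested distributions: BZD duration types among everyone
prescribed a BZD at index, and class combinations among multiple-MOA
member-years.

Pooling is by patient-years, not unique patients: a member indexed in
both pooled years contributes twice. The per-year cohorts are
patient-year constructs, so deduplicating would mix units; this is an
assumption, stated loudly here and asserted by a fixture test.

Proportions carry two-sided 95% intervals. The default is the Wald
normal approximation clipped to [0, 100] — at cohort sizes in the tens of
thousands it reproduces printed demographic intervals to display
precision — with the Wilson score interval available
(`ci_method = "wilson"`), preferable at small counts; the implementation
is cross-checked in tests against the score interval of
`prop.test(correct = FALSE)`. Display rounding is one decimal, half away
from zero, and is purely a display concern: all partition identities
(category counts summing to their denominator, strata summing to the
unstratified counts) are tested on unrounded counts.

Baseline psychiatric comorbidities are flagged from diagnosis claims in
the baseline window by ICD-10 category prefix: substance use F10–F19,
schizophrenia spectrum F20–F29, bipolar F30–F31, depressive F32–F33,
anxiety F40–F42, neurocognitive restricted to Alzheimer's disease (F00,
G30 only — unspecified dementia F03 deliberately falls in the residual),
and a residual of any other F-chapter code. Flags are non-exclusive.

## The synthetic generator

Real claims data of this kind is proprietary, so the generator is a
first-class module, not a fixture. It works *archetype-first*: each
member's intended label is drawn, then claims are synthesized to realize
it — incident starters (empty washout, one index prescription),
persistent users (a same-class refill chain from ≥200 days pre-index
through the index), switchers (~90 covered days of one class, then a
switch 60 days pre-index, so no class reaches 180), intermittent users
(14-day claims 90 days apart — fragmented under any grace below 76
days), and ineligible decoys that each violate exactly one gate or
exclusion. Drawing labels first guarantees exact ground truth, which is
what makes zero-error recovery a meaningful acceptance check rather than
a statistical hope.

One consequence is modeled rather than suppressed: a persister's
pre-index chain reaches months into the *previous* fiscal year, where its
first claim is an index with an empty washout — the member is genuinely a
new user there. The truth table records these prior-year echoes
explicitly, and recovery is asserted member-year by member-year.

Defaults encode the study conditions: age, sex and comorbidity margins
of the pooled final-two-years cohorts, index MOA mixes matching the
observed new-user and long-term pattern distributions, and an archetype
mix of 40/25/15/15/5 (starter/persister/switcher/intermittent/decoy).
Two-class combinations are drawn weighted toward BZD + z-drug, the
dominant observed pairing. Dates are uniform within feasibility windows;
days supplied draw from {14, 28, 30} truncated at each drug's cap.
Contamination toggles (PRN flags on mid-chain claims, a second-institution
claim away from the index, planted narcolepsy) default off; when on, the
ground truth is updated with them, so recovery stays exact — asserted in
tests.

What the generator does *not* emulate: real enrollment churn, dose and
strength, costs, seasonal prescribing, correlated comorbidity onset, or
calibration of joint distributions beyond the configured margins. Passing
recovery tests therefore demonstrates that the cohort logic implements
its rules exactly — not that the pipeline is robust to every pathology of
real claims data.

## Numerical and testing choices

* All dates are day-granular ISO calendar dates; all intervals closed.
  Enrollment continuity defaults to `max_gap_days = 0` (strict
  continuity), configurable for sensitivity analyses.
* Baseline windows use calendar-month arithmetic with end-of-month
  clamping (an index on March 31 with a 1-month window starts
  February 28/29).
* The new-user washout checks dispense dates only: a claim before the
  window whose supply leaks into it does not disqualify — "not
  prescribed" is claim language. The leaky-supply variant is a sensitivity
  switch a caller can emulate by pre-filtering.
* Ties (two index-day claims from different institutions) resolve
  specialty by the claim earliest in record order — deterministic, and
  reruns of every stage are bit-identical by design and by test.
* The statistical-recovery acceptance check is a family of twelve
  binomial comparisons (six categories, two user types). The 99%
  acceptance level is applied to the family — per-category exact-binomial
  envelopes at the Bonferroni-corrected level, with counts pooled over
  ten generator seeds of 5,000 members each (cohorts above 1,000 per user
  type per seed). A single-draw, uncorrected version of this check
  rejects a perfectly calibrated generator roughly one seed in nine,
  which tests luck, not calibration; pooling makes the check stricter on
  genuine miscalibration, since deviations accumulate over ~16,000
  member-years.

Problem sizes in the shipped tests — up to 5,000 members per simulated
scenario, 20 seeds for recovery, 200 randomized claim sets per grace
setting — were chosen so that every planted structure (each decoy kind,
both user types, all MOA categories, prior-year echoes) appears hundreds
of times, which is where the exactness claims carry force.

## Known limitations

* The pipeline analyzes bedtime-instruction outpatient prescriptions
  only; inpatient prescribing, dose tapering and cross-class
  ("any-hypnotic") episodes are out of scope.
* Specialty inference can misclassify institutions whose psychiatry
  department is not primary, exactly as the underlying database would.
* The missing-prescription-date exclusion interprets "hypnotics lacking
  prescription information" as unparseable/absent dispense dates; vendor
  semantics may differ.
* With `grace_days` at 76 or above, the intermittent archetype's gaps
  chain and its planted "neither" label no longer holds; the generator's
  guarantee is stated for grace between the chaining slack and 75 days.
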