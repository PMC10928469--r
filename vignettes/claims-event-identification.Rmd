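---
title: "Identifying first and recurrent cardiovascular events in claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying first and recurrent cardiovascular events in claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdclaims)
library(dplyr)
```

## The problem

Single-payer health-insurance claims cover whole populations and are an
attractive source for national cardiovascular disease statistics, but a
claim is a billing record, not a clinical event. Three features of claims
data break the naive "one claim = one event" reading:

* **Billing-cycle splitting.** A hospitalization longer than the billing
  cycle (about 30 days) is submitted as several consecutive claims.
* **Complication readmissions.** A patient discharged after a stroke and
  readmitted days later for a complication files new claims for what is
  clinically one event.
* **Code carry-over.** Diagnosis codes are copied onto later visits
  regardless of the visit's purpose, so codes alone badly over-count
  events — especially *recurrent* events.

`cvdclaims` implements a three-stage pipeline that addresses these
problems: claims are first grouped into **hospitalization episodes**, each
episode is then tested against position-aware diagnosis-code rules
supplemented by procedure evidence, and finally each patient's episodes are
sequenced into at most one *first* event plus any number of *recurrent*
events per disease. A validation layer computes stratified and pooled
positive predictive values (PPVs) from chart-review adjudications, and a
synthetic generator produces cohorts with known ground truth so the whole
pipeline is testable without access to real claims.

## Hospitalization episodes

Two consecutive disease-coded claims A and B (sorted by start date, end
date, claim id) are split into separate episodes only when **both**
conditions hold:

1. the gap between the **first dates** of A and B *exceeds 28 days*
   (strictly `> 28`), and
2. the interval between the **last date** of A and the first date of B
   *spans 3 days or longer* (`>= 3`).

Either condition alone keeps the claims together. Thirty-day billing
fragments start 30 days apart (condition 1 holds) but leave a 1-day
discharge-to-admission interval (condition 2 fails), so they merge; an
early complication readmission fails one of the two conditions as well.

```{r}
claims <- new_claims(
  claim_id = c("A", "B"), patient_id = "p1", hospital_id = "h1",
  hospital_type = "tertiary",
  start_date = as.Date(c("2019-01-01", "2019-01-31")),
  end_date = as.Date(c("2019-01-30", "2019-02-14")),
  dx = list("I21.0", "I21.0"),
  evidence = list("PCI", character(0))
)
group_claims(claims, "AMI")[, 1:8]
```

Two implementation choices deserve a note:

* **Interval reference.** With overlapping or nested claims the "last date
  of claim A" is ambiguous under sorting. The default (`interval_mode =
  "episode_max"`) measures condition 2 against the episode's *running
  maximum* end date, which never splits a claim that lies temporally inside
  the episode; the literal pairwise reading is available as
  `interval_mode = "pairwise"` for sensitivity analyses. Condition 1 always
  uses the immediately preceding claim's start date, so a long stay chains
  across any number of billing fragments even when the episode span exceeds
  28 days.
* **Day conventions.** All arithmetic is in whole calendar days. Episode
  length is inclusive (same-day admission and discharge = 1 day), so the
  rules' "episode length ≥ 3 days" means at least three distinct calendar
  days. Both thresholds and the comparison senses (`> 28`, `>= 3`) are
  arguments with the published values as defaults.

Only disease-coded claims enter a disease's stream: grouping does not look
at interleaved claims without the disease code (e.g. rehabilitation
claims), and no look-back washout is applied before calling an event
"first" — first means first *observed* in the data at hand.

## Identification rules

Episodes are classified by branch hierarchies that combine the ICD-10 code
position (primary = first-listed vs secondary or lower), procedure
evidence, episode length and in-episode death. Branches are evaluated top
to bottom; the first branch whose *code precondition* matches selects the
criterion, and if that criterion fails the episode is not an event.

| Branch | Codes | Criterion |
|---|---|---|
| AMI_F1 | I21–I23 primary | ECG, cardiac enzyme, CAG, PCI, CABG, or death |
| AMI_F2 | I21–I23 secondary+ only | CAG, PCI or CABG |
| AMI_R | I21–I23 any position | PCI/CABG **and** (≥ 3 days or death) |
| STROKE_F1 | I63–I64 primary | (imaging **and** [≥ 3 days or death]) or intervention or death |
| STROKE_F2 | else I60–I61 any | same as F1 |
| STROKE_F3 | else I63–I64 secondary+ | intervention **and** (≥ 3 days or death) |
| STROKE_R1 | I63–I64 primary | (imaging or intervention) **and** (≥ 3 days or death) |
| STROKE_R2 | else I60–I61 primary | same as R1 |
| STROKE_R3 | else any stroke code secondary+ | intervention **and** (≥ 3 days or death) |

In-episode death (the patient-level death date falling inside the episode
span) substitutes for evidence that could not be collected, covering deaths
before any workup such as type 3 myocardial infarction. The recurrent rules
are deliberately stricter than the first-event rules because carried-over
codes make subsequent hospitalizations unreliable; every recurrent-positive
episode is also first-positive (verified exhaustively in the tests), so the
chronological scan below is well defined.

A code group counts as "primary" if it occupies position 1 on *any* member
claim of the episode, because the rules are applied per episode and the
admitting claim's coding may differ across billing splits. The rules are
stored as a declarative branch table (precondition + criterion), and the
test suite checks the engine against an independently hand-written truth
table over the full grid of code placements × all 128 evidence subsets ×
length/death states.

## Sequencing

Per patient and disease, episodes are scanned chronologically. Until a
first event is found, only the first-event algorithm is applied —
non-qualifying episodes (e.g. rule-out admissions) are skipped silently and
do not block later detection. From the first event on, only the recurrent
algorithm is applied; an episode that would qualify as a first event but
fails the recurrent criteria emits nothing. The AMI and stroke streams are
fully independent: a stroke episode is never counted as recurrent relative
to a first AMI.

## Validation statistics

PPV is estimated per (disease, kind, hospital type) stratum as
`100 × adjudicated-true / identified`, with a Wald 95% interval
`100 (p ± z √(p(1−p)/n))` truncated to [0, 100]. The Wald form was frozen
after verifying that it reproduces all eleven defined published stratum
intervals to one decimal (e.g. 584/617 → 92.9–96.4, 51/121 → 33.4–50.9);
Wilson intervals are available via `ci_method = "wilson"`. Display rounding
is half-up to one decimal on the percentage scale. When nothing is
identified, or when the interval is degenerate (0 adjudicated-true — the
published 0/1 recurrent-AMI primary-hospital cell), the cell renders `N/A`
while the underlying counts are always reported.

Pooling is either *unweighted* (PPV of the summed counts) or *weighted* by
external per-hospital-type case counts:
`pooled = Σ w_t ppv_t / Σ w_t`. The published analysis weights by national
case counts per hospital type, which are not public, so the package treats
weights as user configuration; the weighted pooled interval uses the Wald
combination `var = Σ w_t² p_t(1−p_t)/n_t / (Σ w_t)²`, a documented choice
that cannot be verified against the published pooled intervals for the same
reason. Multi-hospital episodes can be stratified by the first hospital
visited or by the highest-level hospital (tertiary > secondary > primary);
both rules are computed.

```{r}
counts <- validation_counts()
cbind(counts[1:3], cell = format_ppv(ppv(counts$n_true, counts$n_identified)))
```

## The synthetic cohort generator

`generate_cohort()` emulates exactly the fragmentation phenomena the
episode rules exist for, with every knob a probability in
`simulation_config()`:

* each true event targets a specific rule branch (uniform random evidence
  would under-sample rare branches such as STROKE_F3) and emits the codes,
  evidence, stay length and death flag that satisfy that branch;
* stays over 30 days are emitted as consecutive billing fragments that must
  re-merge; complication readmissions are placed inside the merge window
  (either a < 3-day interval or a ≤ 28-day gap);
* carried-over-code noise claims — short, evidence-free, after the event —
  and rule-out claims must never produce events;
* a configurable fraction of events is fatal, emitted as 1-day episodes
  with death and (half the time, for branches with a pure death arm) no
  procedures at all, exercising the type-3-MI-like paths;
* hospital types are drawn per claim, so episodes can span hospital levels
  and both stratification rules are exercised.

Defaults (500 patients, 30% AMI and 30% stroke prevalence, 35% recurrence,
12% fatality, one-year enrolment window) are chosen to give a few hundred
events with all nine branches represented, not to mimic Korean national
incidence; real fragment-count distributions are not published, so the
fragmentation probabilities are stated placeholders. Recurrent events are
scheduled at least 70 days after the first episode ends so that the
generator's own separation guarantees hold regardless of noise placement,
and a recurrent event is only scheduled when the first event is emitted
detectably (because recurrent-qualifying patterns also satisfy the
first-event rules, an undetected first would make the later episode a
correct FIRST call and the ground-truth label unscorable).

With canonical settings (`p_detectable = 1`) the pipeline must recover the
ground-truth log *exactly* — same patients, kinds and dates, no extras —
and the test suite asserts this at 500 patients, alongside a property-style
comparison of the episode builder against a brute-force partition
enumerator on 10,000 random ≤ 5-claim instances in a 120-day window.
What passing these tests shows is internal consistency and faithfulness to
the stated rules on data exhibiting the modelled phenomena; it does not
show performance on real claims, whose coding error structure (miscoded
positions, transfers between insurers, calendar effects of coding
revisions) the generator deliberately does not model.

## Numerical and degenerate-input choices

* Sorting key `(start_date, end_date, claim_id)` everywhere, making every
  stage deterministic and independent of input row order.
* ICD-10 matching is by 3-character prefix, so subdivided codes (I21.0,
  I63.9) are included, mirroring the published ranges which carry no
  subcode restrictions.
* Unknown service codes are an ingest error under `strict = TRUE`
  (default) or dropped with a warning otherwise; unknown hospital types
  and malformed codes are always errors.
* Empty inputs flow through: an empty cohort yields empty episode, event
  and report tables rather than errors.
* All simulation randomness is seeded (`withr::with_seed`), so identical
  configs give byte-identical CSVs.

## Problem sizes used in the checks

The bundled checks run the generator at 40–500 patients, the episode
oracle at 10,000 random instances, the rule-table enumeration at 2,048 AMI
and 8,192 stroke grid cells, and the chart-review recovery at 200
replicates of a 1,398-event review panel. These sizes give stable
stochastic margins (e.g. replicate-mean PPVs within 1 percentage point)
while keeping a full run in a few minutes on one core.

## Limitations

* The manual adjudication criteria used in the original chart review are
  human procedures and are represented only as configurable per-stratum
  error rates in `simulate_chart_review()`.
* No washout window, no cross-disease interaction, no outpatient/inpatient
  distinction, and no incidence or person-time estimation.
* The published *weighted* pooled PPVs cannot be reproduced without the
  unpublished national case-count weights; the package checks only the
  bounding property (any weighting lies within the stratum PPV range).
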