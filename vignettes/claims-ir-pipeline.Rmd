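---
title: "Methods: claims-based inadequate-response phenotyping for bDMARD initiators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based inadequate-response phenotyping for bDMARD initiators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimsir)
```

`claimsir` turns a five-table administrative-claims extract — enrollment
intervals, a catastrophic-illness registry, medical claims with ICD-9-CM
diagnoses, pharmacy dispensings, and code lists — into a response-phenotyped
new-user cohort of rheumatoid-arthritis (RA) patients starting their first
biologic DMARD, with annualized resource-use and cost summaries. This
vignette documents the model, its assumptions, the tunable parameters, and
the design decisions taken where the method leaves room.

## Cohort model

The design is a standard new-user (incident-exposure) design. A patient's
*index date* is the date of their first-ever bDMARD dispense over all
available history; the patient enters the candidate pool only when that
dispense falls inside the configurable index period (default calendar
2010, giving each patient a full pre-index year from a 2009 data start and
up to three follow-up years before a 2013 data end). Washout is absolute:
any earlier bDMARD dispense anywhere in the data disqualifies, not merely
inside the 365-day pre-index window. Inclusion needs both an RA-coded
healthcare event (ICD-9-CM 714.xx excluding juvenile chronic polyarthritis
714.3x) and an RA catastrophic-illness certification, the registry acting
as a diagnosis gold standard. Exclusions apply in a fixed order — age
under 18 at index; broken pre-index enrollment; selected inflammatory
comorbidities (psoriasis/psoriatic arthritis 696.xx, ankylosing spondylitis
720.0x, Crohn's disease 555.xx, ulcerative colitis 556.xx, 714.3x);
malignancy 140–208 excluding non-melanoma skin cancer 173.xx, or HIV/AIDS
042–044 — with the diagnosis scans covering the whole data horizon, and
every step logged in an attrition table whose remaining-n is monotone by
construction.

Two conventions deserve note. ICD-9-CM "xx" wildcards become prefix
matching on dot-stripped codes, with carve-outs expressed as negative
prefixes (so "714 excluding 714.3" is `include = "714", exclude = "7143"`);
the 140–208 range is expanded to explicit three-digit prefixes when the
default lists are built, which keeps the lists enumerable and testable.
Second, patients dispensed two distinct bDMARD agents on their index date
have no principled index agent; they are excluded as ambiguous and counted
in the attrition table rather than resolved by an arbitrary tie-break.

## Response classification

Follow-up is the half-open year `[t0, t0 + 365)` with day 0 the index
date. The classifier evaluates five criteria:

* **Low adherence.** PDC is the size of the union of per-dispense coverage
  intervals `[dispense date, dispense date + days supplied)` clipped to the
  window, divided by 365. The union collapses overlapping supplies; there
  is deliberately no stockpiling shift, the simplest defensible PDC, and
  the denominator stays 365 for every non-Unknown patient (censoring is
  handled by the Unknown status instead of by rescaling). The threshold is
  a strict `< 0.80`: exactly 292 covered days (0.8 × 365) is *not* low
  adherence. Internally the comparison is on integer covered-day counts,
  so no floating-point boundary can flip a label.
* **Switch or add** of a non-index bDMARD agent: any dispense in-window.
* **New csDMARD**: a compound with a dispense strictly after the index
  date and none in the pre-index window or on the index date itself — an
  index-day co-start is regimen design, not a response to failure.
* **Joint injections**: glucocorticoid joint-injection claims at or above
  `gc_injection_min_count`. The default is 2 ("more than one"); because
  the at-least-one reading also circulates, the count is configurable and
  1 is a supported setting.
* **Oral glucocorticoid increase**: mean daily prednisone-equivalent dose
  over follow-up days `[90, 365)` strictly above the pre-index mean, and
  at least one oral glucocorticoid dispense in that comparison window. The
  first 90 days are excluded because bridging steroids at biologic start
  are routine; the margin defaults to 0% (any strict increase, so new use
  over a steroid-free baseline counts). Both the bridging length and the
  margin are configurable; doses are compared in prednisone equivalents
  via the shipped potency table (`gc_equivalence()`).

The sixth criterion of the original US algorithm — an increased dose of
the index bDMARD — is **omitted outright**, not hidden behind a flag:
under Taiwanese reimbursement rules patients cannot increase their dose,
so the criterion is unobservable in these data and including it would
misdescribe the localized algorithm.

A patient whose enrollment (death-truncated, with coverage breaks shorter
than the 30-day tolerance bridged) ends before day 365 and who met no
criterion before the censor day is **Unknown**; any met criterion makes
the patient **IR**; meeting none makes them **Stable**. "Stable = meeting
none of the five criteria" is the only self-consistent reading of the
algorithm's verbal description, which elsewhere ties stability to meeting
criteria; we adopt it and note the ambiguity here rather than silently.
For censored patients, event criteria (2–5) are evaluated on claims before
the censor day, and adherence counts as met only once the threshold has
become arithmetically unreachable — that is, once the 74th uncovered day
has passed, since 73 uncovered days are compatible with reaching 292. The
same day also serves as the criterion's event date for first-met
attribution; criterion attribution always reports overlapping marginals
and first-met shares separately, with ties broken by the fixed criterion
order.

## Comorbidity and outcomes

Baseline comorbidity is the Deyo ICD-9-CM adaptation of the Charlson
index: 17 categories with weights 1/2/3/6 and hierarchy suppression
(complicated diabetes over diabetes, moderate/severe over mild liver
disease, metastatic over primary malignancy), shipped as an editable CSV
(`inst/extdata/charlson.csv`). The lookback is the pre-index year plus the
index date, one claim in any setting sufficing; the rheumatic-disease
category (which every RA patient triggers) is counted by default, and both
choices sit in the configuration because claims-based Charlson
implementations genuinely differ here. Malignancy categories stay in the
map even though cohort exclusions make them unreachable — the scorer is a
reusable library component.

Annual summaries for follow-up years 1–3 include a patient only when
continuously enrolled through that year's window, which is what makes the
enrolled-n shrink year over year. Admissions count at the admission date;
hospital days are discharge minus admission with a floor of one day;
costs split into inpatient/outpatient/ED (non-medication claim lines by
setting) and medication (pharmacy plus medication lines of medical
claims), so the per-patient total is the category sum by construction.
Time to switch is reported conditionally on switching, matching how such
means are usually printed, and an empty switcher set yields an absent row,
never a zero. Currency converts at a configurable 0.033 USD per NT$;
every reported percentage and whole-dollar figure rounds half away from
zero, the convention that reproduces printed claims-report tables.

## The synthetic generator

`generate_claims()` exists so that every downstream stage has an exact
oracle. For each planted patient it draws a status (Stable/IR/Unknown),
criterion flags for IR patients, and then *realizes* each flag with
concrete claims: low-adherence patients get dispensing gaps, switch
patients a second agent, and so on. Three properties are engineered in:

* **Exact counts.** Statuses, index-drug mix, criterion flags, switcher
  counts and destinations are assigned without replacement at their exact
  planted counts, so cohort composition reproduces exactly, not in
  expectation. Criterion flags are dealt like tokens — one to each IR
  patient first, the rest to patients lacking that flag — so marginal
  counts are exact *and* every IR patient has at least one criterion.
* **Non-interference.** Patients not flagged for a criterion are built so
  that the criterion cannot fire: unflagged PDCs are drawn in
  `[0.80, 1]` and realized as `ceiling(u·365)` covered days (flagged ones
  in `[0.2, 0.80)` via `floor`, so integer day counting cannot cross the
  boundary); unflagged patients keep at most one injection, a
  non-increasing steroid dose and no new compounds; Unknown patients are
  censored in days 30–334 (the upper bound leaves a ≥ 31-day trailing
  gap, beyond the 30-day bridging tolerance) with no prior criterion and
  index-agent supply running to the censor day so adherence stays
  undecidable.
* **Calibration.** The `taiwan_2010_preset()` scenario plants 818
  patients (258/540/20 stable/IR/unknown, 375/443 adalimumab/etanercept,
  79/56 switchers with exact destination counts, criterion marginals
  294/164/139/65/25), per-cohort-year resource-use means (Poisson counts)
  and cost means (log-normal with the printed SDs for outpatient and
  medication; inpatient and ED costs are per-event log-normals whose
  compound mean matches the cell, SD emergent), enrollment attrition
  giving 798/785/741 summarizable patients in years 1–3, demography
  (age 55.5 ± 13.1, 685 female) and per-status Charlson targets
  (1 + Poisson extra weight-1 categories). Early (criterion-2) switchers
  get uniform year-one switch days; late switchers get a uniform window
  centred so each agent's overall mean time to switch equals its target
  (782.4 / 755.6 days) in expectation conditional on the early draws.
  Published criterion-attribution percentages (36/20/17/8/3 of the
  cohort) overlap to 84% against a 66% IR rate; the preset therefore
  plants them as overlapping cohort-level marginals, a modeling choice,
  since the original denominators are not stated.

A configurable number of decoy patients — each violating exactly one
inclusion or exclusion rule — exercises the attrition table without
touching the planted cohort, and `add_nuisance_claims()` appends visits
whose diagnoses match no code list, for robustness checks.

What the generator does **not** emulate: disease progression,
within-patient correlation between comorbidity, adherence and cost beyond
cohort-level means, per-cohort demography differences, seasonal claim
patterns, or coding noise. Passing the plant-and-recover suite therefore
shows the pipeline is faithful to the algorithm's definitions — it does
not validate the algorithm against clinical response, and performance on
real NHIRD extracts (which are access-restricted) may differ.

## Numerical and degenerate-input choices

Dates are handled as integer day offsets; all criterion windows are
half-open. Enrollment gaps are whole uncovered days between closed
coverage intervals; a gap of exactly the 30-day tolerance is a break
("< 30 days" is strict), and leading/trailing uncovered runs count as gaps
too. Costs are generated and stored as whole NT$, so double-precision sums
are exact and the conservation identity holds to equality. Empty inputs
are first-class: empty bundles read and write as header-only files, an
empty cohort classifies to an empty result, and an empty switcher set
yields empty switching tables. Malformed input never drops rows silently —
every schema or invariant violation raises a classed error naming the
table, column and offending rows. The catastrophic-illness certification
must predate the index date by default (`require_card_before_index`),
since certification is what qualifies the RA diagnosis at indexing; the
switch accommodates the laxer reading.

## Problem sizes and test design

The validation suite runs the full calibrated scenario (818 patients plus
decoys, ~140,000 claim rows) once and reuses it across tests; property
suites use 1,000 random dispense sets for the PDC union/brute-force
equivalence, 200–1,000-patient scenarios for label recovery and marginal
recovery (binomial 3-SE bands), and 50–120-patient scenarios for
monotonicity and nuisance-robustness checks. Planted continuous
quantities are checked within three standard errors at the preset n;
planted counts are checked exactly. These sizes were chosen as the
smallest that make the stochastic checks sharp.

## Known limitations

The classifier observes claims, not disease: steroid escalation for a
comorbidity, or a csDMARD added for tolerability, still count as
inadequate response. PDC treats supply on hand as consumption. The
Unknown rule discards any criterion information after the censor day by
design. The code lists target ICD-9-CM only (the study horizon predates
Taiwan's ICD-10 transition), and the cost model has no comparative or
inferential machinery — the underlying design is descriptive.
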