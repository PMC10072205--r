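---
title: "Treatment trees and anchored survival comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment trees and anchored survival comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careflowr)
```

This vignette is the package's account of its methods: what is computed,
under which assumptions, which defaults were chosen where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about real data.

## From treatment tables to an event log

The input is three tables: treatment lines (one row per patient, line,
modification, with a treatment type from a controlled vocabulary, start/stop
dates and an advanced/adjuvant setting flag), dated response assessments
(CR/PR/SD/PD for advanced lines, RE/NR for adjuvant ones), and a patient
index (sex, birth date, death date, last follow-up, free attributes). Dates
are accepted as `DD.MM.YYYY` (the native dialect of such curation tables) or
ISO-8601; output is always ISO.

**Modification merging.** A line's modifications — maintenance after
induction, or a within-class drug switch — are collapsed to one event
retaining the *first start date and the latest stop date*. When
modifications differ in type (induction CTLA4+PD1 followed by PD1
maintenance), the merged line keeps the *first* modification's type: the
line's identity is its induction treatment. A missing stop date means the
line is ongoing; the merged stop is then missing and durations are censored
at last follow-up.

**Validation.** Rows violating hard invariants (unparseable dates, inverted
intervals, non-positive indices, duplicate keys, unknown labels) are dropped
and reported, one JSON-lines record per issue. Patients whose start dates
contradict their line order are excluded from the log with a per-patient
reason, mirroring the eligibility screening any curated cohort undergoes.
Overlapping date ranges across *different* lines are only warned about:
nothing in the data model says how they should be repaired, so we refuse to
guess. Responses referring to lines absent from the treatment table are
kept but flagged.

Event labels are the pair (type, setting), written `adj:PD1` for adjuvant
lines: an adjuvant PD1 course and a first-line advanced PD1 course are
clinically different entities and must occupy different tree nodes.

## Treatment-tree discovery

The tree is the prefix tree of per-patient label sequences. The root
("recruitment") holds all patients — including patients with no systemic
treatment lines, who sit only there. A node at depth *d* with path
\(\ell_1 \dots \ell_d\) holds exactly the patients whose first *d* labels
are that path; its per-patient **anchor date** is the start of that
patient's *d*-th line. Children are ordered by descending patient count,
ties broken lexicographically — the ordering is a free choice, fixed so
that identical logs yield byte-identical output. Edge weight is the branch
fraction \(|child|/|parent|\).

Pruning at threshold *m* removes every node with fewer than *m* patients
together with its whole subtree (prefix-tree semantics: grandchildren are
not re-attached), and is exactly equivalent to re-discovering at *m*.
Pruning only removes: asking for a threshold below the tree's current one is
an error rather than a silent rebuild. The display default is 4 patients
per box; no maximum depth is imposed. The implementation is validated
against exhaustive prefix enumeration on random logs and obeys the
conservation identity |node| = Σ |children| + (patients whose sequence ends
there).

## Per-node outcomes

**Best overall response** is the maximum of a line's assessment labels under
CR > PR > SD > PD — the conventional RECIST-like ordering. Patients without
assessments are `NE` (not evaluable); `NE` is a real category in
retrospective data and both normalizations of the objective response rate
(per evaluable, the default, and per all patients) are exposed. Adjuvant
nodes use the two-outcome recurrence vocabulary: `RE` if any recurrence
label exists, else `NR`, else `NE`.

**Node OS** is the Kaplan-Meier estimate of time from each patient's own
anchor date to death, censored at last follow-up. A death date counts as an
event even without a recorded progression. The five-year horizon truncates
only the display; the estimator uses all follow-up. Patients whose anchor
falls after their last follow-up with no death cannot contribute and are
dropped with a warning.

## Cohorts and comparison

A cohort is built by set algebra over node patient sets: union of added
nodes minus union of subtracted nodes (pure set difference — a subtracted
node removes its patients no matter which added node contributed them).
Each member is anchored at the start of the line of the node that
contributed it; a patient entering via several added nodes takes the
*shallowest* node's anchor, with a warning — the earliest anchor is the
conservative choice against immortal-time artefacts, and the event is
recorded so the analyst can reconsider. The expression mini-language
(`"PD1>CTLA4+PD1 + PD1>PD1 - adj:PD1"`) makes these selections scriptable;
operators must be whitespace-separated because `+` is legal inside labels.

Endpoints are anchored at each member's own anchor date. **OS** is time to
death, censored at last follow-up. **PFS** is time to the earlier of the
first progression assessment (PD, or RE for adjuvant anchoring lines) on
the anchoring line *or any later line*, and death; otherwise censored at
last follow-up. Death-counts-as-progression is the standard oncology
convention; the data model does not define PFS itself, so the convention is
stated here prominently. PFS evaluates the anchoring line only in the sense
that its clock starts there; later-line progressions still end the interval,
which matches how a progression that triggered the next line is recorded
at the switch.

The statistical layer is deliberately standard and routed through the
`survival` package behind this package's interface: the product-limit
estimator with a Greenwood-variance log-log confidence band (so landmark
rates and their CIs come from one consistent band), the two-group log-rank
chi-square with 1 df, and a Cox proportional-hazards fit with a single
binary covariate, Efron tie handling (ties are common with day-resolution
data) and a Wald 95% CI. The hazard ratio is always reported as
second-listed cohort versus first-listed, and printed with that order.
Degenerate inputs are defined rather than accidental: zero events across
both groups yield log-rank statistic 0 and p = 1; a Cox fit with zero
events is an error; complete separation is reported with the
infinite-bound convention. The test suite checks these routines against
independent oracles — a first-principles product-limit estimator (equality
to 1e-10), a permutation null for the log-rank p-value, a type-I-error
simulation, and brute-force maximization of the Efron partial likelihood on
a grid (agreement to 1e-4) — plus a CI-coverage simulation for the hazard
ratio.

## The synthetic cohort generator

The generator emulates the *shape* of an advanced-melanoma real-world
cohort so that every operation above is testable without patient data:

- **Paths**: a first-line label drawn from a melanoma-flavoured mix
  (adjuvant PD1 20%, PD1 28%, CTLA4+PD1 24%, BRAFi+MEKi 16%, CTLA4 8%,
  chemo 4%), then first-order transitions with a per-label stop
  probability; adjuvant PD1 occurs only as a first line. The mix and
  transitions are patterned loosely on the line-frequency ranking seen in
  published melanoma cohorts and are illustrative, not estimates of any
  specific dataset.
- **Responses**: one best-overall-response label per line from per-label
  mixes whose objective response rates echo the published ordering of the
  classes (combination ICI ≈ 53%, PD1 ≈ 42%, CTLA4 ≈ 22%, targeted therapy
  high initial response, chemotherapy low), assessed at a uniform time
  within the line; every switch to a next line is preceded by a terminal
  progression (PD, or RE after adjuvant lines) so that tree transitions are
  response-consistent.
- **Survival**: exponential time to death with a per-first-line daily
  hazard (medians from ≈10 months for chemotherapy to ≈6.5 years for
  adjuvant PD1) optionally multiplied by `hr_map` effects of labels present
  in the path — which is what the hazard-ratio recovery tests exercise.
  Follow-up is administratively capped (default 2200 days) with random
  early censoring (default 15%). Lines that would start after death or
  censoring are not observed; the truth export records the *realized* path,
  and all round-trip tests compare against it.
- **Modifications**: a fraction of closed lines (default 15%) is split into
  2–3 consecutive modification rows covering the same interval, so that
  merging is exercised end-to-end; splitting then merging is the identity.

What the generator does **not** model: confounding by indication, immortal
time between diagnosis and treatment, non-proportional hazards, dependent
censoring, misclassified or missing response assessments. Green tests
therefore establish the *correctness of the machinery* on data satisfying
the stated model — not the clinical validity of any comparison on real
data, where those biases are the dominant concern.

All randomness flows from a single integer seed through R's default
generator; identical seeds reproduce every table and export byte-for-byte.

## Numerical and design choices

- Probability vectors are validated to sum to 1 within 1e-9; KM oracle
  comparisons are at 1e-10; the Cox grid oracle is at 1e-4 (grid resolution
  1e-5).
- Child ordering (count, then label), node numbering (depth-first) and CSV
  column orders are fixed for deterministic output.
- Result tables export as CSV; tree structure as JSON (patient identifiers
  withheld unless explicitly requested) and Graphviz DOT with edge pen
  width proportional to the branch fraction and adjuvant nodes filled
  yellow.
- Test problem sizes were chosen to make the checks sharp yet quick: tree
  oracles on ≤30 patients and ≤5 labels (where exhaustive enumeration is
  exact), log-rank calibration with 2,000 null simulations at 50 subjects
  per arm, hazard-ratio recovery at 500 per arm with 200-replicate CI
  coverage, end-to-end scripts on a 300-patient synthetic cohort.

## Limitations

The package reproduces analysis machinery, not clinical findings: cohorts
selected from a discovered tree are conditioned on observed sequences, and
anchored comparisons between them inherit every selection bias of the
underlying data. Only two-group comparisons with a single binary covariate
are provided — no covariate adjustment, stratification or propensity
methods — and conformance checking or Markov-model process mining are out
of scope.
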