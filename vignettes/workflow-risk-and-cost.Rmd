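---
title: "Costing and risk-scoring radiotherapy workflows"
author: "rtworkflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing and risk-scoring radiotherapy workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtworkflow)
```

This vignette explains the models behind the package, the assumptions
baked into the packaged fixtures, and the design choices made where the
problem left the design genuinely open.

## The cost model

Time-driven activity-based costing assigns resource costs to process
steps through capacity cost rates. A resource's CCR (USD/min) is its
annual cost divided by its annual available minutes,
`annual_days * daily_hours * 60`. The packaged rate table uses the
standard capacity assumptions for a radiotherapy department: personnel
work 260 days x 8 h (the 2080-hour year, 124,800 min), equipment and
rooms are available 260 days x 10 h (156,000 min), except the PET/CT
simulator and its room at 8 h/day. When a table supplies both an annual
cost and a CCR, the two must agree to 0.5% relative tolerance; a supplied
CCR takes precedence, because published rate tables print rounded CCRs
whose underlying salaries are not disclosed.

A process map is an ordered list of stages (default: consultation,
simulation, planning, treatment, on-treatment visit, follow-up) holding
steps. Each usage of a resource by a step contributes

$$\mathrm{cost} = \mathrm{CCR} \times \mathrm{minutes} \times
\mathrm{headcount} \times p_{\mathrm{occ}} \times
\begin{cases} n_{\mathrm{fractions}} & \text{per-fraction step} \\
1 & \text{otherwise} \end{cases}$$

to the (resource, stage) cell. The occurrence probability
$p_{\mathrm{occ}} \in [0,1]$ models tasks that do not apply to every
patient and defaults to 1. Headcount is modelled explicitly rather than
folded into minutes so reports can show staff counts and person-minutes
separately; it is only meaningful above 1 for personnel. All cost
arithmetic is carried in full double precision and rounded to cents only
for display: the published stage-total grid is internally consistent only
if summation precedes rounding. Rollups satisfy a conservation identity —
stage totals, resource totals, category totals and the grand total all
agree to well below $10^{-6}$ — which the test suite checks on hundreds
of randomised workflows against a brute-force per-usage enumeration.

Display rounding throughout the package is half-away-from-zero on the
exact value (so 832/9 = 92.444… prints as 92.44 and 2.5 rounds to 3),
implemented in exact integer arithmetic for rationals rather than via
binary floating point.

## The packaged fixtures

All study inputs ship as plain text under `inst/extdata/`, each record
tagged `[PAPER]` (printed value) or `[DERIVED]` (back-derived, with the
derivation noted in the file):

* `resources.csv` — the published CCR table: 7 personnel categories,
  5 equipment items, 3 rooms.
* `workflow_mrgrt.yaml`, `workflow_ctgrt.yaml` — the two five-fraction
  SBRT process maps at (personnel x stage) granularity. The published
  per-step minutes exist only as a figure image, so each non-zero cell of
  the published personnel cost grid becomes one aggregated step whose
  minutes are the exact quotient `printed cost / CCR`, stored as a
  fraction string (`"124.02/2.34"`) and divided only at load. The engine
  therefore recomputes the published grid from minutes and rates; the
  fixture never stores a cost.
* equipment and space usages are calibrated to the published modality
  totals (MRgRT: $4,471.15 equipment, $199.04 space; CTgRT: $1,343.97 and
  $74.85). Their per-stage split is under-determined: the fixtures assume
  a one-off CT simulation on the PET/CT simulator and room (20 min in the
  MRgRT map, 30 min in the CTgRT map) and attach the remaining machine
  and vault minutes to the treatment stage. Only modality-level
  equipment/space totals are asserted anywhere.
* `register_table2.csv` — the 47 printed high-priority failure modes.
* `interventions.yaml` — the five technology interventions.

Treatment-stage personnel minutes that divide evenly by the fraction
count are stored as per-fraction steps (e.g. three therapists at 108
min/fraction); course-level aggregates stay course-level.

## The FMEA model

Scores are exact rationals. The register's physics rows were scored by
three independent raters and averaged, so printed values like 5.33 are
exact thirds (16/3). The score parser reads a two-decimal value as the
nearest third whenever that third rounds back to the printed value; this
interpretation reproduces every printed fractional RPN in the packaged
register (92.44, 88.89, 69.33, 40.3, 34.67) exactly, while multiplying
the rounded decimals does not (4 x 5.33 x 4.33 = 92.32). A literal
`"decimal"` parsing mode is available as an explicit opt-in. Score cells
may also be fraction strings (`"16/3"`) or rater lists (`"5;5;6"`, which
are averaged exactly). Two printed RPNs (52.33 and 51.13) disagree with
exact recomputation (1408/27 = 52.15 and 462/9 = 51.33) under any
consistent reading; the package treats them as publication errata, keeps
the printed values as data, and surfaces them through `audit_register()`
at its default absolute tolerance of 0.1.

Risk levels come from a 10 x 10 (severity x occurrence) grid constrained
to be monotone — the level never decreases as S or O increases — and to
satisfy the severity override: rows S = 9–10 are entirely high, because
high-severity failures demand mitigation regardless of how rarely they
occur. Non-conforming grids are rejected at construction, so a loaded
matrix is always valid. The published matrix figure's cell boundaries are
not machine-readable; the packaged default (high when S ≥ 9, or S ≥ 7
and O ≥ 6, or S ≥ 5 and O ≥ 8; low when S ≤ 2, or S ≤ 4 and O ≤ 3) is an
assumption of this package, documented as such and fully replaceable by
any valid user grid. Fractional consensus scores are ceiling-rounded for
the lookup — the conservative choice, never understating risk.

Top-fraction selection ranks descending by RPN (or severity), takes
`k = ceiling(fraction * n)`, and includes every item tied with the k-th
value, so the flagged set is well-defined under ties and never excludes
an item that outranks a flagged one. With `group_by = "role"` the ranking
runs independently within each personnel role, mirroring the practice of
prioritising separately per care-team member. The source's own "top 20%"
count (52 of 279, i.e. 18.6%) shows the published selection was not a
strict ceiling rule; the package does not calibrate to it.

## The scenario model

Interventions are edits: `remove_step`, `reduce_minutes` (a per-occurrence
delta applied to each resource of a concurrently-working set, per head),
and `scale_minutes`. Reductions clamp at zero minutes with a warning.
Savings are always computed as `rollup(baseline) - rollup(edited)`, so
the personnel/equipment/space decomposition is consistent with the cost
engine by construction. Elapsed time saved counts each edit's delta once
per occurrence (the affected resources work concurrently), and a removed
step counts its longest usage.

The packaged suite makes four modelling choices worth stating:

* **The treatment-delivery resource set** is 3 therapists + physicist +
  dosimetrist + machine + vault. This is back-derived: the published
  per-course personnel saving divided by minutes saved gives
  5.61 USD/min = 3(0.71) + 2.34 + 1.14.
* **VMAT is incremental on MLC tracking.** The published 8.53 min/fraction
  for "VMAT + MLC tracking" only reproduces the published combined
  component sums if read as 8.53 *on top of* MLC tracking's 3.56
  (12.09 min/fraction combined); the prose reads as a total, the
  arithmetic says incremental. The packaged `vmat` intervention carries
  `requires: mlc_tracking` to encode this.
* **The dose-rate upgrade** (600 to 1400 MU/min) shrinks the MU-limited
  beam-on portion by `1 - 600/1400`. The underlying beam-limited time is
  not printed; 35.18 min/course is back-derived from the published saving
  divided by the delivery-set CCR sum, and stored exactly as 140.72/7
  minutes of reduction.
* **Synthetic CT** removes the one-off 20-min CT-simulation step
  (2 therapists, PET/CT simulator and room, 4.71 USD/min).

Recomputed savings differ from the published totals by a few cents to a
few dimes (e.g. MLC tracking $248.84 vs $248.88; auto-segmentation
$1,774.05 vs $1,774.27) because the published components embed CCRs at
more precision than the rate table prints. The test suite asserts
recomputed totals within $1.00 of the published figures (within $0.15
for synthetic CT) and the combined course time reduction within 2 min of
270.55; identities among printed components are checked exactly.

Combining interventions applies them sequentially in list order after
verifying that every `requires` dependency appears earlier; when edits
fit within the available minutes (as the packaged suite does), the
per-intervention savings sum exactly to the combined saving.

## The synthetic generator

`synth_workflow()` and `synth_register()` produce seeded random inputs
with known ground truth, used by the property tests: workflows with 4
stages of 2–6 steps, log-normal step minutes (median 15 min, log-sd 0.5),
headcounts 1–3 for personnel, occurrence probability 1 with probability
0.8 and Uniform(0.2, 0.9) otherwise, and a 20% chance a step repeats each
of 5 fractions; registers with three integer rater scores per dimension
drawn from a discrete triangular distribution peaked at 3. These defaults
were chosen once to exercise the code paths at realistic magnitudes; they
carry no empirical claim. The generator returns the analytic expectation
of the rollup total (a product of the component means, by independence of
the draws) and, for registers, planted RPNs, risk levels and top-k sets
computed by direct bookkeeping.

What the generator does *not* emulate: correlation between step duration
and staffing, stage-dependent duration distributions, inter-rater
disagreement structure, and the long tail of rare catastrophic failure
modes. Passing property tests therefore demonstrate the engines'
arithmetic and invariants — conservation, homogeneity, oracle
equivalence, ranking correctness — not that any particular clinic's
numbers look like the synthetic ones.

## Problem sizes and numerical tolerances

The default test run uses 200 synthetic workflows (~15 steps each) for
the conservation/homogeneity/oracle properties, registers of up to 50
modes for ranking checks, and 200 seeds for the expected-cost recovery
(asserted within 3 standard errors of the analytic expectation); the
whole suite runs in well under a minute. Cost equalities are asserted at
1e-9..1e-6 USD before display rounding; FMEA arithmetic is exact, so its
assertions are identities on the displayed two-decimal values.

## Known limitations

* No scheduling or queueing semantics: steps carry durations, not
  calendar times, so throughput and waiting are out of scope.
* No overhead-allocation model beyond the CCR, and no billing or
  reimbursement modelling.
* The fixtures cover only the published top-RPN register subset (47 of
  279 failure modes) and stage-level, not step-level, personnel minutes.
* The default risk matrix is an assumption; conclusions that depend on
  exact level boundaries should supply the clinic's own grid.
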