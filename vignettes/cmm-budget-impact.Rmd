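---
title: "A deterministic budget-impact model for pharmacist-led medication management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic budget-impact model for pharmacist-led medication management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmmbia)
```

## The question the model answers

Comprehensive Medication Management (CMM) is a standardized, pharmacist-led
service for patients on complex regimens: the pharmacist reviews every
medication, resolves drug-therapy problems (unnecessary drugs, missing
drugs, subtherapeutic doses, adverse reactions, nonadherence) and follows
up on therapy goals. From a single-payer's point of view the question is
affordability: over a short horizon, what does a nationwide roll-out cost,
and how much of that cost is offset by the healthcare it avoids?

`cmmbia` implements a deterministic, prevalence-based budget-impact
analysis (BIA) of exactly this question for patients with hypertension plus
another established cardiovascular disease (CVD) and/or type 2 diabetes
(DMT2) who take five or more medicines daily. The built-in parameterization
is the Croatian 2022--2024 roll-out; every parameter is an explicit field
of a scenario document, so the same machinery runs any comparable
parameterization.

## Model structure

One model run is pure arithmetic over a scenario; there is no sampling and
no time-stepping beyond the yearly index. For years $t = 1, \dots, T$ and
patient groups $g \in \{\text{DMT2+CVD}, \text{CVD}\}$:

**Population.** On-medication counts grow geometrically,
$N_t = N_1 (1+r)^{t-1}$, with $r$ the yearly prevalence growth. The
overlap correction assumes every diabetic also has a CVD, so
$N^{\text{DMT2+CVD}}_t$ is the DMT2-on-medication count and
$N^{\text{CVD}}_t$ the remainder. The eligible population applies the
polypharmacy share $\pi$ (five or more medicines):
$E_{g,t} = \pi N_{g,t}$, and enrollment applies the per-year fraction
$\phi_t$: $n_{g,t} = \phi_t E_{g,t}$. All of these are carried unrounded;
half-up rounding produces display headcounts only.

**Costs.** Annual visits are $V_t = v \cdot n_t$ with $v$ visits per
patient-year. Pharmacist demand is $F_t = V_t / c$ full-time equivalents,
with $c$ the annual visit capacity; labour cost is $F_t \cdot w$ and
therapy-modification cost $n_t \cdot d$ with $d$ the per-patient-year
added medication cost. Total direct cost sums labour, training and therapy.

**Utilization savings.** Each avoided-service category transfers from a
source utilization study as a per-visit rate $\rho_s = a_s \alpha_s / m$
(avoided count, adjustment, encounters), priced at the local DRG tariff:
$S^{\text{util}}_{s,t} = \rho_s V_t p_s$.

**Event savings.** Each clinical event spec carries a yearly incidence per
1000, a guideline relative risk reduction $RR$ tied to reaching the
blood-pressure target, and an efficiency $\eta$: the effective per-patient
absolute risk reduction is $\delta = (I/1000) \cdot RR \cdot \eta$.
Expected avoided events are $n_{g,t} \delta$ (unrounded; the half-up
integer is reported per cell) and savings price them at the event's unit
cost (inpatient DRG + follow-up/rehabilitation + device).

**Aggregation.** The budget impact is total costs minus total savings;
negative means the service is dominant. Per-patient metrics divide by the
total enrolled headcount over the horizon. The sensitivity scan multiplies
*both* savings-side rate families by a common factor $f$ and re-runs the
model; by linearity this equals $C - f \cdot S$, and the implementation
asserts the re-run against that closed form at $10^{-9}$ relative.

## The two parameter modes

The built-in scenario ships in two modes because the source material's
parameter tables and result tables are not mutually consistent, and we
refuse to merge them silently.

* **`published_tables`** (default) reproduces the printed *results*. It
  carries the minimal set of back-calculated effective values: the
  stroke/CVD risk reduction uses $0.0146 \times 0.315$ and the
  fatal-MI/CVD one $0.018 \times 0.18$ (the literally printed reductions
  reproduce neither the printed avoided events nor the printed savings for
  those rows); nonfatal MI, angina and revascularization are priced at
  EUR 864.79 rather than their component sums. Labour is priced on the
  unrounded FTE at EUR 28,000/year with no separate training charge — the
  only labour model that reproduces all three printed yearly labour cells
  to the euro — and therapy costs EUR 37.4733 per patient-year, the
  constant recovered to four decimals from all three printed therapy cells.
* **`as_stated`** takes the parameter tables literally: no event
  overrides, therapy at EUR 37.47, and the printed yearly labour and
  training totals as fixed inputs (those totals follow no recoverable
  formula — they are neither headcount x salary nor hires x unit training
  cost — so they enter verbatim rather than being imitated by a guessed
  derivation).

Which mode reflects the original authors' intent is undecidable from the
published record; both are first-class and a field-wise diff between them
is part of the test suite.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `visits_per_patient_year` | visits | 2 | never printed in the source; forced by back-calculation (every utilization cell equals rate x 2 x enrolled x price) and recoverable from any run's ledgers |
| `visit_capacity_per_pharmacist_year` | visits | 2904 | 11 visits/day x 264 working days |
| `annual_cost_per_pharmacist` | EUR/yr | 28,000 | salary incl. half an administrative worker |
| `training_cost_per_pharmacist` | EUR | 200 | one-off, charged on new hires (`as_stated` fallback only) |
| `therapy_cost_per_patient_year` | EUR/yr | 37.4733 / 37.47 | added medication cost from resolved drug-therapy problems |
| `efficiency` | fraction | 0.9 | pilot achieved a 9 rather than 10 mmHg systolic reduction; effect scaled linearly |
| clinic-outpatient `adjustment` | fraction | 0.7 | pharmacists cannot prescribe locally, so 30% of avoided GP visits still happen |
| `sensitivity_factors` | — | 1.05, 0.95, 0.8, 0.6 | 5% under/over and 20%/40% overestimation of the savings-side rates |

The "overestimated by $x$%" columns of the sensitivity analysis are
implemented as savings multipliers $f = 1 - x$ (and $f = 1.05$ for 5%
underestimation): back-calculation shows every printed sensitivity cell
equals $C - f \cdot S$ under exactly that reading.

## Numerical conventions

* All intermediate quantities (counts, FTE, rates, savings) are doubles at
  full precision; nothing is rounded internally. Rounding is half-up
  (half away from zero) and applies only to display columns and reported
  integer counts — `round_half_up()` exists because base R's
  round-half-to-even does not match the headcount convention (31.69
  pharmacists are 32; 87.76 events are 88).
* Savings from avoided events are computed from the *unrounded* expected
  event counts. The test suite carries an oracle showing the
  rounded-count alternative misses printed cells that the unrounded
  computation hits.
* Totals are sums of unrounded cells; printed-style totals of rounded
  integers are reported where the source tables do that (avoided-event
  totals are sums of per-cell integers).
* Replication tolerances absorb the source's own display rounding: EUR
  cells match within 0.1% or EUR 5 (whichever is larger), aggregate
  totals within 0.05%, headline figures within 0.5%. These are
  replication slacks, not model error bars. One printed figure is
  documented as internally inconsistent and deliberately not reproduced:
  the stated 3-year total savings of EUR 7,787,765.60 disagrees with the
  sum of the printed savings tables (EUR 7,757,094), which the printed
  budget impact follows. The avoided-events grand total prints as 2742,
  but the printed cells sum to 2741; we reproduce every cell and report
  their sum.
* Scenario documents are YAML (canonical) or JSON; unknown keys are
  errors, so a typoed parameter name can never silently fall back to a
  default. Validation returns violations as data (field, rule, observed
  value) rather than throwing on first failure.
* Degenerate inputs are defined: empty service or event catalogues yield
  zero savings; zero enrollment yields zero costs and savings; a
  zero-savings scenario has no finite break-even factor and reports `NA`.

## The synthetic-scenario generator

`random_scenario()` draws complete scenarios from broad bounds bracketing
plausible national parameterizations (population 1e5--1e7 log-uniform,
on-medication fractions 0.01--0.5, growth -2% to +5%, enrollment 0--20%,
avoided counts 0--12,000 against 33,706 encounters, unit prices 5--5,000
EUR log-uniform, incidence 0.5--50 per 1000, guideline reductions
0.05--0.6, efficiency 0.5--1). A single integer seed drives one stream and
the draw order is append-only, so adding a parameter later cannot
reshuffle existing draws. `perturb_scenario()` wobbles every numeric
parameter multiplicatively and preserves validity (fractions cap at 1,
the overlap ordering is restored).

The generator emulates the *structure* the model assumes — bounds-only
realism. It makes no attempt at epidemiologically coherent joint
distributions (incidences are independent across events, prices
independent of rates), and the model itself has no age/sex structure, no
mortality attrition of the cohort, no event recurrence and no correction
for patients at risk of several events at once. Passing property tests
therefore certify the arithmetic and its invariants — the accounting
identity, linearity of every savings ledger in its rates, monotonicity of
the budget impact in the savings factor, recoverability of the
back-calculated constants — not the epidemiological realism of any
particular scenario.

## Problem sizes used in the tests

The model is desk-scale: one full run (projection, three ledgers,
aggregation, four-point sensitivity scan) takes well under 50 ms. The
property sweeps run 200 random scenarios for the validity/accounting
invariants and 25--50 for the heavier per-ledger linearity and
parameter-recovery checks; the whole suite completes in well under a
minute.

## Worked run

```{r}
fit <- bia(croatia_scenario("published_tables"))
fit
```

```{r}
fit$sensitivity
```

`write_bia_tables(fit, dir)` emits each result table as CSV (population,
costs, utilization savings, event savings, avoided events, sensitivity,
plus a one-row summary and a JSON manifest with checksums);
`compare_runs()` diffs two such directories cell by cell — comparing the
two modes localizes every difference to the five documented override
families.

## Known limitations

The status quo arm is implicit (CMM is costed as a pure add-on to usual
care); savings rates transfer from a US utilization study and
international incidence studies rather than local data; DRG unit costs
understate true treatment costs, which biases the budget impact upward;
and double counting across events is possible since joint risks are
unknown. These are properties of the modelled question, faithfully kept —
the package's contribution is to make every one of them an explicit,
testable parameter rather than a spreadsheet cell.
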