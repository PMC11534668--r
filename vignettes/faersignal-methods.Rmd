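---
title: "Disproportionality analysis of spontaneous reports with faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous reports with faersignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect voluntary
safety reports with no denominator of exposure: they can never estimate an
incidence, but imbalances in *reporting* are a well-established screening
instrument for drug-safety signals. `faersignal` implements the full claim
chain of such a screen for a single target drug, using semaglutide — a GLP-1
receptor agonist marketed both as subcutaneous injections (Ozempic, Wegovy)
and an oral tablet (Rybelsus) — as the running example: ingestion of the
quarterly ASCII tables, case deduplication, primary-suspect selection, PT→SOC
coding, route-of-administration classification, reporting-odds-ratio (ROR)
signal detection, a formulation-stratified comparison, and descriptive
demographics/onset tables.

Because a spontaneous-report analysis is a chain of filtering decisions,
every stage here is a separate, inspectable function with a tabular input
and output, and the package ships a synthetic report generator whose ground
truth (case counts, per-term odds ratios, route mix, onset distribution) is
known exactly, so the chain can be validated end to end.

## The disproportionality model

For one reaction term the reports are cross-classified in the 2×2 four-grid
table

|                | term reported | term not reported |
|----------------|---------------|-------------------|
| target drug    | a             | b                 |
| all other drugs| c             | d                 |

counted at **case level**: a case contributes once to `a` no matter how many
times it lists the term. The reporting odds ratio and its Woolf-type 95%
interval are

$$\mathrm{ROR} = \frac{a/c}{b/d}, \qquad
\mathrm{CI}_{95} = e^{\ln \mathrm{ROR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d}}$$

and a signal is declared when the lower bound exceeds 1. Under the null
hypothesis of no reporting imbalance this criterion fires with one-sided
probability ≈ 2.5%, which the test suite verifies empirically on 2,000
simulated null terms.

Numerical choices, all of which matter in the tails:

* **Zero cells** make a table non-evaluable rather than being patched; the
  formula cannot produce an estimate there and inventing one invents
  signals. An optional Haldane–Anscombe +0.5 correction is available behind
  `correction = "haldane"`, off by default.
* **Minimum report count**: terms with `a < 3` are listed but marked
  non-evaluable by default (`min_count = 3`), a common pharmacovigilance
  screening convention; it is a parameter, not a constant.
* **No multiplicity adjustment** is applied — the convention of published
  ROR screens — but `glance()` always reports the number of terms tested so
  a reader can calibrate expectations.
* **Ordering** of result tables is by descending ROR among evaluable terms
  with lexicographic tie-breaks, so output is deterministic.

The half-width multiplier is the published constant 1.96 (not
`qnorm(0.975)`), because the published formula is the contract the engine is
tested against, to 1e-12 relative error on the exhaustive grid of tables
with cells 1–30.

## Deduplication and case selection

A FAERS case may be submitted repeatedly; each version shares the `caseid`
but has its own `primaryid` and received date (`fda_dt`). The selection rule
keeps, per case, the version with the **latest received date**, breaking
ties by the **numerically largest primaryid**. Received-date is the primary
key because a FAERS `primaryid` is the case id concatenated with a version
counter, so the latest received report is the current state of the case;
when dates tie (or are missing, which sorts earliest) the larger version
wins. The rule is idempotent and order-invariant, both tested, and on
synthetic data with a 20% duplicate fraction it recovers the true case count
exactly.

Target cases are those whose selected version lists the target drug with
role code `PS` (primary suspect); name matching is case-insensitive
substring over a configurable pattern list (default: semaglutide, ozempic,
wegovy, rybelsus), because FAERS drug names are free text. A case reporting
the drug only as concomitant is background, not target.

Age is normalized to years by FAERS unit code (DEC×10, YR×1, MON÷12, WK÷52,
DY÷365.25, HR÷8766). An unrecognized unit code makes the age unusable; a
*missing* code with a recorded age is read as years, the de-facto FAERS
convention.

## Partial dates and time to onset

FAERS dates come at day, month or year precision; `faersignal` keeps the
integer value plus a precision tag and never coerces. Time-to-onset is
`event_dt − therapy_start` in days, defined only when both sides have day
precision; `therapy_start` is the earliest day-precision start date among
therapy rows pointing at a target-drug row. Negative onsets (event dated
before therapy start — real in FAERS, due to coding errors or pre-existing
events) are **excluded and counted**, not clipped: clipping to zero would
bias the quartiles downward silently. Onset quartiles use
linear-interpolation quantiles (`stats::quantile` type 7); no convention is
canonical in the field, so the most common default is used and stated.

Because FAERS does not date individual reactions, onset is a case-level
approximation of the PT-level quantity; this is the only defensible reading
of report-level data.

## Route classification

The formulation of each target case is identified from four free-text
fields in fixed precedence: explicit `route`, then `dose_form` keywords
(tablet → oral; solution/pen/injection → subcutaneous), then trade name
(Rybelsus → oral; Ozempic/Wegovy → subcutaneous), then `dose_freq`
(daily → oral; weekly → subcutaneous). Structured fields outrank the trade
name, which outranks frequency, because an explicit route is the least
ambiguous evidence. The first level with a hit decides and is recorded as
evidence; if keywords for *both* formulations fire at that level the case is
left unclassified with a conflict flag — conflicts are surfaced, never
resolved by guessing. Cases with no identifying information are excluded
from the comparison (and counted). The keyword sets live in a YAML rulebook
(`inst/extdata/route_rules.yaml`), not in code, because FAERS free text
drifts over time.

## Counting conventions in the descriptive tables

* SOC and PT frequency tables count **(case, PT) events**, not cases: a
  case with three gastrointestinal PTs contributes three events. This is
  the unit under which published SOC columns sum to their event totals.
* Demographic tables use the **case** as unit with the full cohort as
  denominator throughout, so age bands (with unknown as its own band) and a
  truncated country list need not sum to 100%.
* Report year comes from the received date, since yearly rows describe
  reporting volume, not event timing.
* Percentages are rounded **half-up to 2 decimals** everywhere. Published
  tables of this kind mix conventions row by row; one convention is chosen
  and applied uniformly, and every emitted table recomputes exactly from its
  own counts.
* The serious-outcome set defaults to all outcome codes except `OT`
  ({DE, LT, HO, DS, CA, RI}); a death/life-threatening-only rate is one
  argument away. The choice is a parameter because "serious" is not
  enumerated consistently across studies.

The comparison with coded social-media reviews consumes a table of already
MedDRA-coded reviews (one row per review, semicolon-joined PT list);
free-text mining is out of scope, since that transformation is a manual,
human step. Review tables run through the same event mapping and frequency
machinery via `map_events(..., id_col = "review_id", pts_col = "pts")`.

## The synthetic generator

`simulate_reports()` generates the five quarterly tables with every
estimable quantity controlled:

* **Embedded per-term odds.** For a term with embedded ROR $r$ and
  background occurrence probability $p_b$ (default 0.01), the target-arm
  probability solves the odds equation exactly:
  $\mathrm{odds}_t = r \cdot p_b/(1-p_b)$, $p_t = \mathrm{odds}_t/(1+\mathrm{odds}_t)$.
  The population reporting odds ratio is therefore $r$ by construction, not
  approximately. A case that draws no catalog term receives the filler term
  "Drug ineffective", which is outside the catalog and leaves the embedded
  odds untouched.
* **Duplicates** share a `caseid` with increasing `primaryid`s and
  non-decreasing received dates; by default later versions differ *only* in
  those two fields, which isolates the deduplication contract (field-level
  noise is available behind `duplicate_noise = TRUE`).
* **Route mix** defaults to 13% oral / 85% subcutaneous / 2% unclassifiable,
  the magnitude of the published formulation split; field missingness and
  plain substance names make a small additional fraction unrecoverable,
  which is exactly what the evidence/conflict bookkeeping is for.
* **Onset** is log-normal rounded to integer days with median 4 and
  `sdlog = log(8)/qnorm(0.75) ≈ 3.08`, i.e. an upper quartile of 32 days —
  the strongly right-skewed shape reported for gastrointestinal reactions to
  this drug class.
* **Demographics and missingness** mimic the published cohort: ~62% female,
  ~47% missing age, US-dominated reporter countries, serious-outcome code
  probabilities that put the {DE..RI} rate near 3%.

One RNG is seeded once per run and the caller's RNG state is restored, so
identical configuration and seed give byte-identical output files.

What the generator deliberately does **not** emulate: drug-name
misspellings, correlated reactions within a case (terms are drawn
independently), secular reporting trends (dates are uniform over the
window), duplicated cases with *different* caseids, and multiaxial MedDRA
coding. Passing tests therefore demonstrate that the pipeline computes its
estimands correctly under controlled conditions — not that real FAERS data
are free of the biases those features create.

## Validation scale and what the suite shows

The test suite and the acceptance script validate, at sizes chosen to make
Monte-Carlo error small relative to the tolerances:

* ROR engine vs an independently coded log-odds oracle on the exhaustive
  810,000-table grid with cells 1–30 (1e-12 relative);
* null calibration on 2,000 simulated null terms at 5,000 cases per arm:
  signal rate within 3 Monte-Carlo standard errors of 2.5%;
* interval coverage of embedded RORs {0.5, 1, 2, 5, 36} (8 terms each,
  5,000 cases per arm) at ≥ 90%, with the ROR-36 arm always flagged;
* exact dedup recovery at a 20% duplicate fraction.

The published headline quantities of a full-database semaglutide screen
(19,289 cases, the specific extreme-term RORs, the 2,487/785/932 PT Venn
counts) require the complete multi-year FAERS extraction plus a licensed
MedDRA dictionary and are **not** reproduced here; the packaged ~90-term
dictionary is a synthetic demonstration fixture, and a licensed MedDRA
export in the same two-column TSV layout is a drop-in replacement. What the
suite shows is that every operator applied to such data computes the right
quantity.

## A small worked run

```{r, eval = FALSE}
cfg <- sim_config(n_cases_target = 1000, n_cases_background = 1000, seed = 7)
res <- run_pipeline(run_config(simulate = TRUE, sim = cfg,
                               output_dir = tempfile(), seed = 7))
glance(res$signals)
tidy(res$signals) |> filter(is_signal)
autoplot(res$signals, signals_only = TRUE)  # forest plot
```

## Known limitations

* The comparator is "all deduplicated cases where the target drug is not
  primary suspect"; other background definitions (all drugs including the
  target, drug-class-restricted comparators) change RORs and are not
  currently configurable.
* Single-SOC dictionary: multiaxial PTs are assigned whatever SOC the
  dictionary row carries; primary-SOC logic is out of scope.
* No probabilistic duplicate detection across different caseids, and no
  drug-name normalization beyond substring patterns.
* ROR is a reporting imbalance, not a risk estimate; nothing in this
  package estimates incidence.
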