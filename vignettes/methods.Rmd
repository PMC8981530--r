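---
title: "Methods: DDD costing, therapeutic substitution and the savings counterfactual"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DDD costing, therapeutic substitution and the savings counterfactual}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statincost)
```

## The problem

Five statins (simvastatin, atorvastatin, rosuvastatin, pravastatin,
fluvastatin) dominate lipid-lowering prescribing in English primary care.
They are therapeutically close substitutes, but their acquisition costs
diverged dramatically over 2003--2018 as simvastatin (May 2003) and then
atorvastatin (May 2012) lost patent protection and generic competition
collapsed their prices. Under a cost-minimisation view of a therapeutic
class with comparable efficacy, every initiation of a still-patented statin
when a generic equivalent exists forgoes money the health system could have
kept. This package quantifies those forgone savings, describes how quickly
and how unevenly practices moved to the cost-effective choice, and provides
a synthetic data generator so the whole pipeline can be exercised and tested
without access to confidential prescription extracts.

## Cost standardisation

Annual price tables record, per (year, statin, strength), total tablets
dispensed and total spend at net ingredient cost (NIC) — the basic
acquisition cost of the dispensed drug, before fees and discounts. Two
derived quantities drive everything downstream:

* **Unit cost** per tablet: spend / quantity for one strength-year.
* **Cost per DDD**: strengths of one statin in one year are pooled by total
  milligrams, `DDD_mg * sum(spend) / sum(quantity * strength_mg)`. The WHO
  defined daily dose (DDD) — 20 mg atorvastatin, 60 mg fluvastatin, 30 mg
  pravastatin, 10 mg rosuvastatin, 30 mg simvastatin — converts a cost per
  milligram into a cost per treated day, the only scale on which drugs of
  different potency can share one axis. Milligram pooling is the one scheme
  that yields a single curve per drug without arbitrary strength weights;
  it is exactly a quantity-weighted average of per-strength costs.

Money amounts are expressed in constant 2018 GBP by multiplying by
`100 / index(year)` with a GDP-deflator series indexed to 2018 = 100.
Calendar-year indices are used (the price tables are calendar-year);
deflation applies to money only, never to quantities, and a year missing
from the series is an error rather than an extrapolation. A small
approximate UK series ships as the default; supply an exact one for real
analyses.

Prices are annual, so a prescription issued in any month of a year is
costed at that year's average acquisition cost — the resolution of the
source price statistics is the resolution of the costing.

## Therapeutic substitution

The counterfactual prescriber always chooses the policy comparator:
simvastatin strictly before May 2012, atorvastatin from May 2012 onwards
(the month generic atorvastatin arrived). Substitution must preserve
treatment intensity, which is banded by percentage LDL-cholesterol
reduction: 20--30% low, above 30% to 40% medium, above 40% high. The bands
are read as contiguous intervals on a continuous scale, so 30 is low and 40
is medium; reductions below 20% fall below any band and are rejected.

`equivalent_dose()` maps a (statin, dose) to the **smallest** target dose in
the same band — cost-minimising whenever price is monotone in dose, which
is the natural tie-break given that the comparator is chosen on cost. When
the target has no dose in the band (e.g. no atorvastatin dose is
low-intensity), the smallest target dose achieving at least the source's
reduction is used; if even the strongest target dose falls short, that
strongest dose is returned flagged `band_unmatched`. Substituting a drug
onto itself is the identity.

The shipped equivalence table follows the standard NICE LDL-reduction
intensity groupings. The unit tests deliberately exercise the substitution
logic on small synthetic tables as well, so its correctness does not hinge
on any particular transcription of published dose--response values.

## The two savings scenarios

Each record's **actual** cost charges
`tablets * min(days_supplied, cap) / days_supplied` tablets at the
strength-year unit cost, deflated to 2018. The **hypothetical** cost prices
the same tablet count and duration at the comparator's equivalent-dose unit
cost; records already on the comparator are a fixed point. Day-capping
prorates tablets by the day fraction, which keeps the result neutral to
pack-size conventions.

* **Scenario 1 (first episodes)** restricts to first prescription episodes
  and caps costing at 28 days: the cost of starting every new patient on
  the comparator, free of any assumption about ongoing treatment histories.
* **Scenario 2 (all patients)** costs every record in full. Substitution is
  evaluated per record at its own issue month, so patients straddling the
  cutover are substituted to simvastatin before it and atorvastatin after
  it. This is an upper bound: it assumes ongoing patients could be switched
  immediately and costlessly, ignoring intolerance, review appointments and
  clinical inertia.

Per calendar year the scenario reports patient counts (first episodes, or
distinct patients with any record), actual and hypothetical cost, and
absolute and relative savings, plus a cumulative row. Savings are defined
as actual minus hypothetical, so cost conservation
(`actual = hypothetical + savings`) holds by construction and is asserted,
together with linearity in tablet counts and agreement with an independent
per-record brute-force summation, in the test suite. Patient counts can be
rescaled to a national level with a single multiplicative ratio
(`scale_to_national()`); results are sample-level by default.

## Trend and heterogeneity descriptives

* `market_shares()`: per month or quarter, the share of new patients
  (first-episode records) initiated on each statin. Periods with no new
  patients are kept with an explicit `NA` marker rather than dropped.
* `quintile_means_dynamic()`: practices ranked every period by their own
  share of new patients on the focal statin, split into quintiles at ranks
  `ceiling(k * N / 5)` (ties broken by practice identifier — the data give
  no better key), and unweighted group means reported. Practice means are
  unweighted by volume: the quantity described is variation *across
  practices*, not across patients.
* `quintile_means_fixed()`: membership frozen at a baseline period (default
  Q3-2003, the first study quarter) and group means tracked forward. The
  contrast between the two modes separates persistent practice-level
  differences from churn: practices swapping ranks period to period inflate
  the dynamic gap but not the fixed one.
* `switch_away_rate()`: among patients switched onto a target statin
  (target preceded by a different statin), the percentage receiving a
  non-target statin within a window (4 or 12 months) of the switch —
  a descriptive proxy for intolerance of, or reversal from, the
  cost-effective choice. Patients never prescribed again remain in the
  denominator; with no switch events the rate is undefined (`NA`), not zero.

All of these are descriptive; the package deliberately fits no changepoint
or interrupted time-series models.

## The synthetic cohort generator

The generator exists so that every stage has realistic, fully reproducible
input. It makes the data-generating assumptions explicit rather than
claiming to reconstruct any real extract:

* **Prices.** Each statin has a branded real price per DDD (defaults
  0.60--0.90 GBP/DDD across the five drugs), constant until patent expiry,
  then multiplied by 0.70 per quarter down to a floor of 5% of the branded
  price — a stylised generic-entry collapse with the two historical expiry
  dates (May 2003, May 2012) as defaults. A tablet of strength *m* costs
  `ddd_price * (m / DDD)^0.8`: sublinear in strength, as higher strengths
  are cheaper per milligram. Dispensed quantities are log-normal around
  configured volumes (they act only as pooling weights).
* **Choice.** Practice *p* holds a preference `alpha(p, s) ~ N(0, sigma^2)`
  per statin, drawn once. New patients arrive as a Poisson stream spreading
  a yearly volume schedule (linear 1.15M down to 782K per year, scaled by
  `sample_frac = 1/1000` for desk-scale runs) evenly over months and
  practices. The initial statin is multinomial-logit with utility
  `alpha - beta * price_per_DDD + gamma * recommended`, with defaults
  `beta = 5` per GBP/DDD and `gamma = 1` (the scale on which the observed
  50→90→10% share swings arise from price movements of tens of pence per
  DDD), and a guideline history recommending simvastatin from January 2006
  and atorvastatin from May 2014. The logit form is this generator's
  explicit modelling assumption, not a claim about how prescribers actually
  decide.
* **Persistence.** Patients receive one 28-tablet prescription per month at
  the statin's modal strength until discontinuation (geometric, monthly
  hazard 0.05 — a mean of 20 months on treatment) and are switched to the
  current policy comparator with probability 0.02 in each later month.
  Default heterogeneity is `sigma = 1`, enough to produce the wide
  practice-level quintile fans seen in real prescribing data.

A single integer seed drives every draw; generation is wrapped in a scoped
seed (the caller's RNG state is saved and restored), which gives the same
byte-identical-output contract as threading an explicit generator state
object while staying idiomatic R. Identical seeds give identical record
tables and, downstream, identical pipeline manifests.

What the generator does **not** emulate: patient covariates (age, sex,
risk), secondary-care initiation, commissioning-group effects, seasonal
prescribing, strength mixes within a statin, or intolerance-driven
switch-backs. Tests passing on synthetic cohorts therefore demonstrate the
pipeline's arithmetic and its qualitative behaviour under the stated
process — not representativeness of any real population.

## Validation design

The suite checks, among others:

* both scenarios against an independent brute-force per-record summation
  (no shared grouping code) on random fixtures of at most 20 records, at
  `1e-9` relative tolerance;
* cost conservation and tablet-linearity on 200 random fixtures;
* the comparator fixed point (comparator-only cohorts yield zero savings);
* at 50,000+ initiations with homogeneous practices, generated shares
  within three multinomial standard errors of the logit probabilities, and
  a two-parameter conditional-logit refit (aggregated month-by-statin
  counts, `stats::optim`) recovering the price coefficient within 15%;
* the qualitative share shape under the default two-expiry price
  configuration — the pre-cutover comparator's initiation share rises by
  more than 0.2 between the window start and the cutover quarter and falls
  by more than 0.2 by the window end — and a dynamic top-minus-bottom
  quintile gap increasing in `sigma` over {0, 0.5, 1, 2};
* an exhaustive scan of the shipped equivalence table confirming every
  substitution preserves the intensity band whenever the target has a
  same-band dose.

Simulation sizes are chosen for speed with wide margins: full-window
cohorts at `sample_frac = 1/1000` hold roughly 15,000 patients and 275,000
records and generate in about two seconds; the logit-recovery cohorts use
`sample_frac = 1/290` with a one-month treatment duration to reach 50,000
initiations without inflating record counts.

## Known limitations

* Costing ignores dispensing fees, discounts and concessionary
  adjustments: NIC only.
* Annual price resolution means within-year price movements (e.g. the
  months right after an expiry) are smoothed into the year average.
* The equivalence mapping models intensity only — no contraindications,
  interactions, or primary- versus secondary-prevention targets.
* Scenario 2's immediate-switch assumption makes it an upper bound by
  construction.
* Whether a source dose sitting exactly on a band boundary should map to
  the same band or the neighbouring one is a genuine convention choice; the
  inclusive-upper-bound reading (30 low, 40 medium) is fixed and
  documented here.
* The price quantity column is tablets throughout; sources reporting packs
  must be converted before ingestion.
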