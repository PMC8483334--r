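---
title: "Modelling cardiovascular disease policy with cvdflow: methods and design"
author: "cvdflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiovascular disease policy with cvdflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdflow)
```

## The model

`cvdflow` is a deterministic stock-and-flow (system dynamics) simulator of
cardiovascular disease (CVD) in an open population aged 40 and over, built
for strategic policy comparison rather than clinical or operational detail.
The state of the model is a person count per compartment and 5-year age band
(40–44 … 85+). Compartments comprise a disease-free stock, transient acute
stages — pre-hospital and in-hospital, for acute coronary syndrome (ACS) and
stroke, each split into initial and recurrent events — a chronic CVD
community stock, and a short-stay chronic in-hospital stock. Sink
accumulators count deaths by place (pre-hospital, in-hospital, community,
and non-CVD), hospitalisations by type, acute discharges, and demographic
entries and exits; they are the raw material for every reported outcome.

People enter by turning 40 (an exogenous, slowly growing inflow) and by net
migration, and exit through CVD and competing non-CVD mortality. Ageing
between bands is a first-order flow at rate 1/(band width) per year — the
standard compartmental approximation of cohort ageing. It smooths cohort
waves relative to a bookkeeping (shift-register) scheme; the consequences
for projections are discussed under *Limitations*.

Integration is explicit Euler with a default step of 0.1 year. Two
safeguards make this simple scheme dependable. First, outflows from any
(stock, age band) cell are jointly capped at the cell's content within a
step and scaled proportionally on breach, which preserves non-negativity
*and* branching fractions even for the very fast acute stages (mean
residence times of days). Second, conservation is checked in tests: at
every step the change in total persons equals entries plus net migration
minus all deaths to machine precision. Cumulative 20-year deaths change by
less than 1% between steps of 0.1 and 0.05 years, and linear test models
agree with matrix-exponential solutions.

### Case fatality as competing hazards

Stage inputs arrive as a case-fatality probability `p` and a mean residence
time `tau`. A transient stage is modelled with total exit hazard `1/tau`
split into a death hazard `p/tau` and a continuation hazard `(1-p)/tau`.
With this *fractional allocation* the probability of dying in the stage is
exactly `p` in the small-step limit and is preserved at coarse steps by the
proportional outflow cap. We chose it over the textbook period-probability
conversion `-log(1-p)/tau` (available as `probToHazard()`) because the
latter, combined with an independent exit hazard, biases the branching
probability away from `p` — and the stage case-fatality split is precisely
the quantity the model must honour (it drives the death-place distribution
and every acute-response strategy).

## Strategies as ramped parameter overlays

Eight broadly defined strategies act as multiplicative overlays on model
parameters, in three reporting groups:

* **Supportive environment** — salt reformulation (sodium −10% over 4
  years), physical activity (two levers, each −5 percentage points of the
  inactive proportion), smoking (prevalence glide to ~6% over 20 years).
  These scale initial and recurrent incidence through parameterised
  risk links.
* **Acute response** — public-access defibrillators (−50% deaths after
  out-of-hospital cardiac arrest, applied to the arrest-amenable share of
  pre-hospital ACS deaths) and pre-hospital delay reduction to a 2-hour
  target (−20% acute death probabilities among the time-critical-amenable
  share).
* **Medication and treatment** — preventive prescription (+7.5 percentage
  points of eligible adults treated, the midpoint of 5–10), adherence
  (+15% relative, midpoint of 10–20), cardiac rehabilitation (+22.5%
  relative completion, midpoint of 15–30, lowering recurrent ACS risk).

At time `t` a strategy with full-effect multiplier `m`, eligible fraction
`e` and rollout fraction `f(t)` contributes a factor `1 - e f(t) (1 - m)`
to each targeted parameter; concurrent strategies combine multiplicatively
(hence order-invariantly), and probability-valued parameters are clamped to
[0, 1]. The rollout fraction is a linear ramp over 2–10 years; where risks
respond to exposure with delay (salt, physical activity, the medication
strategies) the emitted fraction is the exact first-order lagged response
to the ramp with time constant `riskLag`. The smoking strategy is a
prescribed prevalence trajectory, implemented as an exponential glide that
reaches ~95% of its endpoint at 20 years; its 20-year duration is the one
deliberate exception to the 2–10-year ramp band. Cost-side targets
(medication spend, rehabilitation participation) track the rollout
directly, without the risk lag — uptake is paid for as soon as it happens,
while its health benefit accrues later; this is what produces early
negative net benefit for the medication group.

Percentage-point versus relative readings follow the most natural reading
of each magnitude: prescription ("5 to 10%") is a percentage-point increase
in the treated proportion, adherence and rehabilitation are relative
increases, and the two physical-activity levers are percentage-point
reductions of the inactive proportion. Each range's midpoint is the
deterministic default; the full range feeds the sensitivity analysis.

Risk-factor links (salt → blood-pressure-mediated risk, inactivity and
smoking prevalences with relative risks, treatment uptake with a risk
ratio) are single population-average relative-risk mappings with their own
parameters, so every magnitude can be replaced when better evidence is
available. Eligibility is a fractional weight on the incidence reduction
rather than explicit treated/untreated stocks — the key structural
simplification; it halves the state space at the cost of within-group
heterogeneity.

## Economics

Health outcomes (deaths, hospitalisations) are reported undiscounted;
economic quantities are discounted at 5% per year from the 2019 rollout
year, each flow at its mid-step time. Quality-adjusted life years accrue as
person-time weighted by state utilities (disease-free 0.86, chronic 0.73,
acute and in-hospital 0.60) and are monetised at AU$50,000 per QALY. Costs
comprise flow-linked unit costs (acute admissions by type, chronic
admissions, rehabilitation participation) and stock-linked per-person-year
management costs, each split across Commonwealth, state/territory and
consumer payers; household costs (out-of-pocket and carer time per
person-year) and friction-cost productivity (working-share-weighted value
per chronic person-year plus a per-death friction value) extend the
perspective. Net benefit under the health-system perspective is monetised
QALY gain minus the health-service cost delta; the societal perspective
subtracts the household delta and adds productivity gains. Implementation
costs of the strategies themselves are deliberately out of scope — the
model prices flow-on service use, not programme delivery.

## Uncertainty and calibration

The probabilistic sensitivity analysis samples the uncertainty table by
Latin hypercube (via the `lhs` package; a counting test pins the
one-draw-per-stratum property), with 250 draws as the default and uniform
distributions where evidence is thin. Base case and scenario are simulated
under the *same* draw — uncertainty intervals are reported on outcomes
*relative* to the base case, and only paired draws keep those differences
tight; a regression test demonstrates the inflation under independent
draws. Intervals are interquartile ranges with linear order-statistic
interpolation (`quantile` type 7, pinned in tests). The shipped uncertainty
table mirrors the strategies' stated magnitude ranges plus ±25% on the
remaining effect sizes, standing in for a fuller evidence-derived list.

Calibration minimises the sum over 2011–2017 and both series (annual CVD
deaths and hospitalisations) of squared relative errors — relative, so the
two differently scaled series weigh equally — over a small set of bounded
global multipliers (incidence, recurrence, chronic admission scales), using
`optim` L-BFGS-B with numerical gradients. A self-consistency test
perturbs the multipliers by ±20%, regenerates targets from the model
itself, and requires recovery within 2%. Structural validity is probed by
an extreme-condition battery: zero incidence (flat CVD accumulators), total
pre-hospital fatality (no admissions), zero entry (population decays to
zero), zero discounting (present value equals nominal).

## The synthetic default parameter set

The authoritative numeric inputs of the published model live in its
supplementary appendix and are not redistributed here. The package instead
ships a *synthetic* parameter set (`generateDefaultParams()`), constructed
in two stages: magnitudes were first set from public Australian-scale
facts (a 40+ population near 12 million, age-graded incidence roughly
doubling per decade, Gompertz-like background mortality, acute stage
residence times of days), then a handful of levers (incidence gradients,
case-fatality levels, chronic admission and community death rates, initial
chronic prevalence) were adjusted so the base-case run reproduces the
published aggregate behaviour it is meant to emulate: roughly 1.3 million
CVD deaths and 11.7 million CVD hospitalisations over 2019–2039, a death-
place split near 55:20:25 (pre-hospital : in-hospital : community), a
chronic share of hospitalisations near 60%, and a strong escalation of
annual burden (about +73% deaths and +79% hospitalisations across the
horizon in this parameterisation). Matching synthetic calibration targets
for 2011–2017 are generated by the model itself with seeded multiplicative
lognormal noise (sigma 0.02).

What passing tests on this fixture do show: the machinery — integration,
conservation, strategy overlays, economics, sampling, calibration — behaves
correctly, and the model reproduces the *qualitative* published pattern
(prevention reduces both deaths and hospitalisations; acute response saves
the most lives but increases hospitalisations through recurrent admissions
among survivors; benefits at 20 years are several times those at 3 years;
prevention's societal net benefit exceeds its health-system net benefit
while acute response's does not). What they do not show: agreement with the
published point estimates beyond fixture scale, because the synthetic
inputs are not the appendix inputs. In particular, the fixture's annual
death growth (+73%) falls short of the published +80%, a consequence of
the first-order ageing chain smoothing the real age-structure wave; and
the split of societal net benefit between productivity and health gains
depends on productivity valuation inputs we set conservatively.

## Numerical and design choices

* Step size 0.1 year by default; every routine accepts a coarser or finer
  step. Tests and the sensitivity analysis use 0.2–0.5-year steps where
  only aggregate 20-year quantities matter (a full 28-year run at dt = 0.1
  takes well under a second; a 100-draw paired PSA a few tens of seconds).
* Migration applies to the disease-free stock by default
  (`demography.migration_applies_to = "all"` extends it to every living
  stock); migrant CVD prevalence is otherwise unspecified.
* Recurrent events originate from the chronic community stock only; early
  re-infarction from the acute in-hospital state is not modelled.
* The economic base year equals the rollout year (2019); both are
  configurable metadata.
* Discounting uses `(1+r)^(-t)` at mid-step flow times; with r = 0 present
  value equals nominal value exactly.
* Parameter files are YAML with a versioned schema; unknown keys are
  errors, which catches typos in strategy target paths early.
* Degenerate inputs: empty scenarios return base parameters unchanged;
  zero-death windows make the death-split summary an error rather than a
  0/0; uncertainty entries with `lo == hi` reproduce the point estimate in
  every draw.

## Limitations

The model is strategic, not operational: no within-hospital pathways, no
socioeconomic or Indigenous stratification, no implementation costing, no
feedback from resource constraints. The first-order ageing chain
understates cohort waves, which damps projected burden growth relative to
a full demographic projection. The published prose and its results table
disagree on the supportive-environment net benefits (AU$12.9B vs AU$17.97B
health-system; AU$34.2B vs AU$43.28B societal at 20 years); we treat the
table as authoritative where a comparison is wanted, and surface rather
than resolve the discrepancy. All strategy effects here flow through a
small set of population-average risk links; interactions between risk
factors are multiplicative by construction.

## A worked comparison

```{r example, eval = FALSE}
gen <- generateDefaultParams(seed = 1)
params <- gen$params
base <- simulateModel(params)
supp <- simulateModel(params, namedScenario("supportive_environment"))
relativeReduction(supp, base, "deaths", 20)            # ~8.8 (%)
netBenefit(supp, base, params)                         # Table-2-style rows
psa <- runPsa(namedScenario("supportive_environment"), params,
              n = 250, seed = 1)
subset(psa@summary, outcome == "deaths_reduction_pct" & checkpoint == 20)
```
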