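---
title: "Methods: a decision-tree / Markov model for antiplatelet therapy after ACS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-tree / Markov model for antiplatelet therapy after ACS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsCEA)
```

`acsCEA` estimates the lifetime cost-effectiveness, from the perspective of
the German statutory health insurance, of twelve months of ticagrelor
versus clopidogrel (each on top of low-dose aspirin) after an acute
coronary syndrome (ACS).  This vignette is the package's own account of
the model: its structure, the conventions we had to fix where the source
evidence leaves them open, the synthetic-data machinery used for testing,
and the known limitations.

## Model structure

The model has two parts, run per treatment arm and then compared.

**Year 1 — decision tree.**  The first year uses trial-observed,
arm-specific probabilities of three mutually exclusive endpoints:
non-fatal myocardial infarction (MI), non-fatal stroke, and death from
any cause; the remainder of the cohort ends the year event-free.  The
year is valued directly: each outcome carries a utility weight (the
"death" utility is the average within-year quality-adjusted accrual of
decedents, not a state utility), decedents are credited half a life-year,
and costs comprise the first-year event costs, a one-off cost of death,
and the drug cost (below).

**Years 2+ — Markov cohort model.**  Annual cycles advance a six-state
cohort: `no_event`, tunnel states `mi_y1` / `stroke_y1` (exactly one
cycle after a non-fatal event), `mi_post` / `stroke_post` (all later
post-event years), and absorbing `dead`.  Survivors of a first-year
non-fatal event enter the corresponding tunnel state at cycle 1, so the
first-post-event-year costs and mortality hazard ratios apply to their
first Markov cycle.  From `no_event`, annual probabilities `q_mi` and
`q_stroke` send patients to the tunnel states; after a non-fatal event no
further non-fatal events occur (post-event states only transition to
death).  Treatment acts only through the year-1 probabilities: all
long-term transition probabilities are common to both arms, so the arms
differ in the long run only through their state mix at the end of year 1.

**Mortality.**  Background mortality comes from a sex-specific life
table; the cohort's annual death probability mixes male and female `qx`
by the cohort's male fraction.  On the hazard scale this background is
combined with the annual fatal-cardiovascular-event probability
`q_cv_fatal`, and the state-specific hazard ratio (HR) multiplies the
combined hazard:

$$p_{\text{death}}(a, s) \;=\; 1 - \exp\!\big[-\big(h_{\text{lt}}(a) + h_{\text{cv}}\big)\, \mathrm{HR}_s\big],
\qquad h = -\log(1 - q).$$

The base-case HR set is 1 (no event), 1.6 / 1.4 (MI year 1 / later) and
3.23 / 1.5 (stroke year 1 / later); an alternative "global model" set
(2, 6, 3, 7.43, 3) ships for sensitivity analysis.  Whether the HRs
should multiply the combined hazard or only its life-table component is
not decidable from the source material; we multiply the combined hazard —
a single, conservative knob that keeps post-event mortality above
event-free mortality at every age.  Fatal CV risk is deliberately *not*
removed from the life table, so overall mortality is somewhat
overestimated by construction.

**Ordering of competing transitions.**  Within a cycle, death is applied
first and the non-fatal event split acts on survivors.  The source is
silent on this ordering; applying death first keeps every row of the
trace an exact probability distribution (sums to 1 within $10^{-12}$),
which the test suite asserts, and makes the tunnel bookkeeping exact.
There is no half-cycle correction: state membership is evaluated at cycle
end, and the year-1 half-credit for decedents plays that role in the
decision tree.  Age advances one year per cycle, starting at
`start_age + 1` for cycle 1; age-band utilities switch at exact ages 70
and 80; ages below 60 use the 60–69 band (no younger band is reported).

## Valuation

Discounting is annual at 3% for both costs and effects in the base case;
the decision-tree year carries discount index 0 and Markov cycle $t$
index $t$.  Life-years per cycle are the living occupancy; QALYs weight
occupancy by the age-band utility minus the MI/stroke decrement (year-1
versus later variants); costs weight occupancy by annual state costs
(first-post-event-year totals in the tunnel states, "following years"
totals afterwards; the event-free state costs nothing but drugs in the
base case).

**Drug cost.**  Therapy runs one year, so drug costs arise only in the
decision tree: `drug_days × DTC × (1 − p_death × (1 − f))`, with daily
therapy costs (DTC) of EUR 2.90 for ticagrelor and EUR 0.72 for generic
clopidogrel (EUR 0.35 lowest-generic and EUR 2.38 branded in scenarios),
`drug_days = 365`, and `f = drug_death_fraction = 0.5`: decedents accrue
half a year of drug cost.  The half-year convention is a derived
calibration — the published gap between the two price scenarios'
incremental costs matches `365 × ΔDTC × (1 − p_death/2)` and not
full-year exposure — and it is configurable.

**Death cost.**  The one-off cost of death (EUR 8,650) is charged for
deaths in the decision-tree year only.  This is a deliberate package
convention: the amount is derived from the trial's observed distribution
of death causes, which applies to deaths within the treatment year;
extending it to every later background death would make terminal-care
costs the dominant lifetime cost component and puts the per-arm lifetime
totals far above the published ones, while the year-1-only convention
reproduces them closely.  Later deaths therefore accrue no event cost
(their cost consequence is the *end* of the post-event annual streams).

**Dominance and ICERs.**  Increments are ticagrelor minus clopidogrel.
When one strategy is cheaper and more effective it dominates and no ICER
is reported; a zero effect difference leaves the ICER undefined rather
than infinite.  ICERs are invariant to the cohort-scale normalisation,
which the tests assert.

## Survival calibration and extrapolation

Long-term annual probabilities derive from Weibull event-time models,
$S(t) = \exp[-(t/\lambda)^k]$.  Two routes are implemented:

* `fit_weibull_mle()` — maximum likelihood on right-censored
  individual-patient data, fitted per endpoint (records of other
  endpoints count as censored, matching marginal per-endpoint
  regressions).  Optimisation runs on $(\log k, \log\lambda)$ with an
  analytic gradient (BFGS followed by a Newton polish), convergence
  declared at a per-observation gradient norm of $10^{-8}$ with an
  iteration cap of 500, and the log-parameter covariance taken from the
  observed information.  Fitting each arm separately is equivalent to a
  saturated two-arm regression.
* `calibrate_from_probs()` — when only a first-year cumulative
  probability $p_1$ and a conditional second-year probability $p_2$ are
  known, the pair inverts in closed form via
  $2^k - 1 = \log(1-p_2)/\log(1-p_1)$; equal probabilities give $k = 1$
  (memoryless).  The second-year conditional probability,
  $(S(1)-S(2))/S(1)$, is held constant beyond year 2 in the cohort model.

The test suite cross-checks the MLE against `survival::survreg` and a
Kaplan–Meier oracle, and verifies the round-trip identity of the
calibration to $10^{-10}$.

## Synthetic data

No patient-level data are distributable, so the package generates its
own, in two places.

**Individual patient data** (`generate_ipd()`): one latent Weibull time
per endpoint, earliest wins (competing risks), administrative censoring
at the 6-, 9- or 12-month visit with a configurable mix, default
(0.2, 0.2, 0.6), mimicking an event-driven trial in which some patients
leave at their 6- or 9-month visit.  Latent shapes come from the
closed-form calibration; latent scales are then recalibrated by a
fixed-point loop (at most 5 rounds) so the *marginal* (competing-risks)
12-month cumulative incidence of each endpoint matches the configured
first-year probability — the achieved incidences are verified by
numerical integration at each round.  Event times are recorded at day
(1/365) resolution, which biases a fitted shape of $k \approx 0.5$
upward by a few percent while leaving the year-1 and conditional year-2
probabilities essentially exact; the tests document this.  The generator
emulates event timing and censoring only: no covariates, regions,
aspirin dose or adverse events, so passing tests say nothing about
covariate-adjusted analyses of real data.

**Life tables** (`generate_life_table()`, `bundled_life_table()`): a
Gompertz–Makeham hazard $h(a) = \alpha + \beta e^{\gamma a}$ integrated
over each year of age, closed with $q_x = 1$ at age 110.  Two fixtures
ship: `synthetic_default` (one schedule for both sexes,
$\alpha = 5\times10^{-5}$, $\beta = 3.5\times10^{-5}$, $\gamma = 0.095$)
and `german_2009_synthetic`, a per-sex reconstruction whose parameters
were calibrated once against published summary levels of German period
mortality around 2009 (annual death probabilities at ages 40–90 and life
expectancy at ages 60–65, males $\alpha = 5\times10^{-4}$,
$\beta = 2.75\times10^{-5}$, $\gamma = 0.0958$; females
$\alpha = 3\times10^{-4}$, $\beta = 7.2\times10^{-6}$,
$\gamma = 0.108$).  It is a synthetic stand-in, not a transcription of
the official table, and is named accordingly.  The cohort default is a
start age of 62 with 72% males — typical of large ACS trial populations —
since the source reports neither; both are mandatory configuration
fields so reproduction runs can vary them.

## Probabilistic sensitivity analysis

The PSA re-runs the full model per draw (default 10,000 iterations;
2,000 are used in the test suite and the acceptance script to stay well
inside their runtime budgets, with Monte-Carlo error on the CEAC of
about one percentage point).  Sampled are:

* **hazard ratios** — log-normal with the base value as median; the
  default log-sd (`log(1.5)/1.96 ≈ 0.207`) makes the 95% interval span
  `[HR/1.5, 1.5·HR]`;
* **event probabilities** (first-year per arm, and the shared long-term
  annual probabilities) — beta distributions with the base value as mean
  and an effective sample size (default 5,000 per arm), sharing one
  standard-normal quantile per endpoint across arms so that arm-specific
  probabilities move together like estimates sharing a baseline; a
  `covariance_mvn` alternative instead draws Weibull log-parameters from
  the multivariate normal implied by fits to synthetic patient-level
  data;
* **utilities and decrements** — beta distributions matched to mean and
  a standard error of 0.02, decrements capped at the band floor.

Costs and discount rates are treated as known with certainty.  The
source reports no uncertainty magnitudes for any of these inputs, so all
of the above are labelled synthetic defaults and the acceptability-curve
behaviour should be read qualitatively (shape, monotonicity, high
acceptability at conventional thresholds), not as calibrated probability
statements.  Draws are deterministic in `(seed, index)`; a draw that
violates a probability-sum invariant is redrawn up to a documented cap
(100) and failures are counted, not fatal.  Setting `hr_log_sd = 0`,
`utility_se = 0` and `prob_n_effective = Inf` collapses every draw to
the base configuration, which anchors the unbiasedness tests.

## Deterministic scenarios and tornado

`scenario_set("paper_univariate")` bundles the published one-way
analyses: the three clopidogrel price points, the global-model HR set,
0%/3%/5% discounting, indirect costs (EUR 2,744 MI year 1; EUR 4,417 /
4,336 stroke year 1 / later) and an annual cost for the event-free
state.  For the last, the source names no amount; the bundled scenario
uses EUR 974/year — the "following years" outpatient (doctor's visit /
nursing care) figure — as a defensible annual cost of routine secondary
prevention, and the value is an ordinary override.  The tornado orders
parameter groups by ICER range; a dominant scenario is reported as a
flagged bound, not a negative ICER, and is placed at 0 for ordering.

## Numerical choices

* Trace rows are exact distributions (asserted to $10^{-12}$); the
  cohort loop stops at `max_age` (life-table closure guarantees
  extinction) or when living occupancy falls below $10^{-9}$.
* The Weibull likelihood is optimised on log-parameters for
  unconstrained positivity; the observed-information covariance is
  symmetrised; fewer than two events is an error, as is non-convergence
  after the iteration cap (with diagnostics).
* The five-cycle micro-simulation oracle (one million simulated
  patients following the same transition rules) agrees with the cohort
  trace to within $10^{-3}$ per state per cycle — the Monte-Carlo
  resolution of that sample size.
* The full deterministic model runs in well under a second per cohort;
  problem sizes used by the checks (50,000-patient synthetic samples for
  fitting, $10^6$ for the oracle, 2,000 PSA draws) were chosen so the
  whole suite completes in a few minutes.

## Known limitations

* The lifetime extrapolation holds year-2 conditional probabilities
  constant for life and admits no recurrent non-fatal events, therapy
  switching, or variable treatment duration.
* Per-arm lifetime results depend on the start age, sex mix, and life
  table, none of which are reported by the source; the bundled values
  reproduce the published per-arm costs and incremental life-years /
  QALYs closely, but the incremental *cost* — a small difference of
  large numbers — remains some 10–25% above the published figures under
  every convention consistent with the published drug-cost arithmetic,
  and the ICERs inherit that gap.  The acceptance checks encode the
  published values with a ±10% band and report this honestly.
* Costs are 2009 EUR throughout; there is no currency conversion or
  re-inflation, and cost uncertainty is excluded from the PSA by design.
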