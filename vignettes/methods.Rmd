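---
title: "Model and methods: TILs-guided chemotherapy de-escalation CEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: TILs-guided chemotherapy de-escalation CEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Stromal tumor-infiltrating lymphocytes (TILs) are a prognostic biomarker
in early-stage triple-negative breast cancer: patients with TILs at or
above 30 % have excellent survival without adjuvant chemotherapy. The
package compares two strategies for a cohort of 10,000 women aged 50:

* **Strategy 1 (TILs testing).** Every patient is tested (3,000 yuan).
  Those with TILs ≥ 30 % — 3,333 of 10,000, reflecting the roughly
  one-third prevalence reported for this biomarker — are spared
  chemotherapy and enter Markov pathway **M1**; the remaining 6,667
  receive a chemotherapy course and enter **M2**.
* **Strategy 2 (no testing).** All 10,000 receive chemotherapy and enter
  **M3**.

The split is encoded as exact counts (3,333 / 6,667) rather than the
fraction 1/3 because the published decision-tree cost components are
whole-yuan multiples of those counts; the choice is configurable.

## Markov structure

Each pathway is a three-state cohort model — progression-free (PFS),
progressed (PD), dead — run in annual cycles over 27 cycles (age 50 to
77, the average maximum life expectancy assumed). PD cannot return to
PFS; death is absorbing.

The source material specifies a disease-free survival (DFS) curve and an
overall survival (OS) curve per pathway but not how the two map onto a
three-state transition matrix. We use one defensible decomposition,
stated here as a design decision:

* **Out of PFS.** Death takes the background age-specific probability
  `q(age)` from the life table (PFS patients are at or near population
  mortality risk); progression receives the remainder of the DFS exit
  probability, `to_pd = max(0, tp_DFS(t) − q(age))`, where
  `tp_DFS(t) = 1 − S_DFS(t)/S_DFS(t−1)` is the time-dependent cycle
  transition probability.
* **Out of PD.** Death is the conditional one-cycle OS death
  probability floored at background mortality,
  `to_death = max(q(age), 1 − S_OS(t)/S_OS(t−1))`.

Rows are clipped into `[0, 1]` and renormalized by construction; when a
cohort has fully failed (`S(t−1) = 0`) the transition probability is
defined as 1.

Accrual conventions (also configurable): no half-cycle correction;
discounting at `(1 + r)^{-k}` on end-of-cycle occupancy with `r = 0.05`
per annum; cycle-0 upfront costs (chemotherapy course, TILs test)
undiscounted; QALYs accrue as occupancy × utility; PFS follow-up costs
follow the year schedule 1,846 / 2,128 / 1,564 yuan (year 1 / year 2 /
later); the recurrence treatment cost (70,319.9 yuan) is charged once on
entry to PD, because it is described as a treatment cost rather than an
annual state cost — an annual mode is available.

Utilities: 0.8 (PFS), 0.5 (PD) for patients who underwent chemotherapy
(M2, M3); 0.94 (PFS), 0.73 (PD) for patients spared chemotherapy (M1);
death 0.

## Survival families and the (λ, γ) convention

Published parameter tables in this literature give each curve a family
plus scale-role λ and shape-role γ without defining the
parameterization per family. The package fixes one convention
(Weibull `S = exp(−λt^γ)` proportional-hazards form, Gompertz hazard
`λe^{γt}`, log-logistic `S = 1/(1+(t/λ)^γ)`, log-normal `(μ, σ) = (λ,
γ)`, generalized gamma in the stable (μ, σ, Q) form) and documents two
known ambiguities rather than guessing silently:

* The M1 overall-survival log-normal carries γ = −0.120, inadmissible
  as a log-scale standard deviation. `survival_model()` folds it to
  |γ| with a loud warning; per-curve overrides are possible in the
  configuration.
* Whether the published non-Weibull parameters are on the natural or
  log scale, and in which time unit, is not stated (the M2-OS
  log-normal λ = 5.92 implies a median of ~372 years if read as a
  meanlog in years). Because of this, the package does **not** claim to
  reproduce the published Markov-derived pathway totals numerically;
  the full-model claim is restricted to the direction of the result
  (the testing strategy dominates), which is robust to these readings.

Time is in years everywhere, with cycle length `u = 1`.

Maximum-likelihood fitting of right-censored data is delegated to
`flexsurv::flexsurvreg()` (deterministic given the data), with results
mapped back to the (λ, γ) convention; AIC `= 2k − 2ℓ` and BIC
`= k·ln n − 2ℓ` are recomputed and asserted as identities. Model
selection ties (within 1e-9) break by fewer parameters, then by a fixed
family order.

## Pseudo-IPD reconstruction

The reconstruction follows the iterative interval scheme associated
with Guyot: per numbers-at-risk interval, an initial censoring count is
guessed from the survival drop, censor times are spread evenly over the
interval (uniform-censoring assumption), events at each digitized
coordinate follow from the product-limit relation with sequential
rounding, and the censoring count is adjusted until the implied number
at risk at the next boundary matches the published count. Sequential
(click-by-click) rounding is used because the product-limit recursion
requires integer counts at each step; it is deterministic, which keeps
the stage reproducible. In the final interval no censoring is assumed
unless a total event count is supplied, in which case the interval is
rescaled in whichever direction is needed (extra censoring for an
excess; end-of-follow-up survivors converted to events for a
shortfall). Survivors past the last coordinate are censored there.

Digitization granularity matters: event drops between grid points snap
to the next grid time, so boundary clicks can carry events that
occurred just before a risk-table boundary. The implied boundary counts
therefore track the published ones only up to this integer granularity;
internal bookkeeping (start − events − censorings = next start) is
exact. On noise-free fixtures the reconstructed KM curve matches the
input coordinates to well under 0.02 absolute.

## The synthetic-data generator

The generator replaces the published digitized figures and the national
life table; it makes no claim to emulate the source trials beyond their
structure:

* **IPD**: event times from any supported family; censoring composes
  administrative end-of-follow-up at 5 years (the follow-up of the
  underlying adjuvant trials), optionally uniform over the follow-up
  window to mimic rolling entry, and exponential dropout. Defaults: 5-y
  administrative censoring, no dropout.
* **Digitized curves**: the KM step function sampled on a regular grid
  (default 0.25 y), optional Gaussian jitter on the probability scale
  with monotonicity re-imposed by clipping, and an exact risk table at
  1-year intervals (matching the model's annual cycle).
* **Life table**: Gompertz–Makeham,
  `q(age) = 1 − exp(−(a + b·e^{c·age}))` with defaults a = 5e-4,
  b = 3e-5, c = 0.09, giving ~3 per 1,000 annual mortality for women at
  50 rising to ~3 per 100 by the late 70s — plausible mid-life female
  all-cause mortality where the real national table is not available in
  machine-readable form. Real tables load from the same `(age, qx)`
  format.

What passing tests on these fixtures do **not** show: robustness to
digitization error structure of real figures (hand clicks are not
i.i.d. Gaussian on a grid), to non-proportional censoring in the source
trials (unreported), or to miscalibration of the published survival
parameters themselves.

## Sensitivity analysis

One-way analysis reruns the deterministic model at each parameter's low
and high bound (published procurement ranges for drug prices; ±20 %
elsewhere; discount rate 0–10 %), sorting by ICER swing. The PSA draws
all distributed parameters independently each iteration — gamma for
costs, beta for utilities, normal for the recurrence cost — using
method-of-moments matching with mean at the base value and SD
`(high − low)/(2·1.96)`, i.e. reading the published range as a 95 %
interval (no dispersion rule is published). Infeasible beta moments
fall back to a uniform draw over the range, with a warning. Negative
cost draws are rejected and redrawn (max 1,000 attempts). Survival
parameters and the discount rate carry no published distribution and
are excluded from PSA (a config switch can add user-supplied
uncertainty).

## Regimen costing and two documented discrepancies

Costing reproduces the published worked table exactly: BSA 1.5661 m²
for the 158 cm / 59 kg representative patient; ceiling vial rounding
per administration (validated by all published vial counts:
6/5 for TC, 16/7/5 for AC-T); concomitants as fixed per-cycle packs;
adverse-event management, administration and laboratory testing as flat
per-cycle components multiplied by the 4 cycles (the published totals
require this, even though the narrative describes AE costs as
event-driven).

Two internal inconsistencies of the source material are surfaced as
configuration options rather than resolved silently:

* The narrative assigns AC-T to tested-but-treated patients and TC to
  untested patients, while the published base-case cost components
  equal 6,667 × the **TC** course (tested arm) and 10,000 × the
  **AC-T** course (untested arm). Default `regimen_assignment =
  "cost_table"` reproduces the published arithmetic;
  `"guideline_text"` follows the narrative.
* The narrative's TC composition (docetaxel + epirubicin) differs from
  the worked cost table (docetaxel + cyclophosphamide); the cost table
  is used because its arithmetic is self-consistent.

## Numerical choices and problem sizes

* Transition probabilities, occupancies and costs are plain double
  arithmetic; cohort mass conservation holds to 1e-9 relative by
  construction and is asserted.
* Weibull closed-form and generic-ratio transition probabilities agree
  to 1e-12 and both are tested.
* Parameter-recovery checks run each family at n = 2,000 with 20
  replicates through the full simulate → digitize (0.1-y grid) →
  reconstruct → refit pipeline, requiring median relative error below
  10 %; a 0.1-year grid corresponds to reading a published figure at
  good resolution, and is chosen because shape parameters (Weibull λ in
  the PH form, the generalized-gamma Q) are sensitive to early-time
  granularity.
* PSA reproducibility and acceptability are exercised at 500–1,000
  iterations in the test suite; the full analysis uses 10,000.

## Limitations

* The three-state structure omits local recurrence, long-term adverse
  events and tunnel states, and runs at cohort (not individual) level.
* The DFS/OS-to-transition decomposition is one defensible reading of
  an under-specified model; alternatives (e.g. partitioned survival)
  would change pathway totals.
* Utilities derive from non-Chinese literature; parameters are sampled
  independently in PSA (no correlation structure is published).
* The published survival-parameter scales are ambiguous (see above);
  conclusions should rest on the dominance direction and the
  sensitivity analyses, not on absolute QALY totals.
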