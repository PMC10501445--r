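---
title: "Methods: a Markov cohort cost-effectiveness model for first-line immunochemotherapy in ES-SCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model for first-line immunochemotherapy in ES-SCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclccea)
```

This vignette documents the model implemented by `sclccea`, the assumptions
behind each stage, the numerical choices, and what the synthetic-data tests
do and do not establish about real data.

## The decision problem

Two strategies for first-line treatment of extensive-stage small cell lung
cancer are compared from a healthcare-system perspective: four 21-day
induction cycles of serplulimab (4.5 mg/kg) plus etoposide (100 mg/m²,
days 1–3) and carboplatin (AUC 5, day 1), followed by serplulimab
maintenance until progression; versus the same chemotherapy with placebo.
After first progression, patients receive second-line chemotherapy
(irinotecan or etoposide, with carboplatin), a share of them continuing
serplulimab (55.23%) or placebo (50.23%); after second progression, best
supportive care until death. Outcomes are discounted costs (2022 USD),
life-years (LY) and quality-adjusted life-years (QALY) per patient, combined
into the incremental cost-effectiveness ratio (ICER) and judged against a
willingness-to-pay threshold of $37,423/QALY (three times China's 2022
per-capita GDP).

## Cohort model

Four states — progression-free (PFS), first progression (PD1), second and
later progression (PD2+), death — with a 21-day cycle and
`floor(7.44 × 365.25 / 21) = 129` cycles (a lifetime horizon for this
disease: by then the modelled cohort is essentially extinct). The cohort
enters 100% progression-free.

Transitions are derived each cycle from two parametric survival curves,
PFS `P(t)` and OS `O(t)`, evaluated at cycle boundaries:

* PFS → PD1: `[P(t) − P(t+1)] / P(t)`. An empty PFS state progresses nobody.
* PFS → death: the per-cycle equivalent of a background annual mortality
  probability, `1 − (1 − q)^(21/365.25)`.
* PD1, PD2+ → death: `[O(t) − O(t+1)] / [O(t) − P(t)]` — the OS decrement is
  attributed to the progressed occupancy implied by the two curves.

Two guards handle the places where digitized or mismatched curves break the
arithmetic. If `O(t) − P(t)` falls below `1e-12` the death probability is 0
(an empty progressed state cannot supply deaths); the first model cycle is
always in this situation by construction and is handled silently, later
occurrences warn. Raw values outside `[0, 1]` — possible when the fitted PFS
and OS curves nearly touch or cross — are clipped with a warning. If the two
PFS exits sum above 1, background mortality keeps its floor and progression
is renormalized. A consequence of the clipping worth knowing: when the PFS
and OS shapes differ markedly, early-cycle deaths can lag the OS curve by up
to one cycle's decrement; with background mortality off, cohort survival
otherwise tracks the OS curve exactly (this is a tested invariant).

**The PD1/PD2+ split is a modelling decision, not an evidence-based
quantity.** Only two curves are published, but the cost structure
distinguishes second-line treatment from best supportive care. We realize
the split as a tunnel: entrants to progression receive second-line therapy
for `secondline_cycles` cycles (default 4, mirroring induction) and then
move to best supportive care. Death risk is identical in both progressed
states, so the tunnel length shifts costs, not survival. The length and the
second-line chemotherapy mix (default 50% irinotecan-based / 50%
etoposide-based; the source reports no split) are configuration parameters,
and the mix is held fixed in the probabilistic analysis as a structural
share.

## Accruals

Every accrual uses a half-cycle correction (the mean of the
adjacent-boundary occupancies) and is discounted at 5%/year with model time
measured at cycle start. Per cycle: PFS pays the induction combination for
cycles 1–4 and maintenance thereafter, plus routine follow-up; PD1 pays the
second-line mix, the continued-immunotherapy share, and follow-up; PD2+ pays
best supportive care. Follow-up cost is applied to the on-treatment states
(PFS, PD1) — the best-supportive-care cost is taken as the all-in cost of
that state. Utilities weight LYs into QALYs: 0.673 (PFS), 0.473 (both
progressed states), 0 (death).

Grade ≥3 adverse events with incidence ≥5% (anemia, decreased white-blood-
cell/neutrophil/platelet counts) are applied once at model entry — they
cluster in induction — as a lump cost `Σ risk × cost` and a QALY decrement
`Σ risk × disutility` lasting one cycle. Both the timing and the one-cycle
disutility duration are package conventions; the source does not state them.

Per-cycle drug *costs* are model inputs taken as given. `compute_doses()`
exists to audit them against unit prices: serplulimab 4.5 × 65 kg = 293 mg,
etoposide 100 × 1.72 m² = 172 mg/day, carboplatin by the Calvert formula
with Cockcroft–Gault creatinine clearance (male form, mg/dL), giving
5 × (71.2 + 25) ≈ 481 mg. Milligram rounding is half-up; the "nearest
milligram" rule stated in the source has no tie policy.

Background mortality is a scalar configuration input, default 0.00718/year —
a placeholder of the right magnitude for all-cause mortality around age 61
in China; the source cites a national 2021 rate without printing it. It
matters little: progression dominates exits from PFS.

## Curve reconstruction

`reconstruct_ipd()` rebuilds pseudo individual patient data from digitized
Kaplan–Meier coordinates anchored to a numbers-at-risk table. Within each
at-risk interval `(T_i, T_{i+1}]` the number leaving is fixed by the table;
the event/censoring split is solved so the product-limit estimate over the
reconstructed records matches the digitized survival ratio across the
interval, with censoring spread uniformly over the interval. Fractional
event counts are resolved by largest-remainder apportionment with ties to
the earlier drop — deterministic by design. Patients at risk past the last
table entry have events placed at remaining digitized drops and are censored
at the last digitized time. The contract is the round-trip invariant — the
product-limit estimate of the reconstruction agrees with the input curve at
every risk-table boundary within `1/(2n)` for noise-free fixtures — not
bit-compatibility with any published implementation of curve
reconstruction. Infeasible tables (counts that increase) are rejected with
the offending interval named.

## Parametric fitting and selection

Five families are fitted to the right-censored records by maximum
likelihood through `survival::survreg`: exponential, Weibull, logistic,
log-logistic, log-normal. The Weibull is carried in the rate form
`S(t) = exp(−λt^γ)` used by the transition formulas (`λ = exp(−μ/σ)`,
`γ = 1/σ` from the location–scale estimates; conversions to the conventional
scale parameterization are provided and round-trip tested). The *logistic*
family is the plain location–scale logistic on time, which places some mass
on negative times; survival evaluations are clamped to `[0, 1]`, so `S(0)`
can sit marginally below 1 for that family only. It is included because it
is part of the candidate set the analysis specifies, not because it is a
good survival model.

`select_model()` takes the minimum-AIC fit (`AIC = 2k − 2ℓ`,
`BIC = k ln n − 2ℓ`, with `k = 1` for the exponential and 2 otherwise), ties
broken by BIC and then by the candidate order above; the tie policy is a
package convention. Median survival uses the Weibull/exponential closed
forms, with numeric bisection for the other families (and as a cross-check,
agreeing to `1e-8`).

## Sensitivity analyses

*One-way (tornado):* every cost, utility, disutility and probability
parameter at ±20% of base; the discount rate over 0–8%; the horizon over
2.00–7.44 years. Bars are ranked by the absolute ICER spread, reported in
$/QALY.

*Probabilistic:* 1000 draws; costs ~ Gamma, utilities/disutilities/
probabilities ~ Beta, each moment-matched to mean = base and SD = 20% of the
mean. The source gives ±20% ranges but no standard errors; SD = 20% of the
mean is the common convention in this literature and is configurable
(`sd_frac`). Parameters degenerate at 0 or 1 stay fixed; infeasible Beta
dispersion is shrunk to the feasibility boundary with a warning. Discount
rate, horizon and the survival-curve parameters are fixed; adverse-event
risks, the continued-immunotherapy shares and background mortality are
sampled as probability variables. Every draw is reproducible from
`(seed, index)`, and a whole run is bit-reproducible from its seed.

The acceptability curve is the fraction of draws with positive incremental
net monetary benefit per WTP value (default grid 0–200,000 by 2,000).

*Price scenarios:* total cost is affine in the serplulimab unit price with
slope equal to the discounted serplulimab-attributable spend, which the
accrual tracks explicitly; `scale_serp_price()` therefore rescales results
exactly without re-running the model, `price_scenario()` evaluates discount
fractions, and `threshold_price()` solves for the discount at which the ICER
meets the WTP threshold by bisection (relative ICER tolerance `1e-6`;
interval convergence to `1e-12` so that it agrees with the affine closed
form to `1e-8`).

## Synthetic data: what it emulates, and what it does not

The generator produces trial-like data under the published design: 585
patients randomized 2:1 (390:195), Weibull event times calibrated so the
medians land exactly on the published values (PFS 5.7 vs 4.3 months, OS 15.4
vs 10.9 months), administrative censoring at 30 months (a trial-like
follow-up; the source does not state one). The published analysis fitted
Weibull curves to digitized trial data but does not report the fitted
parameters, so the shapes here are declared placeholders: γ = 1.2 for PFS
(event-time hazards typically rise before the median) and γ = 1.0 for OS.
Digitized-curve fixtures evaluate the true survival at a reading grid, with
an optional additive uniform ±0.005 reading error re-monotonized by a
running minimum (off by default).

Consequences to keep in mind:

* Base-case totals are *approximations*, not reproductions. Under this
  calibration the deterministic ICER is ≈ $129,000/QALY versus the published
  $179,161/QALY; the qualitative conclusions (never cost-effective at the
  threshold; price-discount arithmetic) are reproduced, and the printed
  incremental identities are checked directly from the published totals.
* With the larger modelled survival gain, the time-horizon bar tops the
  tornado here, whereas the published ranking puts the serplulimab cost
  first; serplulimab cost is the top-ranked ±20% parameter in both.
* Arm-level curves are generated independently per endpoint; there is no
  subject-level PFS/OS coupling (a cohort model needs none) and no
  individual-level microsimulation.
* Passing tests show the pipeline is internally correct under these
  conditions — they cannot validate the digitization of the real trial
  figures, which is out of scope (inputs arrive as CSV coordinates).

## Problem sizes and determinism

The test suite runs the full 129-cycle model, the 1000-draw probabilistic
analysis, trial-sized (n = 585) generation/refitting checks, and
parameter-recovery checks at n = 10⁴; pipeline mechanics are exercised on a
scaled-down trial (n = 120, 25 draws). All randomness flows through explicit
seeds; fixed seeds give bit-identical IPD, PSA samples and pipeline output
files.

## Known limitations

* The PD1→PD2+ transition is a structural stand-in (fixed-length tunnel);
  nothing in the published curves identifies it.
* Only continued serplulimab/placebo are modelled after progression — no
  other subsequent immunotherapies or targeted agents.
* Utilities come from non-small-cell lung cancer literature (as in the
  source); SCLC-specific utilities may be lower, which would raise the ICER.
* The logistic family's support leakage at `t = 0` is tolerated by design
  (clamping), so its fitted "survival" is not a proper survival function at
  the origin.
* Costs are taken as final 2022 USD; no inflation or currency machinery is
  included.
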