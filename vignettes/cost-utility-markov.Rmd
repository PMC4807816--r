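---
title: "Cost-utility modelling with Weibull-derived Markov cohort traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-utility modelling with Weibull-derived Markov cohort traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcua)
```

## The model

`markovcua` implements a trial-based cost-utility analysis as a
three-state Markov cohort model. The health states are
progression-free survival (PFS), disease progression (DP) and death;
transitions are one-way (PFS → DP → death, PFS → death) and death is
absorbing. The cohort starts fully progression-free and advances in
fixed cycles (21 days by default, matching the oral-drug packaging and
the 3-week salvage chemotherapy schedule of the bundled analysis) over
a 5-year horizon, `ceiling(5 * 365.25 / 21) = 87` cycles.

Survival enters the model through the two-parameter Weibull law

$$S(t) = \exp(-\lambda t^{\gamma}),$$

with shape $\gamma$ (hazard rising for $\gamma > 1$, falling for
$\gamma < 1$) and scale $\lambda$ on the day metric. Two curves are
used per arm: progression-free survival and overall survival (OS).
Given a curve, the conditional probability of leaving the state during
cycle $t$ is

$$P(t) = 1 - \exp\{\lambda_c (t-1)^{\gamma} - \lambda_c t^{\gamma}\},
\qquad \lambda_c = \lambda \cdot c^{\gamma},$$

where $c$ is the cycle length in days. This is algebraically identical
to the conditional failure probability
$[S((t-1)c) - S(tc)]/S((t-1)c)$, and the test suite asserts that
identity to $10^{-12}$.

### Fitting Weibull curves to Kaplan–Meier points

`fit_weibull_km()` uses the linearised least-squares route: for
Weibull survival, $\ln(-\ln S(t)) = \gamma \ln t + \ln \lambda$, so an
ordinary regression of the double-log-transformed survival on $\ln t$
returns the shape as its slope and the log-scale as its intercept,
together with an adjusted $R^2$ and correlation coefficient on the
transformed scale. Points with $S \in \{0, 1\}$ (or $t = 0$), where
the transform is undefined, are dropped with a message; fewer than
three usable points is an error. On exact curve points the fit returns
the generating parameters to numerical precision (a property tested
over $\gamma \in [0.5, 3]$, $\ln\lambda \in [-9, -2]$). Maximum-
likelihood fitting on individual-patient data is deliberately out of
scope: the intended input is a set of points read off a published
curve, for which the regression route is the natural estimator and
matches the presence of fit statistics in the reference parameter
table.

### From two curves to three states

A published analysis of this design reports only a PFS and an OS curve
per arm; it does not say how PFS departures split between progression
and death. The package adopts the standard reconstruction for
PFS+OS-based three-state models: the per-cycle death probability comes
from the OS curve and applies equally to both alive states, and the
PFS → DP probability is the PFS exit probability minus the death
probability, floored at zero. A useful consequence (and a regression
test): the trace's PFS occupancy telescopes back exactly to the PFS
survival curve at cycle boundaries, and the alive fraction to the OS
curve, so the model's median PFS and OS equal the medians of the
fitted curves up to grid interpolation.

State membership is end-of-cycle occupancy and rewards attach to the
end-of-cycle state. No half-cycle correction is applied by default
(the bundled analysis gives no indication one was used); it is
available as `half_cycle_correction` in the configuration.

## Economics

Costs are 2014 US dollars throughout; no currency conversion layer is
provided. Per cycle:

* **PFS**: the drug acquisition cost, charged only while the
  manufacturer assistance programme has not yet taken over. The
  bundled base case charges icotinib ($3 \times \$449.80 = \$1349.40$
  per cycle) for the first 9 cycles (≈ 6 months) and gefitinib
  ($2.1 \times \$865.94 = \$1818.48$) for the first 7 cycles
  (≈ 5 months).
* **DP**: routine follow-up (\$57.96) every cycle, plus docetaxel for
  the first 6 cycles after progression. Docetaxel dosing is
  75 mg/m²; with no body-surface area given in the source material
  the package assumes 1.6 m² (a representative adult value), i.e.
  120 mg ≈ 6 × 20 mg ampules at \$108.72, configurable via
  `docetaxel_ampules_per_cycle`. Docetaxel exposure is tracked by
  expected progression influx: the sub-cohort entering DP at cycle $s$
  receives docetaxel at cycles $s, \dots, s+5$ while it survives —
  expected-value accounting over the cohort, not per-individual
  simulation.
* **Death**: no cost, no utility.

Utilities are 0.673 (PFS on oral targeted therapy) and 0.473 (DP).
Serious adverse drug reactions (diarrhoea, nausea, rash, raised
aminotransferase) are rare one-off events; their expected treatment
cost $\sum_i p_i c_i$ and expected utility decrement
$\sum_i p_i (u_{PFS} - u_i)$ are applied once at cycle 1. The
six reaction-probability rows of the source table carry no arm labels;
the bundled mapping (icotinib: diarrhoea 2%, rash 0.5%, raised
aminotransferase 0.5%, nausea 0.5%; gefitinib: rash 1%, raised
aminotransferase 1%) is anchored on the tornado label that places the
2% diarrhoea risk in the icotinib arm, and is fully editable in the
configuration. The financial effect of any plausible re-mapping is
below \$3 per strategy.

Both costs and QALYs are discounted at the same annual rate (3%
default, 0–8% admissible) with per-cycle factors
$(1+r)^{-t \cdot c/365.25}$.

The incremental cost-utility ratio is
$\mathrm{ICUR} = \Delta\mathrm{cost}/\Delta\mathrm{QALY}$; a strategy
that is cheaper and more effective is *dominant*, dearer and less
effective *dominated*, anything else a *tradeoff*. A zero QALY
difference leaves the ratio undefined (reported `NA`, never a
division).

## Sensitivity analysis

**One-way (tornado).** Each parameter is set to the bounds of its
range with everything else at base; each bound is one full two-arm
model run. Bars are ranked by the absolute ICUR span. Ranges follow
the source table, with one convention decided here: where that table
prints a single range value, it is read as the low bound with the base
case as the high bound. This makes the icotinib drug-cost range
degenerate (width 0), so that parameter cannot rank in the tornado —
a documented limitation of the printed ranges, not of the method.
When a bound flips the sign of $\Delta$QALY the ratio is
discontinuous across the range; such rows are flagged `unstable`
rather than plotted as a ratio span.

**Probabilistic (PSA).** All uncertain parameters are redrawn jointly
per iteration (1000 by default, seed mandatory in the configuration):
costs from lognormal distributions, utilities and event probabilities
from beta distributions — the conventional choices for positive and
bounded quantities — each moment-matched so the base case is the mean
and the one-way range spans ≈ 95% of the mass. The discount rate is
held fixed. Degenerate ranges stay at base. The acceptability curve
reports, for each willingness-to-pay value $w$ on a grid from 0 to 3×
per-capita GDP (GDP is a configuration input), the fraction of draws
with strictly positive incremental net monetary benefit
$w\,\Delta\mathrm{QALY} - \Delta\mathrm{cost}$; ties count as not
preferred.

One numerical interaction deserves note: the strict validation rule
that an adverse-reaction utility may not exceed $u_{PFS}$ (the
decrement would be negative) cannot hold across the whole sampled or
one-way range of $u_{PFS}$, whose lower bound (0.27) lies below every
reaction utility. Sensitivity analyses therefore evaluate with the
per-event decrement floored at zero; direct calls to
`expected_adr_adjustment()` keep the strict error by default.

## Synthetic data

`simulate_ipd()` draws individual event times by inverse transform
from the Weibull law and censors administratively at the 5-year
horizon, standing in for the original trial arms (≈ 199 and 196
patients). `km_estimate()` is the product-limit estimator.
`recovery_harness()` closes the loop: simulate → KM → sample the step
function at 21-day cycle boundaries (mimicking how a published curve
is read off) → refit → compare. At $n = 2000$ the shape is recovered
within ±0.1 and the log-scale within ±0.5; recovery bias shrinks as
$n$ grows (checked at $n = 200/2000/20000$).

What the generator does *not* emulate: correlated PFS/OS times within
a patient (the cohort model never consumes joint individual-level
data), non-administrative dropout, and digitisation error in reading
published curves. Passing recovery tests therefore demonstrate the
estimator chain, not robustness to messy real-world extraction.

## Reference parameter set and its internal inconsistencies

The bundled configuration (`default_config()`, also shipped as
`inst/extdata/default_config.yaml`) encodes a published-style
comparison of icotinib vs gefitinib as second-line therapy for
advanced NSCLC in China. Its survival parameter table had to be
interpreted: the printed "scale" column holds values 0.93–1.19 and the
printed "shape" column negative values around −5 to −7.5, which no
Weibull admits; the only valid reading — adopted here — is that the
columns are swapped, the 0.93–1.19 values being the shape $\gamma$ and
the negative values $\ln\lambda$, exactly what a linearised regression
intercept would produce. The time unit of $\lambda$ is likewise
unstated; days is the only common unit that puts all four medians on a
plausible clinical scale, and a `time_unit: months` switch is provided
for month-scale inputs.

Taken at face value, this parameter set is internally inconsistent
with the headline results it accompanied, and the package reproduces
it faithfully rather than adjusting anything:

* The OS curves imply model medians of **12.6** and **13.3** months
  (icotinib / gefitinib) — within about one month of the accompanying
  validation table (13.6 / 14.0).
* The icotinib PFS curve implies a median of **5.0** months against a
  reported 4.2; the gefitinib PFS parameters imply **6.0** months
  against a reported 3.5, irreconcilable under any single time unit
  (both arms share whatever unit the fit used), and they make the
  gefitinib curves *better* than icotinib's.
* Consequently the model yields ≈ 0.72 vs 0.77 discounted QALYs and
  $\Delta\mathrm{QALY} < 0$: icotinib is cheaper but not dominant
  under these inputs, whereas the accompanying headline (0.279 vs
  0.269 QALYs) reports dominance. The headline QALYs are themselves
  irreconcilable with the reported medians: any three-state trace with
  a ~13.6-month OS median accrues roughly 0.7–0.8 discounted QALYs at
  these utilities, under every discounting reading we examined.
* Costs, which are driven by the capped drug-charging window rather
  than by the far tail of survival, land close to the reported totals:
  ≈ \$10,310 vs \$10,662.82 (icotinib, −3%) and ≈ \$11,587 vs
  \$13,127.57 (gefitinib, −12%).

The acceptance suite states the reported headline values at face
value, so the QALY and dominance checks fail against this parameter
set — deliberately: they document the inconsistency instead of
papering over it with recalibrated inputs.

## Worked example

```{r example}
cfg <- default_config()
res <- compare_strategies(cfg, new = "icotinib", comparator = "gefitinib")
res$new
res$comparator
res$icur
```

```{r owsa}
ow <- one_way_sa(cfg)
head(as.data.frame(ow)[, c("parameter", "icur_low", "icur_high", "width")])
```

```{r psa, eval = FALSE}
psa <- run_psa(cfg)            # 1000 draws, seeded from the config
cc <- ceac(psa, wtp_grid(cfg))
plot_ceac(cc)
```

## Numerical choices and limitations

* Medians are linearly interpolated between the bracketing 21-day
  cycle boundaries and converted at 30.44 days/month; an exact 0.5 at
  a boundary is taken as-is, and a series that never reaches 0.5
  raises an explicit "median not reached" condition.
* The trace recursion enforces conservation (rows sum to 1 within
  $10^{-9}$) and monotonicity; a schedule whose probabilities sum
  beyond 1 in a cycle is rejected.
* Problem sizes: the default analysis is 87 cycles and runs in
  milliseconds; the full PSA (1000 × two-arm evaluations) takes a few
  seconds; recovery checks use cohorts of 200–20,000 patients.
* The model is a cohort expectation — no microsimulation, tunnel
  states, background mortality split, or EVPI. Indirect costs and
  items identical between arms (physician visits, CT) are excluded by
  design.
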