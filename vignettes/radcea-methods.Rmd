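---
title: "Model and methods: cost-effectiveness of prostate radiotherapy fractionation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: cost-effectiveness of prostate radiotherapy fractionation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcea)
```

## The decision problem

Ultra-hypofractionated radiotherapy (UHRT; 42.7 Gy in 7 fractions of
6.1 Gy) and conventionally fractionated radiotherapy (CRT; 78 Gy in 39
fractions of 2 Gy) are near-isoeffective treatments for intermediate-
to high-risk localized prostate cancer: with a tumour
$\alpha/\beta = 3$ Gy their biologically effective doses,
$\mathrm{BED} = D\,[1 + d/(\alpha/\beta)]$, are 130 Gy and 129.52 Gy.
The HYPO-RT-PC randomized trial reported identical 5-year failure-free
survival (84% in both arms), similar 5-year overall survival (96% vs
94%), but more grade $\geq 2$ urinary toxicity with the
ultra-hypofractionated schedule (6% vs 2%). The economic question is
whether the shorter, cheaper course justifies its extra toxicity burden
from a payer's perspective. `radcea` implements the standard
health-economic machinery for that question: a Markov cohort model,
discounted cost and QALY accumulation, incremental cost-effectiveness
ratios (ICERs), and deterministic and probabilistic sensitivity
analysis.

## Model structure

Three mutually exclusive health states: failure-free survival (FFS),
progressive survival (PS, pooling biochemical recurrence and clinical
metastasis), and death. The whole cohort starts in FFS. Each cycle a
patient in FFS may progress to PS or die of other causes; a patient in
PS may die; PS cannot return to FFS and death is absorbing.

Disease transitions are driven by Weibull survival functions
$S(t) = \exp(-\lambda t^{\gamma})$ in the rate parameterization. The
probability of the transition during the cycle starting at time $t$,
conditional on not yet having made it, is

$$P(t \to t+1) = 1 - \exp\!\left[\lambda t^{\gamma} - \lambda (t+1)^{\gamma}\right]
              = 1 - \frac{S(t+1)}{S(t)},$$

so the per-cycle probabilities telescope back into the survival
function: $\prod_{k=0}^{T-1}(1 - P(k \to k+1)) = S(T)$. The test suite
asserts this identity to $10^{-12}$ over randomized models. Internally
the conditional probability is evaluated in exponent form,
$1 - \exp[\lambda(t_0^\gamma - t_1^\gamma)]$, which stays finite where
$S(t_0)$ itself underflows to zero.

Other-cause mortality is a constant per-cycle probability of 0.0003
applied to the FFS state (derived from Swedish all-cause mortality in
the source estimates). Whether such a figure is per cycle or per annum
is ambiguous when cycles are not annual, so the
`background_mortality_timescale` setting makes the interpretation
explicit; with the default annual cycles the two readings coincide.
Within a cycle the competing FFS exits (progression, background death)
are treated as additive probabilities, clipped proportionally with a
warning in the extreme case where their sum would exceed one. This
matches the simple decision-tree structure of the model; a
cause-specific hazard conversion would change occupancies only at the
third decimal place for the probabilities involved here.

### Cycle length and horizon

The horizon is 15 years, by which point nearly all of an elderly
cohort is assumed to have died or progressed. The default cycle length
is 1 year (15 cycles): the transition formula indexes integer cycles
and every published survival anchor is annual, so this is the smallest
structural assumption consistent with the inputs; the engine accepts
any cycle length that divides the horizon (e.g. monthly), with
discounting always computed on elapsed years.

### Where the transition models come from

Published survival for this comparison exists as curves and milestone
probabilities, not as patient-level data, so the package supports two
routes to a Weibull model:

* **Calibration** (`calibrate_weibull`): exact two-point solution
  through milestone survivals,
  $\gamma = \ln(\ln S_1/\ln S_2)/\ln(t_1/t_2)$,
  $\lambda = -\ln S_1 / t_1^{\gamma}$.
* **Fitting** (`fit_weibull`): least squares on the complementary
  log-log linearization $\ln(-\ln S) = \ln\lambda + \gamma \ln t$ of
  digitized Kaplan-Meier points. Digitized curves carry no event
  counts, which rules out maximum likelihood; the linearization is
  deterministic and auditable. When numbers at risk are available the
  points are weighted by the inverse Greenwood variance of
  $\ln(-\ln S)$ — without this, late curve segments estimated from a
  handful of subjects dominate the fit and bias $\lambda$ upward by
  several Monte Carlo standard errors at realistic sample sizes.

The default configuration (`paper_fixture()`) calibrates the FFS
$\to$ PS pathway through the trial's 5-year FFS of 0.84 (both arms) and
a second, long-term milestone that the trial does not provide. That
second anchor defaults to $S(15) = 0.60$ — an illustrative value chosen
to give a plausibly convex failure curve, exposed as an explicit
argument precisely because it is *not* an observed quantity. The PS
$\to$ death pathway has no published anchors at all beyond overall
survival, so it is reduced to one scalar degree of freedom: an
exponential (shape 1) whose rate is solved numerically per arm so the
modelled 5-year overall survival equals the trial's 96% (CRT) and 94%
(UHRT).

## Economics

QALYs accumulate as
$\sum_k (1+r)^{-k \cdot c}\, c\, (\text{FFS}_k u_\text{FFS} + \text{PS}_k u_\text{PS})$
with cycle length $c$ in years and annual discount rate $r$ (3% base
case, varied 0–8%). Costs accumulate analogously from per-cycle
follow-up and progression costs, monthly androgen deprivation therapy
(ADT) charged against FFS occupancy for the first 24 months, and two
one-time charges at entry: the radiotherapy course and the expected
urinary-toxicity cost (unit cost $\times$ arm-specific incidence,
2%/6%). Occupancy for cycle $k$ is taken at the cycle start; a
half-cycle correction (averaging adjacent boundaries) is provided but
**off by default**, matching the usual behaviour of decision-tree
software for this model class, and because the worked incremental
arithmetic the package validates against was produced without it.

Utilities: FFS utility is arm-specific (0.91 CRT / 0.85 UHRT) and
already incorporates the arm's urinary-toxicity burden — the published
estimates only exist in that toxicity-inclusive form, and the
sensitivity analyses vary them directly. The PS utility 0.61 is a
mixture of biochemical-recurrence (0.74) and clinical-metastasis
(0.25) utilities; the mixture weight 0.7347 is back-solved from the
published composite ($0.36/0.49$) and carried as an explicit parameter.

Cost composition is the least determined part of any such model: unit
costs are published (`unit_costs_2020usd()`, 2020 USD) but the
schedule that turns them into per-arm totals is not. The defaults, all
overridable through `paper_fixture()` arguments or the JSON config:

* **Radiotherapy course.** Both arms share the planning/setup items
  (physician, CT, immobilization, positioning, treatment planning
  system). CRT adds IMRT delivery $\times$ 39 fractions; UHRT adds
  X-knife delivery and image guidance, each billed once at the
  first-session rate plus 6 subsequent sessions — following the
  column structure of the published cost table literally. Transportation
  is charged per fraction (39 vs 7 trips).
* **Follow-up while failure-free.** PSA test, digital rectal exam,
  routine and biochemistry bloods, every 6 months.
* **ADT.** Goserelin + bicalutamide monthly for 24 months, per
  guideline-based adjuvant practice.
* **Progression.** Monthly supportive treatment plus a systemic-therapy
  mix (default proportions 0.25 docetaxel, 0.25 abiraterone, 0.05
  cabazitaxel). The trial applied no second/third-line treatment
  pattern, so any composition here is a modelling choice; the
  proportions are deliberately modest and fully configurable.

The ICER is $\Delta C / \Delta E$ for CRT versus UHRT, with dominance
flagged instead of reported as a ratio when one arm is both cheaper
and more effective. Average cost-effectiveness is computed on
unrounded internal values. Decisions at a willingness-to-pay (WTP)
threshold — $31,510/QALY, three times China's 2020 per-capita GDP — use
net monetary benefit, $\mathrm{NMB} = \mathrm{WTP}\cdot E - C$.

## Sensitivity analysis

**One-way (tornado).** Each registered parameter is set to its low and
high value with the rest at base, and the full model re-run. Utilities
use their published ranges; costs use $\pm 20\%$ of base; the discount
rate spans 0–8%. Entries are sorted by ICER spread. Parameters the
engine does not read (the `u_ps` composition components) correctly
show zero spread.

**Probabilistic (PSA).** 1,000 Monte Carlo draws in the base analysis.
Utilities are drawn from beta distributions and costs from gamma
distributions constructed by method of moments from the published mean
and range, reading the range as a 95% interval:
$\mathrm{SE} = (\text{high} - \text{low})/3.92$. That divisor is the
dominant convention in cost-effectiveness practice but is configurable
(`range_divisor`; alternatives 4 and $2\sqrt{3}$). Beta draws are
bounded by $[0,1]$ by construction and are not additionally truncated
at the printed ranges. Each draw samples every parameter once and
applies it to both arms, so shared quantities (unit costs, `u_ps`, the
discount rate) are perfectly correlated across arms while the
arm-specific FFS utilities vary independently — the standard
correlation structure when nothing more specific is published. The
full Markov engine runs per draw; no emulator is used.

**CEAC.** At each WTP the acceptability probability is the fraction of
draws in which the reference arm has the higher NMB, with exact ties
counted as 0.5 — an unbiased convention under exchangeability, stated
explicitly because tie handling is rarely documented. The two arms'
curves sum to one at every threshold by construction.

**Threshold search.** Bisection on the sign of incremental NMB over
any scalar knob (WTP, discount rate, any parameter) to a $10^{-6}$
interval. Because NMB is linear in WTP at fixed increments, the WTP
crossover always equals the deterministic ICER — used as an internal
consistency check.

## Synthetic data

`synthetic_cohort_spec()` / `simulate_event_times()` generate
patient-level Weibull event times by inverse transform
($T = (-\ln U/\lambda)^{1/\gamma}$) with independent exponential
censoring and administrative censoring at end of follow-up;
`km_from_times()` reduces them to a product-limit step curve with
numbers at risk. This emulates the statistical structure of what curve
digitization recovers — a noisy KM estimate of a Weibull survival
function — and makes the whole calibrate/fit pipeline testable without
external data. It does **not** emulate digitization error itself
(pixel quantization, curve-tracing bias), patient covariates, or
informative censoring; passing recovery tests therefore demonstrate
statistical correctness of the estimator, not robustness to
digitization artefacts.

## Validation strategy and problem sizes

The headline outputs of the published analysis this model parallels
(per-arm QALYs near 2.3/2.1, PSA acceptability 57.7%) depend on fitted
survival parameters, cycle structure, and cost schedules that were
never printed, so exact reproduction is not a meaningful target. The
package instead validates:

* exact worked arithmetic — the incremental table ($\Delta C$ 4,251.04,
  $\Delta E$ 0.18, ICER 23,616.89 $/QALY) and both BED values;
* oracle equivalence — the cohort trace against a 50,000-patient
  seeded microsimulation, within 3 binomial standard errors at every
  cycle;
* parameter recovery — the simulate $\to$ KM $\to$ fit pipeline
  recovers $(\lambda, \gamma)$ within 3 Monte Carlo standard errors
  over 200 replicates of $n = 500$;
* structural identities — telescoping, mass conservation to
  $10^{-12}$, monotone death occupancy, ICER/threshold consistency,
  degenerate-PSA exactness, and PSA sample means within
  $3\,\mathrm{SD}/\sqrt{n}$ at $n = 5{,}000$ draws;
* qualitative agreement with the published direction — UHRT cheaper,
  CRT more effective, CRT cost-effective at the Chinese WTP threshold.

These sizes (50,000 microsimulated patients, 200 fitting replicates,
5,000 PSA draws) were chosen to make 3-standard-error bands tight
enough to detect implementation errors of practical magnitude while
keeping the whole suite under a minute of compute.

## Known limitations

* Three memoryless-by-state compartments cannot track time since
  progression, so the PS $\to$ death clock runs on model time, not
  time of PS entry (no tunnel states). With the exponential default
  this distinction is moot; it matters if a user supplies
  $\gamma \neq 1$ for that pathway.
* The long-term FFS anchor and the PS cost mix are modelling choices,
  not data; absolute cost and QALY levels inherit that uncertainty,
  which is why the acceptance checks emphasize structure and direction
  over levels.
* Late bowel/erectile toxicity differences, indirect labour costs
  (retired population), currency inflation beyond a scalar, and
  multi-arm frontiers are out of scope.

```{r example}
cfg <- paper_fixture()
res <- evaluate_config(cfg)
res$result
```
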