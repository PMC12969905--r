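---
title: "Methods: a partitioned survival cost-effectiveness model for second-line advanced endometrial carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned survival cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

Women with advanced or recurrent endometrial carcinoma who progress after
platinum-based chemotherapy face a second-line choice between lenvatinib
plus pembrolizumab (LP) — more effective, far more expensive, not
currently reimbursed in Taiwan for this indication — and doxorubicin-based
chemotherapy. `psmcea` implements the health-economic model behind that
decision from the payer perspective of Taiwan's National Health Insurance:
a three-state partitioned survival model (PSM) producing discounted costs,
life-years (LYs) and quality-adjusted life-years (QALYs) per strategy, and
the incremental statistics a reimbursement committee reads (ICER, net
monetary benefit, acceptability curves, value of information).

## The model

A PSM derives state occupancy directly from the two survival curves
instead of from transition probabilities, which is the standard choice
when only published Kaplan-Meier (KM) curves — not patient-level data —
are available:

* progression-free: $\mathrm{PF}(t) = \min\{\mathrm{PFS}(t), \mathrm{OS}(t)\}$
* progressed disease: $\mathrm{PD}(t) = \mathrm{OS}(t) - \mathrm{PF}(t)$
* dead: $1 - \mathrm{OS}(t)$

The `min` clamps the rare crossing of independently modelled curves so
that PD occupancy cannot go negative; `state_membership()` counts how
often clamping fired. The cohort is evaluated on 21-day cycles over a
20-year horizon, i.e. $K = \lfloor 20 \times 365.25 / 21\rfloor = 347$
cycles; the residual 0.86 cycle is dropped, which at 3% discounting and
sub-1% terminal survival is numerically irrelevant. Occupancy is
evaluated at end-of-cycle by default. PSM software differs on
half-cycle conventions and the choice is not identifiable from published
totals, so a `half_cycle` flag exists but is off in the base case.

Per cycle, each state contributes occupancy × cycle length (in years) ×
discount factor to LYs, additionally weighted by the state utility
(PF 0.817, PD 0.779) for QALYs. Costs accrue as: medication components ×
PF occupancy — pembrolizumab capped at 35 cycles ("up to 35 doses"),
lenvatinib and doxorubicin uncapped because the model description states
no cap (the six-cycle and cumulative-dose figures in the source material
describe claims-data definitions and trial protocol, not model
structure; `max_cycles` makes either reading available) — plus
non-medication PF cost (NT$22,149/cycle) × PF, and supportive care
(NT$49,742/cycle) × PD. Discounting is annual-compound at the cycle's
time in years, $(1+r)^{-t/365.25\,\text{days}}$, with $r = 3\%$ for both
costs and effects.

Grade ≥ 3 adverse events enter as one-off expected values in cycle 1 of
the PF state: expected cost $\sum_e \text{risk}_e \cdot \text{cost}_e$
and expected QALY loss $\sum_e \text{risk}_e \cdot \text{disutility}_e$
for exactly one cycle's duration. Treating the decrement as lasting one
cycle (rather than a lump-sum QALY subtraction) follows the stated
"first cycle" timing; the alternative is indistinguishable at the
reported precision because the whole AE term is worth under 0.003 QALYs.
Fatigue and proteinuria carry no management cost, and weight loss and
proteinuria no published disutility; both are encoded as zeros rather
than imputed.

## Survival curves

Six parametric families are supported (exponential, Weibull, Gompertz,
log-logistic, log-normal, generalized gamma), in the parameterizations
standard in survival extrapolation: the conventions were chosen so that
the published parameters reproduce the trial's month-scale medians
(log-normal LP OS median $e^{2.911} \approx 18.4$ months; log-logistic
chemotherapy OS median = scale = 11.905 months), which pins down both
the parameterization and the month time unit (1 month = 30.4375 days).
The generalized gamma uses the $(\mu, \sigma, Q)$ convention; the source
material does not state which convention it fitted, so results for that
family alone may not transfer.

The base case evaluates the fitted parametric models over the whole
horizon. A hybrid extrapolation — KM within the trial window, a
conditionally rescaled parametric tail beyond,
$S(t) = \mathrm{KM}(c)\,S_\theta(t)/S_\theta(c)$ for $t > c$ — is
available through `hybrid_survival()`. Rescaling the tail (rather than
splicing raw parametric values) guarantees continuity at the join when
the fitted curve misses $\mathrm{KM}(c)$. The default cut point is the
last risk-table time with ≥ 10% of the initial cohort at risk, but the
original analysis's cut point and rescaling convention are unpublished,
as are its digitized KM coordinates — which is why the shipped base case
uses the pure parametric curves (`cut_time = 0`) and why full-model
quantities are compared to the published ones at ~10% rather than
exactly.

`fit_mle()` fits by maximum likelihood
($\sum_{\text{events}} \ln f(t_i) + \sum_{\text{censored}} \ln S(t_i)$):
the exponential family by its closed form (rate = events / total
follow-up), the rest via `flexsurv`, with jittered restarts on
non-convergence. Standard errors come from the inverse observed
information. `rank_models()` orders families by AIC with BIC
tie-breaks. Non-positive times in reconstructed data are shifted to
half the smallest positive time — a digitization artifact guard, logged
as a warning.

## KM reconstruction

`reconstruct_ipd()` rebuilds pseudo individual patient data from
digitized curve coordinates plus a number-at-risk table: within each
risk interval it allocates event and censoring counts so the
re-estimated KM matches the digitized ordinates, iteratively adjusting
the interval's censoring count until the end-of-interval at-risk count
matches the published table, with censoring spread uniformly within the
interval (the standard assumption); a known total event count calibrates
the final interval. The returned report carries the rmse and maximum
absolute deviation between the input ordinates and the re-estimated
curve — with exact inputs and a dense risk table the round trip is exact
(rmse 0), and on a 2,000-subject arm digitized monthly with quarterly
risk tables the rmse stays below 0.02.

## Uncertainty analysis

All 44 uncertain parameters are described by `param_spec` objects
(base value, deterministic bounds, sampling distribution, a setter into
the config). Reading the published parameter table required two
documented interpretation decisions:

* Its "beta" rows mix two conventions: utility and disutility rows are
  genuine shape pairs ($\alpha + \beta = 90$ for the utilities, means
  match the point estimates), while adverse-event risk rows are
  (events, denominator) counts whose ratio equals the printed risk
  (e.g. 159/406 = 0.392). Only this dual reading reproduces every
  printed point estimate, so the two families `beta_ab` and
  `beta_counts` are kept distinct.
* Lenvatinib's uniform parameters (1,452, 2,420) are per-day prices:
  21 × 1,936 = 40,656 reproduces the per-cycle base and the ±25%
  deterministic range. Draws are taken per-day and scaled by 21.
* Three disutilities (diarrhea, decreased appetite, fatigue) are
  published without shape pairs; their beta shapes are derived by method
  of moments treating the ±25% deterministic range as ±2 sd. This is an
  assumption, flagged here; these parameters are too small to move the
  results.

The one-way DSA (`dsa_oneway()`) reruns the full deterministic model at
each parameter's bounds and sorts by INMB spread; the PSA (`run_psa()`)
samples all parameters independently — no covariance structure is
published, see the caveat below — redrawing out-of-support values
(counted, warned). Survival-parameter draws that would invalidate a
model (e.g. non-positive sdlog) are redrawn the same way. `ceac()` and
`evpi()` consume the per-draw cost/effect pairs; ties in net benefit
count for the intervention. Scenario overrides (`apply_scenario()`) are
pure config transformations: horizon, LP price multiplier (intervention
medication only, composable and invertible), discount rates, the
point-value conversion factor (0.9 scales non-medication, supportive
care and AE management costs — the base case values one claims point at
NT$1), and the effect measure.

Reported ICERs always use full-precision deltas; currency rounding is
display-only. This matters: the published INMB is exactly
$0.92 \cdot \mathrm{WTP} - \Delta C$ while the published ICER is *not*
$\Delta C / 0.92$, so the reference pipeline also divided unrounded
quantities.

## The synthetic-data generator

`trial_like_fixture()` emulates the data structure the analysis assumes:
two arms of 411 and 416 subjects, OS/PFS drawn from the base-case
parametric truths by inverse-CDF sampling, administrative censoring at
43 months (the trial's follow-up), digitized curves on a monthly grid
and quarterly risk tables. Within a subject the OS and PFS uniforms are
coupled by a Gaussian copula ($\rho = 0.7$, a value typical of the
strong but imperfect PFS/OS dependence seen in oncology trials), so
PFS ≤ OS holds approximately; a strict mode enforces it per subject.
Both modes matter because the PSM itself assumes curve independence, and
the clamping rule needs exercising. What the generator does *not*
emulate: real digitization error structure (it offers only uniform
ordinate jitter), informative censoring, treatment switching, or cure
fractions — so passing tests demonstrate correctness of the algorithms
on well-specified data, not robustness to every messiness of real
extracted curves.

Problem sizes used in the test-suite simulations — 2,000-subject arms
for reconstruction accuracy and parameter recovery, 10,000 for
distributional (DKW-band) checks, 50,000 for median recovery, 1,000 PSA
iterations — were chosen as the smallest sizes at which the checked
tolerances are comfortably away from Monte-Carlo noise.

## Reproduction accuracy, and a documented discrepancy

With the shipped configuration the deterministic results land close to
the published ones: ICER per QALY within 1% (NT$3,170,978 vs
NT$3,197,177), incremental cost and QALYs within ~6% (the hybrid-curve
gap noted above), the 20% price-reduction scenario flips the decision
exactly as published (INMB +NT$215,184 vs +NT$219,976), and the
scenario ICERs track within a few percent.

The probabilistic results do not, and the gap is structural, not a bug.
Independent sampling of the published distributions yields an INMB
standard deviation of roughly NT$380k and hence a ~27–30% probability of
cost-effectiveness at the threshold and an EVPI of ~NT$50–80k/person.
The published pair (5.5%, EVPI NT$3,903) is internally consistent with
an INMB sd of ≈ NT$155k (under a normal approximation,
$\mathrm{EVPI} = \sigma[\varphi(z) - z(1-\Phi(z))]$ at
$z = 244{,}808/\sigma$ gives NT$3,903 near $\sigma \approx 155$k) — but
the published pembrolizumab uniform alone (±25% of NT$98,668/cycle over
~15 discounted progression-free cycles) contributes ≥ NT$200k of INMB
sd. No independent-sampling PSA of those printed distributions can
produce the printed probability; the reference analysis most plausibly
sampled survival parameters with the (unpublished) fit correlations
and/or narrower effective cost uncertainty. Lacking the covariance, this
package samples independently — the defensible choice given only the
printed table — and reports the wider uncertainty, leaving the
probabilistic comparison red rather than tuning distributions to hit a
number.

## Known limitations

* Two-strategy engine only; no frontier analysis across 3+ options.
* No correlated PSA sampling (no covariances published) and no
  EVPPI/EVSI.
* No treatment-effect waning, cure fractions, or spline/mixture
  extrapolation; covariate-adjusted survival is out of scope.
* The hybrid path is exercised on synthetic fixtures only, since the
  original digitized coordinates are unpublished.
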