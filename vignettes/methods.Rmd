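---
title: "Model structure and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungcea)
```

`lungcea` implements a three-state cohort model for the cost-effectiveness
of toripalimab plus chemotherapy versus chemotherapy alone as first-line
treatment of advanced non-small cell lung cancer (NSCLC) without EGFR/ALK
driver mutations, from the Chinese payer perspective. This vignette is the
package's account of the model: its structure, the inputs, every place
where the published analysis left the construction open and what this
package chose there, and what the validation does and does not establish.

## The model

Patients start progression-free (PFS), may progress (PD), and die. Survival
in each arm is summarized by two Weibull models — overall survival (OS) and
progression-free survival — in accelerated-failure-time (AFT) form with
location `intercept` on log time and `log_scale`, equivalent to

$$S(t) = \exp(-\lambda t^{\gamma}), \qquad
\gamma = e^{-\text{log\_scale}}, \quad \lambda = e^{-\gamma\,\text{intercept}},$$

with $t$ in months (see *Time units* below). The packaged coefficient sets
cover three populations — intention-to-treat (ITT), squamous, and
non-squamous — and both arms, twelve models in all. Where both the AFT
coefficients and the derived shape/rate pairs are available, the package
recomputes $\gamma,\lambda$ from the AFT form (which carries more printed
digits) and uses the published 3-decimal values only as a consistency
check.

The cohort is evaluated on 3-week cycles over a 10-year horizon
(`ceiling(10 * 365.25 / 21)` = 174 cycles), with trapezoidal half-cycle
correction and continuous-time discounting at 3% per year
($(1.03)^{-t}$ with $t$ the exact elapsed years at each cycle boundary).
Costs are in USD at \$1 = RMB 7.2363; the willingness-to-pay threshold is
\$37,653/QALY (three times the 2021 Chinese GDP per capita), with
\$25,100/QALY (twice GDP) as a stricter secondary threshold.

### Occupancy rules

Only the two marginal curves are available, so state occupancy is not
identified without a structural assumption. The package implements two
rules behind a single switch in `run_trace()`:

* **`progressive`** (default): a Markov chain in which the per-cycle
  probability of leaving PFS comes from the PFS-curve hazard, every exit
  from PFS enters PD, and PD drains to death at the OS-curve hazard. Death
  is reached only through progression.
* **`partitioned`**: the partitioned-survival reading — PFS occupancy is
  $S_{PFS}$, death is $1 - S_{OS}$, and PD is the gap, clamped at zero
  (with a logged warning if clamping affects more than 5% of cycles, which
  can happen when independently fitted curves cross).

Partitioned survival is the more common construction in modern health
technology assessment. The progressive chain is the default here because
this package's purpose is to reproduce a specific published analysis, and
the published base-case table is numerically much closer to the chain:
back-calculating state times from the published table (state cost divided
by the per-month cost entering that state, and state QALYs divided by
utility) gives discounted PD times of roughly 13.5 months (placebo) and
21.7 months (toripalimab), where the partitioned rule yields 12.4 and 18.1
and the progressive chain 15.2 and 27.1. Neither rule reproduces the
published PD occupancy exactly — it lies strictly between the two — but
the chain lands the published arm totals and ICERs far more closely. Both
rules satisfy the same conservation and monotonicity invariants and are
tested side by side; every result-producing function takes `rule =` so the
partitioned variant is a one-argument switch.

### Cost-application rules

The published report prices each item "per cycle" but does not state when
each cost applies. The package treats application rules as *data*, not
code: every cost item carries a state, an arm, a cycle window, and an
application kind (`per_cycle`, `per_month`, `one_off`). The packaged
defaults were derived by back-calculating the published base-case table,
which pins them down almost exactly:

* dividing each arm's published PFS-state cost by its implied discounted
  PFS time (in months) returns, to within \$2, the *sum of all that arm's
  recurring Table-type items* — drug, chemotherapy, tests, adverse-event
  management, and hospitalization — i.e. all recurring costs were applied
  **per month** of PFS occupancy, with chemotherapy *not* stopped after
  the induction cycles and adverse-event management recurring rather than
  one-off;
* the published PD-state costs equal the PD treatment price alone times
  the PD time — hospitalization does not accrue in PD;
* the differences between populations' PFS-state costs equal the
  chemotherapy price differences times a *common* state time (see next
  subsection).

The fixtures encode exactly these rules. Users can override any rule in a
config file — e.g. capping chemotherapy at 6 cycles
(`application = "per_cycle"`, `stop_cycle = 5`) or making adverse-event
cost a `one_off` at cycle 0 — without touching code. A
`pd_cost_uptake` multiplier (default 1, i.e. everyone in PD accrues the
subsequent-treatment price) is exposed because partial uptake of
subsequent therapy is a plausible unstated modification; the default does
not use it.

### Population-specific versus shared survival

The published base-case table prints *identical* PD costs and an identical
effectiveness block for all three populations, and its population
differences in PFS-state cost are exactly proportional to the
chemotherapy price differences. That is only consistent with the ITT
survival models having been used for every population, with only the cost
inputs varied. The package therefore supports both readings:

* `builtin_choice01(pop)` returns the population's own fitted survival
  models (the principled default — the squamous and non-squamous models
  exist and differ materially);
* `builtin_choice01(pop, survival = "shared_itt")` and
  `published_base_case()` reproduce the as-published variant.

With population-specific curves the squamous comparison has a much smaller
QALY gain than the ITT one (the squamous toripalimab OS model is far less
favourable), and its ICER is correspondingly higher than the published
value; this is a property of the published inputs, not a package defect.

### Time units

The published report never states the Weibull time unit. Months
(1 month = 30.4375 days; one 3-week cycle = 0.6899 months) is adopted
because it is the only unit under which the models' implied medians are in
the vicinity of the trial's reported Kaplan-Meier medians (e.g. the ITT
placebo PFS model's median is ~6.1 months against a reported 5.6 months —
consistent with parametric smoothing, whereas weeks or cycles are off by
large factors), and under which the back-calculated per-month cost
structure above emerges exactly. The unit is carried on every parameter
object and is configurable.

## Sensitivity analyses

**One-way (tornado).** Parameters are varied one at a time to base ± 30%
(costs) or over their stated ranges (utilities, whose printed ranges are
the ± 30% bounds; caps at [0, 1] are enforced with a message). Cost items
are grouped for the sweep via each item's `dsa_group`: all
progression-free recurring costs of an arm move together, mirroring how
published tornado labels name arm-level treatment costs ("cost of combined
treatment", "cost of chemotherapy in the PFS state"); the two PD treatment
prices are separate parameters. Survival parameters are not varied — the
published one-way analysis varies cost and utility inputs only. Rows are
ranked by the width of the ICER interval.

**Probabilistic (PSA).** Each iteration resamples every cost item from a
gamma distribution and the two utilities from beta distributions (shared
across arms), with mean equal to the base value and standard deviation
`(high - low) / (2 * 1.96)` — the ± 30% interval read as a 95% CI, the
most common convention in published cost-effectiveness analyses
(`sd_rule = "quarter"` gives the `range/4` alternative). Method-of-moments
parameterization is used for both families; an infeasible beta variance
falls back to a uniform draw on the range with a warning. Survival
parameters are held fixed (no uncertainty distribution is published for
them). Because the survival curves do not vary, each iteration is a linear
combination of the sampled values and the pre-computed discounted state
times, so 1,000 iterations take well under a second. The acceptability
curve grid defaults to \$0–\$60,000 in \$1,000 steps, covering both
thresholds above. Sampling is joint-independent (no correlation structure
is published). All sampling is seed-deterministic by contract.

## Curve fitting and synthetic validation

The published analysis digitized Kaplan-Meier curves and fitted Weibull
models to reconstructed individual-patient data (IPD). No digitized
coordinates are published, so this stage is validated entirely against
synthetic ground truth and the packaged AFT coefficients are taken as the
authoritative inputs to the cohort model:

* `simulate_ipd()` draws Weibull event times by inverse transform with
  administrative or exponential censoring;
* `km_estimate()` is the product-limit estimator
  (via `survival::survfit()`);
* `digitize()` emulates digitizer error: sampling on a grid,
  multiplicative noise, re-monotonization by running minimum;
* `reconstruct_ipd()` inverts the product-limit construction with a
  running-correction rounding (cumulative drift below one subject), a
  simplified Hoyle–Henley-style scheme — without a risk table it assumes
  no censoring before the last coordinate; with one, unexplained attrition
  is censored uniformly within intervals. The exact Guyot algorithm is out
  of scope.
* `fit_weibull_ls()` regresses $\log(-\log S)$ on $\log t$ (exact for
  noiseless Weibull points); `fit_weibull_mle()` maximizes the censored
  Weibull likelihood via `survival::survreg()`, with the package's own
  log-likelihood (`weibull_loglik()`) retained as an independent
  stationarity check in the tests.

The generator reproduces the statistical structure the fitting stage
assumes — Weibull margins, independent censoring, monotone noisy
coordinates — and deliberately not features of real trial data such as
delayed treatment effects, non-proportional hazards beyond the Weibull
family, informative censoring, or correlated OS/PFS outcomes (the
published analysis also fits the two endpoints independently). Passing the
round-trip tests therefore shows the pipeline is self-consistent, not that
a Weibull is the right model for any particular trial.

Test problem sizes were chosen to keep sampling error well below the
asserted tolerances at interactive runtimes: single-draw shape recovery
and mean rate recovery over seeded replicates at n = 2,000 (the rate's
single-draw sampling SD at that size, ~10%, exceeds the 5% recovery
tolerance, so the rate is checked on the replicate mean), KM concentration
at n = 5,000, distributional convergence checks at n = 10^5.

## Numerical choices and degenerate inputs

* PD occupancy clamping (partitioned rule) at 0, with a warning when more
  than 5% of cycles clamp.
* Half-cycle correction is the trapezoid of the discounted occupancy;
  setting `half_cycle_correction = FALSE` uses left endpoints.
* One-off costs accrue at their start cycle weighted by state occupancy
  and discount factor at that boundary.
* `icer()` returns dominance labels ("dominant"/"dominated") on the
  off-diagonal quadrants, "undefined" for a zero QALY increment with
  non-zero cost, and 0 for identical strategies; the tornado and PSA use
  the raw cost/QALY ratio, which can validly be negative.
* Capped mean survival uses a trapezoid at one-cycle steps by default
  (checked against adaptive quadrature to 0.1%).
* Parameter files are strict: unknown keys, missing fields, inverted
  ranges, or unknown enumeration values are rejected by name.

## Known limitations

* The published PD occupancy lies between the two implemented occupancy
  rules; neither reproduces the published QALY totals to better than
  about 10%, and the package reports what its engine computes rather than
  interpolating structures to match.
* No background (other-cause) mortality beyond the OS curve; no
  adverse-event disutilities (the trial reported similar AE incidence in
  both arms); no microsimulation; no multi-strategy frontier; no EVPI.
* Costs reflect one institution's 2022 prices converted at a fixed
  exchange rate.
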