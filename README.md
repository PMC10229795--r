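# lungcea

Cost-effectiveness modelling of toripalimab plus chemotherapy versus
chemotherapy alone as first-line treatment of advanced non-small cell lung
cancer (NSCLC) without EGFR/ALK driver mutations, from the Chinese payer
perspective. The package is aimed at health-economics analysts who want a
scriptable, testable version of this decision model — and a reusable
skeleton for similar two-arm, three-state oncology models.

## What it computes

A cohort moves through three health states — progression-free (PFS),
progressed disease (PD), dead — on 3-week cycles over a 10-year horizon.
Each arm's survival is summarized by Weibull accelerated-failure-time
models for overall and progression-free survival,

S(t) = exp(−λ t^γ),  γ = exp(−log_scale),  λ = exp(−γ · intercept),

with t in months. State occupancy comes from these curves (a progressive
Markov chain by default, partitioned survival as an option — see the
methods vignette), costs and utilities accrue per cycle with half-cycle
correction and 3% annual discounting, and the arms are compared by

- **ICER** = ΔCost / ΔQALY, against willingness-to-pay thresholds of
  $37,653/QALY (3× Chinese GDP per capita, 2021) and $25,100/QALY (2×);
- **NMB** = WTP · ΔQALY − ΔCost;
- one-way (±30%) sensitivity analysis with tornado ranking;
- probabilistic sensitivity analysis (1,000 Monte Carlo iterations,
  gamma-distributed costs, beta-distributed utilities) with
  cost-effectiveness acceptability curves.

All published model inputs (per-cycle costs with ranges and distribution
families, utilities 0.673/0.473/0, and the twelve Weibull coefficient
sets for three populations × two arms × two endpoints) ship as editable
JSON fixtures. A curve-fitting stage (`reconstruct_ipd()`,
`fit_weibull_ls()`, `fit_weibull_mle()`) re-implements the digitized
Kaplan-Meier → pseudo individual-patient data → Weibull pipeline the
original analysis used, validated against the package's seeded synthetic
data generator.

## Worked example

```r
library(lungcea)

spec <- builtin_choice01("ITT")   # packaged inputs, intention-to-treat
res  <- compare_arms(spec)
res
#> <cea_result> ITT (progressive rule)
#>   toripalimab: $28914, 1.780 QALYs | placebo: $14278, 0.999 QALYs
#>   delta cost $14636, delta QALYs 0.781, ICER $18735/QALY
#>   NMB at WTP $37653: $14778 -> cost-effective
```

Adding toripalimab costs $14,636 more per patient over ten years
(discounted) and yields 0.781 extra quality-adjusted life years, so each
QALY gained costs $18,735 — well under both Chinese willingness-to-pay
thresholds. `tidy()` gives the state-level breakdown:

```r
tidy(res)
#> # A tibble: 6 × 5
#>   population quantity         placebo toripalimab incremental
#> 1 ITT        cost_pfs_state  9078.      20821.      11744.
#> 2 ITT        cost_pd_state   5201.       8093.       2892.
#> 3 ITT        cost_total     14278.      28914.      14636.
#> 4 ITT        qaly_pfs_state     0.400       0.713       0.314
#> 5 ITT        qaly_pd_state      0.599       1.07        0.467
#> 6 ITT        qaly_total         0.999       1.78        0.781
```

Most of the extra spending is drug cost while progression-free; the QALY
gain splits between longer progression-free time and longer
post-progression survival. Uncertainty:

```r
run_psa(spec, n_iter = 1000, seed = 1)
#> <psa_result> ITT: 1000 iterations, P(cost-effective at WTP $37653) = 1.000

head(one_way(spec), 3)
#> # A tibble: 3 × 6
#>   parameter                 low_value high_value icer_at_low icer_at_high spread
#> 1 combined_arm_pfs_cost       1146.      2128.        10739.       26731. 15992.
#> 2 chemotherapy_arm_pfs_cost    892.      1656.        22221.       15249.  6972.
#> 3 u_pd                           0.33       0.61      22873.       15968.  6906.
```

Every 1,000-iteration draw is cost-effective at the $37,653 threshold,
and the combined arm's treatment cost is by far the most influential
single input. `autoplot()` methods draw the trace, tornado, CE-plane
scatter and acceptability curve; `one_way()` and `ceac()` return plain
tibbles for custom reporting.

The squamous and non-squamous populations run the same way
(`builtin_choice01("squamous")`, `"non_squamous"`), and
`published_base_case()` runs all three under the as-published variant in
which the ITT survival models are shared across populations (see the
methods vignette for why that variant exists). Custom analyses start from
`save_parameters()` / `load_parameters()` on an edited JSON copy of any
fixture.

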