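# Shared fixtures, built in code.

# The printed survival-distribution table: AFT intercept/log(scale) and the
# published 3-d.p. shape (gamma) / rate (lambda) for each population, arm
# and endpoint.
table2_printed <- function() {
  tibble::tribble(
    ~pop, ~arm, ~endpoint, ~intercept, ~log_scale, ~gamma, ~lambda,
    "ITT", "placebo", "os", 3.119, -0.539, 1.715, 0.005,
    "squamous", "placebo", "os", 3.090, -0.851, 2.341, 0.001,
    "non_squamous", "placebo", "os", 3.084, -0.399, 1.490, 0.010,
    "ITT", "toripalimab", "os", 3.5639, -0.186, 1.205, 0.014,
    "squamous", "toripalimab", "os", 3.230, -0.308, 1.360, 0.012,
    "non_squamous", "toripalimab", "os", 3.758, -0.175, 1.191, 0.011,
    "ITT", "placebo", "pfs", 2.072, -0.352, 1.422, 0.053,
    "squamous", "placebo", "pfs", 1.995, -0.621, 1.860, 0.024,
    "non_squamous", "placebo", "pfs", 2.139, -0.217, 1.242, 0.070,
    "ITT", "toripalimab", "pfs", 2.636, -0.203, 1.226, 0.040,
    "squamous", "toripalimab", "pfs", 2.463, -0.263, 1.300, 0.041,
    "non_squamous", "toripalimab", "pfs", 2.777, -0.174, 1.190, 0.037
  )
}

# Tolerances implied by 3-d.p. printing of both the AFT inputs and the
# derived values: |d gamma| <= 0.0005 (print) + gamma * 0.0005 (input
# rounding); lambda's sensitivity to the rounded inputs is tiny relative
# to its own print step.
TOL_GAMMA_PRINTED <- 0.0015
TOL_LAMBDA_PRINTED <- 0.0006

# Published base-case cost-effectiveness table (costs in USD, QALYs).
table3_printed <- function() {
  tibble::tribble(
    ~pop, ~cost_placebo, ~cost_toripalimab, ~delta_cost, ~icer,
    "ITT", 13945, 28392, 14447, 21563,
    "squamous", 11367, 23674, 12307, 18369,
    "non_squamous", 16523, 33108, 16585, 24754
  )
}

# A symmetric bundle (same survival models and costs in both arms), handy
# for zero-increment checks.
symmetric_spec <- function(per_month = 100) {
  os <- weibull_params(gamma = 1.5, lambda = 0.02)
  pfs <- weibull_params(gamma = 1.4, lambda = 0.06)
  costs <- cost_item("care", "both", "PFS", per_month)
  population_spec(
    population = "ITT",
    survival = list(toripalimab = list(os = os, pfs = pfs),
                    placebo = list(os = os, pfs = pfs)),
    costs = costs,
    utilities = utility_set()
  )
}

# The packaged bundle with every sampling distribution degenerate.
degenerate_spec <- function(pop = "ITT") {
  spec <- builtin_choice01(pop)
  spec$costs$distribution <- "fixed"
  spec$utilities$distribution <- "fixed"
  spec
}

all_packaged_arm_models <- function() {
  out <- list()
  for (pop in c("ITT", "squamous", "non_squamous")) {
    spec <- builtin_choice01(pop)
    for (arm in c("toripalimab", "placebo")) {
      out[[paste(pop, arm)]] <- spec$survival[[arm]]
    }
  }
  out
}
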