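# Probabilistic sensitivity analysis: parameter sampling, Monte Carlo
# propagation, and the cost-effectiveness acceptability curve.

#' Sample a cost item's value
#'
#' Draws from a gamma distribution with mean equal to the base value and
#' standard deviation derived from the one-way range, parameterized by the
#' method of moments (`shape = mean^2/sd^2`, `scale = sd^2/mean`). A
#' `"fixed"` item (or a zero standard deviation) returns the base value; a
#' zero base with a gamma family degenerates to 0.
#'
#' @param item A one-row cost item (see [cost_item()]).
#' @param n Number of draws.
#' @param sd_rule How the range maps to a standard deviation: `"ci95"`
#'   treats \[low, high\] as a 95% interval (`sd = (high - low)/3.92`, the
#'   common convention), `"quarter"` uses `sd = (high - low)/4`.
#' @return Numeric vector of `n` non-negative draws.
#' @export
sample_cost <- function(item, n = 1, sd_rule = c("ci95", "quarter")) {
  sd_rule <- match.arg(sd_rule)
  m <- item$base_value
  s <- cost_sd(item, sd_rule)
  if (item$distribution == "fixed" || s == 0) return(rep(m, n))
  if (item$distribution != "gamma") {
    stop("sample_cost expects a gamma or fixed item", call. = FALSE)
  }
  if (m == 0) return(rep(0, n))
  shape <- m^2 / s^2
  scale <- s^2 / m
  stats::rgamma(n, shape = shape, scale = scale)
}

cost_sd <- function(item, sd_rule) {
  width <- item$high - item$low
  if (sd_rule == "quarter") width / 4 else width / (2 * 1.96)
}

#' Sample a utility value
#'
#' Draws from a beta distribution with mean equal to the base value and
#' standard deviation derived from the range by the same rule as
#' [sample_cost()], using method-of-moments shapes
#' `alpha = m (m(1-m)/s^2 - 1)`, `beta = (1-m)(m(1-m)/s^2 - 1)`. If the
#' implied shapes are not positive the draw falls back to
#' `uniform(low, high)` with a warning.
#'
#' @param base Base utility in (0, 1).
#' @param low,high Range of the utility.
#' @param n Number of draws.
#' @inheritParams sample_cost
#' @return Numeric vector of `n` draws in (0, 1).
#' @export
sample_utility <- function(base, low, high, n = 1,
                           sd_rule = c("ci95", "quarter")) {
  sd_rule <- match.arg(sd_rule)
  stopifnot(base > 0, base < 1)
  s <- if (sd_rule == "quarter") (high - low) / 4 else (high - low) / 3.92
  if (s == 0) return(rep(base, n))
  nu <- base * (1 - base) / s^2 - 1
  alpha <- base * nu
  beta <- (1 - base) * nu
  if (alpha <= 0 || beta <= 0) {
    warning("implied beta shapes not positive; falling back to uniform(",
            low, ", ", high, ")", call. = FALSE)
    return(stats::runif(n, low, high))
  }
  stats::rbeta(n, alpha, beta)
}

# Per-dollar accrual factor of every cost item in one arm (cost at
# base_value = 1), used to make each Monte Carlo iteration a linear
# combination of the sampled values.
unit_cost_factors <- function(trace, costs, settings, arm, uptake) {
  unit <- dplyr::mutate(costs, low = 0, base_value = 1, high = 2)
  accumulate(trace, unit, utility_set(), settings, arm, uptake)$breakdown
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: per iteration, every
#' cost item is resampled from its distribution and the two utilities from
#' theirs (utilities are shared across arms), both arms are re-evaluated,
#' and the incremental cost and QALYs are recorded. The survival models
#' are held fixed (no distribution is available for them). Results are
#' reproducible: the same seed and inputs give identical output.
#'
#' @inheritParams run_arm
#' @param n_iter Number of iterations (default from the settings: 1,000).
#' @param seed Integer seed for the sampler (required).
#' @inheritParams sample_cost
#' @return An object of class `psa_result`: `$samples` (one row per
#'   iteration with the sampled parameter values, `delta_cost`,
#'   `delta_qaly`, `nmb`, `acceptable`, `quadrant`), `$base` (the
#'   deterministic [compare_arms()] result) and `$summary` (fraction
#'   acceptable at the settings' WTP and quadrant fractions).
#' @examples
#' run_psa(builtin_choice01("ITT"), n_iter = 50, seed = 1)
#' @export
run_psa <- function(spec, settings = model_settings(),
                    n_iter = settings$psa_iterations, seed,
                    rule = OCCUPANCY_RULES, sd_rule = c("ci95", "quarter")) {
  rule <- match.arg(rule)
  sd_rule <- match.arg(sd_rule)
  stopifnot(inherits(spec, "population_spec"))
  if (n_iter < 1) stop("n_iter must be at least 1", call. = FALSE)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible sampling", call. = FALSE)
  }
  set.seed(seed)

  base <- compare_arms(spec, settings, rule)
  traces <- lapply(base$arms, function(a) a$trace)
  factors <- lapply(stats::setNames(ARMS, ARMS), function(a) {
    unit_cost_factors(traces[[a]], spec$costs, settings, a,
                      spec$pd_cost_uptake)
  })
  # discounted state time in years per arm and state (QALY per unit utility)
  cyc_years <- settings$cycle_days / DAYS_PER_YEAR
  hc <- settings$half_cycle_correction
  ytime <- lapply(traces, function(tr) {
    c(PFS = sum(interval_weights(tr$occ_pfs, tr$disc_factor, hc)) * cyc_years,
      PD = sum(interval_weights(tr$occ_pd, tr$disc_factor, hc)) * cyc_years)
  })

  # each item is sampled once per iteration and applied to the arms it
  # belongs to; items are rows, iterations are columns
  items <- spec$costs
  draws <- matrix(0, nrow = nrow(items), ncol = n_iter)
  for (i in seq_len(nrow(items))) {
    draws[i, ] <- sample_cost(items[i, ], n_iter, sd_rule)
  }
  u <- spec$utilities
  u_pfs <- if (u$distribution == "fixed") rep(u$u_pfs, n_iter) else {
    sample_utility(u$u_pfs, u$pfs_low, u$pfs_high, n_iter, sd_rule)
  }
  u_pd <- if (u$distribution == "fixed") rep(u$u_pd, n_iter) else {
    sample_utility(u$u_pd, u$pd_low, u$pd_high, n_iter, sd_rule)
  }

  fac_of <- function(arm) {
    f <- numeric(nrow(items))
    applies <- items$arm %in% c(arm, "both")
    idx <- match(items$name[applies], factors[[arm]]$name)
    f[applies] <- factors[[arm]]$cost[idx]
    f
  }
  f_to <- fac_of("toripalimab")
  f_pl <- fac_of("placebo")

  cost_to <- as.numeric(crossprod(draws, f_to))
  cost_pl <- as.numeric(crossprod(draws, f_pl))
  qaly_to <- u_pfs * ytime$toripalimab[["PFS"]] + u_pd * ytime$toripalimab[["PD"]]
  qaly_pl <- u_pfs * ytime$placebo[["PFS"]] + u_pd * ytime$placebo[["PD"]]
  dc <- cost_to - cost_pl
  de <- qaly_to - qaly_pl
  nmb <- net_monetary_benefit(dc, de, settings$wtp_per_qaly)

  sampled <- tibble::as_tibble(stats::setNames(
    as.data.frame(t(draws)), items$name
  ))
  samples <- dplyr::bind_cols(
    tibble::tibble(iteration = seq_len(n_iter)),
    sampled,
    tibble::tibble(
      u_pfs = u_pfs, u_pd = u_pd,
      cost_toripalimab = cost_to, cost_placebo = cost_pl,
      qaly_toripalimab = qaly_to, qaly_placebo = qaly_pl,
      delta_cost = dc, delta_qaly = de,
      nmb = nmb, acceptable = nmb > 0,
      quadrant = dplyr::case_when(
        de >= 0 & dc >= 0 ~ "NE",
        de >= 0 & dc < 0 ~ "SE",
        de < 0 & dc >= 0 ~ "NW",
        TRUE ~ "SW"
      )
    )
  )

  summary <- tibble::tibble(
    population = spec$population,
    n_iter = n_iter,
    wtp = settings$wtp_per_qaly,
    prob_cost_effective = mean(samples$acceptable),
    mean_delta_cost = mean(dc),
    mean_delta_qaly = mean(de),
    frac_ne = mean(samples$quadrant == "NE"),
    frac_se = mean(samples$quadrant == "SE"),
    frac_nw = mean(samples$quadrant == "NW"),
    frac_sw = mean(samples$quadrant == "SW")
  )

  structure(list(samples = samples, base = base, summary = summary,
                 seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<psa_result> %s: %d iterations, P(cost-effective at WTP $%.0f) = %.3f\n",
    s$population, s$n_iter, s$wtp, s$prob_cost_effective
  ))
  invisible(x)
}

#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) x$samples

#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) x$summary

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of Monte Carlo samples
#' with positive net monetary benefit.
#'
#' @param x A [run_psa()] result, or a data frame with `delta_cost` and
#'   `delta_qaly` columns.
#' @param wtp_grid Non-negative WTP values; the default $0-$60,000 in
#'   $1,000 steps covers both thresholds discussed for the Chinese setting
#'   (twice and three times GDP per capita).
#' @return A tibble of class `ceac_tbl` with columns `wtp` and
#'   `prob_cost_effective`.
#' @export
ceac <- function(x, wtp_grid = seq(0, 60000, by = 1000)) {
  samples <- if (inherits(x, "psa_result")) x$samples else x
  if (!is.data.frame(samples) || nrow(samples) == 0) {
    stop("no samples to summarize", call. = FALSE)
  }
  if (any(wtp_grid < 0)) stop("wtp_grid must be non-negative", call. = FALSE)
  out <- purrr::map_dfr(wtp_grid, function(w) {
    tibble::tibble(
      wtp = w,
      prob_cost_effective =
        mean(net_monetary_benefit(samples$delta_cost, samples$delta_qaly, w) > 0)
    )
  })
  structure(out, class = c("ceac_tbl", class(tibble::tibble())))
}
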