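# Model inputs: settings, cost items, utilities, per-population parameter
# bundles, config-file I/O, and the packaged CHOICE-01 fixture values.

COST_DISTRIBUTIONS <- c("gamma", "beta", "fixed")
COST_APPLICATIONS <- c("per_cycle", "per_month", "one_off")
COST_STATES <- c("PFS", "PD")
ARMS <- c("toripalimab", "placebo")
POPULATIONS <- c("ITT", "squamous", "non_squamous")

COST_ITEM_FIELDS <- c("name", "arm", "state", "base_value", "low", "high",
                      "distribution", "application", "start_cycle",
                      "stop_cycle", "dsa_group")

#' Global model settings
#'
#' Cycle length, horizon, discounting, half-cycle correction flag,
#' willingness-to-pay threshold, currency conversion and the sensitivity
#' analysis defaults. The defaults are the published study conditions:
#' 3-week cycles, a 10-year horizon with half-cycle correction, a 3% annual
#' discount rate, a WTP threshold of $37,653/QALY (three times the 2021
#' Chinese GDP per capita), $1 = RMB 7.2363, 1,000 Monte Carlo iterations
#' and one-way parameter ranges of +/-30%.
#'
#' @param cycle_days Days per model cycle (> 0).
#' @param horizon_years Time horizon in years (> 0).
#' @param discount_annual Annual discount rate, a fraction in \[0, 1).
#' @param half_cycle_correction Apply the trapezoidal half-cycle correction?
#' @param wtp_per_qaly Willingness-to-pay threshold, USD per QALY.
#' @param rmb_per_usd Exchange rate, RMB per USD.
#' @param psa_iterations Default number of probabilistic iterations.
#' @param dsa_range_fraction Default one-way variation as a fraction of the
#'   base value.
#' @return An object of class `model_settings`.
#' @examples
#' model_settings()
#' model_settings(discount_annual = 0)
#' @export
model_settings <- function(cycle_days = 21,
                           horizon_years = 10,
                           discount_annual = 0.03,
                           half_cycle_correction = TRUE,
                           wtp_per_qaly = 37653,
                           rmb_per_usd = 7.2363,
                           psa_iterations = 1000,
                           dsa_range_fraction = 0.30) {
  stopifnot(
    cycle_days > 0,
    horizon_years > 0,
    discount_annual >= 0, discount_annual < 1,
    wtp_per_qaly > 0,
    rmb_per_usd > 0,
    psa_iterations >= 1,
    dsa_range_fraction >= 0
  )
  structure(
    list(cycle_days = cycle_days, horizon_years = horizon_years,
         discount_annual = discount_annual,
         half_cycle_correction = isTRUE(half_cycle_correction),
         wtp_per_qaly = wtp_per_qaly, rmb_per_usd = rmb_per_usd,
         psa_iterations = as.integer(psa_iterations),
         dsa_range_fraction = dsa_range_fraction),
    class = "model_settings"
  )
}

#' Number of model cycles implied by the settings
#'
#' `ceiling(horizon_years * 365.25 / cycle_days)`; 174 under the defaults.
#'
#' @param settings A [model_settings()] object.
#' @return Integer cycle count.
#' @export
n_cycles <- function(settings) {
  stopifnot(inherits(settings, "model_settings"))
  as.integer(ceiling(settings$horizon_years * DAYS_PER_YEAR / settings$cycle_days))
}

#' Cost item
#'
#' One cost input and its application rule: which arm and health state it
#' accrues in, over which cycle window, and whether the value applies per
#' model cycle, per month of state occupancy, or once. Costs are stored in
#' USD (use [convert_currency()] for RMB prices).
#'
#' @param name Item label.
#' @param arm `"toripalimab"`, `"placebo"`, or `"both"`.
#' @param state Health state the cost accrues in: `"PFS"` or `"PD"`.
#' @param base_value,low,high Base value and one-way range, USD per
#'   application.
#' @param distribution Sampling family for probabilistic analysis:
#'   `"gamma"`, `"beta"`, or `"fixed"`.
#' @param application `"per_cycle"`, `"per_month"`, or `"one_off"`.
#' @param start_cycle,stop_cycle First and last cycle (0-based) in which
#'   the item applies; `stop_cycle = Inf` means unbounded.
#' @param dsa_group Label grouping items that are varied together in the
#'   one-way sensitivity analysis; defaults to `name`.
#' @return A one-row tibble.
#' @examples
#' cost_item("toripalimab", "toripalimab", "PFS", 342, 239, 445)
#' @export
cost_item <- function(name, arm, state, base_value,
                      low = 0.7 * base_value, high = 1.3 * base_value,
                      distribution = "gamma", application = "per_month",
                      start_cycle = 0, stop_cycle = Inf,
                      dsa_group = name) {
  out <- tibble::tibble(
    name = as.character(name),
    arm = as.character(arm),
    state = as.character(state),
    base_value = as.numeric(base_value),
    low = as.numeric(low),
    high = as.numeric(high),
    distribution = as.character(distribution),
    application = as.character(application),
    start_cycle = as.numeric(start_cycle),
    stop_cycle = as.numeric(stop_cycle),
    dsa_group = as.character(dsa_group)
  )
  validate_cost_items(out)
  out
}

#' @keywords internal
validate_cost_items <- function(costs) {
  stopifnot(is.data.frame(costs))
  missing <- setdiff(COST_ITEM_FIELDS, names(costs))
  if (length(missing)) {
    stop("cost items missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(costs), COST_ITEM_FIELDS)
  if (length(extra)) {
    stop("unknown cost item field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(costs))) {
    row <- costs[i, ]
    if (row$base_value < 0) {
      stop("negative cost for item '", row$name, "'", call. = FALSE)
    }
    if (!(row$low <= row$base_value && row$base_value <= row$high)) {
      stop("cost item '", row$name, "' violates low <= base <= high",
           call. = FALSE)
    }
    if (!row$distribution %in% COST_DISTRIBUTIONS) {
      stop("unknown distribution '", row$distribution, "' for item '",
           row$name, "' (expected one of ",
           paste(COST_DISTRIBUTIONS, collapse = ", "), ")", call. = FALSE)
    }
    if (!row$application %in% COST_APPLICATIONS) {
      stop("unknown application '", row$application, "' for item '",
           row$name, "'", call. = FALSE)
    }
    if (!row$state %in% COST_STATES) {
      stop("unknown state '", row$state, "' for item '", row$name, "'",
           call. = FALSE)
    }
    if (!row$arm %in% c(ARMS, "both")) {
      stop("unknown arm '", row$arm, "' for item '", row$name, "'",
           call. = FALSE)
    }
    if (row$start_cycle > row$stop_cycle) {
      stop("cost item '", row$name, "' has start_cycle > stop_cycle",
           call. = FALSE)
    }
  }
  invisible(costs)
}

#' Health-state utilities
#'
#' Annual utility weights for the three health states, with one-way ranges
#' and the sampling family used in probabilistic analysis. The packaged
#' base case uses 0.673 (progression-free), 0.473 (progressed) and 0
#' (death), beta-distributed over the printed +/-30% ranges.
#'
#' @param u_pfs,u_pd Utilities for the progression-free and progressed
#'   states (`0 <= u_pd <= u_pfs <= 1`).
#' @param u_death Utility of death; must be 0.
#' @param pfs_low,pfs_high,pd_low,pd_high One-way ranges.
#' @param distribution Sampling family (`"beta"` or `"fixed"`).
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_pfs = 0.673, u_pd = 0.473, u_death = 0,
                        pfs_low = 0.47, pfs_high = 0.87,
                        pd_low = 0.33, pd_high = 0.61,
                        distribution = "beta") {
  if (!(u_pd >= 0 && u_pfs >= u_pd && u_pfs <= 1)) {
    stop("utilities must satisfy 0 <= u_pd <= u_pfs <= 1", call. = FALSE)
  }
  if (u_death != 0) stop("u_death must be 0", call. = FALSE)
  if (!distribution %in% c("beta", "fixed")) {
    stop("unknown utility distribution '", distribution, "'", call. = FALSE)
  }
  structure(
    list(u_pfs = u_pfs, u_pd = u_pd, u_death = u_death,
         pfs_low = pfs_low, pfs_high = pfs_high,
         pd_low = pd_low, pd_high = pd_high,
         distribution = distribution),
    class = "utility_set"
  )
}

#' Per-population parameter bundle
#'
#' Everything the cohort model needs for one patient population: the OS
#' and PFS Weibull models of both arms, the cost items with their
#' application rules, the utilities, and the optional uptake multiplier
#' applied to progressed-state treatment costs (fraction of progressed
#' patients actually receiving subsequent therapy; 1 by default).
#'
#' @param population One of `"ITT"`, `"squamous"`, `"non_squamous"`.
#' @param survival Nested list: `survival$toripalimab$os`, `...$pfs`,
#'   `survival$placebo$os`, `...$pfs`, each a [weibull_params()].
#' @param costs Tibble of cost items (see [cost_item()]).
#' @param utilities A [utility_set()].
#' @param pd_cost_uptake Multiplier in \[0, 1\] on progressed-state costs.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(population, survival, costs, utilities,
                            pd_cost_uptake = 1) {
  if (!population %in% POPULATIONS) {
    stop("unknown population '", population, "' (expected one of ",
         paste(POPULATIONS, collapse = ", "), ")", call. = FALSE)
  }
  for (arm in ARMS) {
    for (endpoint in c("os", "pfs")) {
      m <- survival[[arm]][[endpoint]]
      if (!inherits(m, "weibull_params")) {
        stop("missing or invalid ", toupper(endpoint), " model for arm '",
             arm, "'", call. = FALSE)
      }
    }
  }
  validate_cost_items(costs)
  stopifnot(inherits(utilities, "utility_set"))
  if (pd_cost_uptake < 0 || pd_cost_uptake > 1) {
    stop("pd_cost_uptake must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(population = population, survival = survival, costs = costs,
         utilities = utilities, pd_cost_uptake = pd_cost_uptake),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec> ", x$population, ": ", nrow(x$costs),
      " cost items, u_pfs = ", x$utilities$u_pfs,
      ", u_pd = ", x$utilities$u_pd, "\n", sep = "")
  invisible(x)
}

weibull_from_config <- function(x, where) {
  allowed <- c("intercept", "log_scale", "gamma", "lambda", "time_unit")
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(weibull_params, x)
}

#' Load a population parameter file
#'
#' Reads a structured JSON parameter file (the same schema as the packaged
#' fixtures; see [save_parameters()]), validates every invariant and
#' rejects unknown keys.
#'
#' @param path Path to a JSON parameter file.
#' @return A [population_spec()].
#' @seealso [builtin_choice01()] for the packaged values.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  allowed <- c("population", "survival", "costs", "utilities",
               "pd_cost_uptake")
  extra <- setdiff(names(raw), allowed)
  if (length(extra)) {
    stop("unknown key(s) in parameter file: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(c("population", "survival", "costs", "utilities"),
                     names(raw))
  if (length(missing)) {
    stop("parameter file missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  surv <- lapply(ARMS, function(arm) {
    node <- raw$survival[[arm]]
    if (is.null(node)) stop("missing survival models for arm '", arm, "'",
                            call. = FALSE)
    list(os = weibull_from_config(node$os, paste0(arm, "$os")),
         pfs = weibull_from_config(node$pfs, paste0(arm, "$pfs")))
  })
  names(surv) <- ARMS
  costs <- purrr::map_dfr(raw$costs, function(item) {
    extra <- setdiff(names(item), COST_ITEM_FIELDS)
    if (length(extra)) {
      stop("unknown cost item key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    item$stop_cycle <- if (is.null(item$stop_cycle)) Inf else item$stop_cycle
    tibble::as_tibble(item)
  })
  u <- raw$utilities
  allowed_u <- c("u_pfs", "u_pd", "u_death", "pfs_low", "pfs_high",
                 "pd_low", "pd_high", "distribution")
  extra <- setdiff(names(u), allowed_u)
  if (length(extra)) {
    stop("unknown utility key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  population_spec(
    population = raw$population,
    survival = surv,
    costs = costs,
    utilities = do.call(utility_set, u),
    pd_cost_uptake = raw$pd_cost_uptake %||% 1
  )
}

#' Save a population parameter set
#'
#' Writes a [population_spec()] to JSON so that
#' `load_parameters(save_parameters(spec, path))` round-trips identically.
#'
#' @param spec A [population_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(spec, path) {
  stopifnot(inherits(spec, "population_spec"))
  costs <- purrr::pmap(spec$costs, function(...) {
    row <- list(...)
    if (is.infinite(row$stop_cycle)) row$stop_cycle <- NULL
    row
  })
  out <- list(
    population = spec$population,
    survival = lapply(spec$survival, function(arm) {
      lapply(arm, function(m) {
        list(intercept = m$intercept, log_scale = m$log_scale,
             time_unit = m$time_unit)
      })
    }),
    costs = costs,
    utilities = unclass(spec$utilities),
    pd_cost_uptake = spec$pd_cost_uptake
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Packaged CHOICE-01 model inputs
#'
#' Returns the parameter bundle for one of the three study populations,
#' loaded from the JSON fixtures shipped with the package: per-cycle costs
#' and their ranges, health-state utilities, and the Weibull OS/PFS models
#' of both arms.
#'
#' The published base-case cost-effectiveness table is numerically
#' consistent with the intention-to-treat survival models having been
#' applied to all three populations (its progressed-state costs and the
#' whole effectiveness block are identical across populations).
#' `survival = "shared_itt"` reproduces that variant by substituting the
#' ITT survival models into the squamous/non-squamous bundles;
#' `"population"` (default) keeps each population's own fitted models.
#'
#' @param population `"ITT"`, `"squamous"`, or `"non_squamous"`.
#' @param survival `"population"` or `"shared_itt"` (see Details).
#' @return A [population_spec()].
#' @examples
#' builtin_choice01("ITT")
#' @export
builtin_choice01 <- function(population = c("ITT", "squamous", "non_squamous"),
                             survival = c("population", "shared_itt")) {
  population <- match.arg(population)
  survival <- match.arg(survival)
  file <- c(ITT = "choice01_itt.json",
            squamous = "choice01_squamous.json",
            non_squamous = "choice01_nonsquamous.json")[[population]]
  path <- system.file("extdata", file, package = "lungcea", mustWork = TRUE)
  spec <- load_parameters(path)
  if (survival == "shared_itt" && population != "ITT") {
    itt <- builtin_choice01("ITT")
    spec$survival <- itt$survival
  }
  spec
}

#' Convert an RMB amount to USD
#'
#' Uses the study's exchange rate ($1 = RMB 7.2363) unless another rate is
#' given.
#'
#' @param amount_rmb Non-negative amount in RMB.
#' @param rmb_per_usd Exchange rate.
#' @return Amount in USD.
#' @examples
#' convert_currency(7.2363)  # 1
#' @export
convert_currency <- function(amount_rmb, rmb_per_usd = 7.2363) {
  if (any(amount_rmb < 0)) stop("amount must be non-negative", call. = FALSE)
  stopifnot(rmb_per_usd > 0)
  amount_rmb / rmb_per_usd
}
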