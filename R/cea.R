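# Incremental cost-effectiveness statistics and the paired-arm comparison.

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_qaly` when the incremental QALYs are positive;
#' `"dominant"` when the intervention is cheaper and more effective,
#' `"dominated"` when costlier and less effective, `"undefined"` when the
#' incremental QALYs are zero but the incremental cost is not. Both deltas
#' zero give 0 (the strategies are identical).
#'
#' @param delta_cost Incremental cost (intervention minus comparator), USD.
#' @param delta_qaly Incremental QALYs.
#' @return A number (USD/QALY) or a dominance label.
#' @examples
#' icer(14447, 0.67)  # 21563 to the nearest dollar
#' icer(-100, 0.5)    # "dominant"
#' @export
icer <- function(delta_cost, delta_qaly) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly))
  if (delta_qaly == 0) {
    return(if (delta_cost == 0) 0 else "undefined")
  }
  if (delta_cost <= 0 && delta_qaly > 0) return("dominant")
  if (delta_cost >= 0 && delta_qaly < 0) return("dominated")
  delta_cost / delta_qaly
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`; the intervention is cost-effective at
#' the threshold `wtp` exactly when the result is positive.
#'
#' @inheritParams icer
#' @param wtp Willingness-to-pay threshold, USD/QALY (>= 0).
#' @return Net monetary benefit in USD.
#' @examples
#' net_monetary_benefit(14447, 0.67, 37653)
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative", call. = FALSE)
  wtp * delta_qaly - delta_cost
}

#' Compare the two arms of a population bundle
#'
#' Runs both arms through the cohort engine and fills the incremental
#' statistics, with the toripalimab arm as the intervention and the
#' placebo (chemotherapy-alone) arm as the comparator.
#'
#' @inheritParams run_arm
#' @return An object of class `cea_result` with per-arm results,
#'   `delta_cost`, `delta_qaly`, `icer`, `nmb` at the settings' WTP and
#'   the cost-effectiveness `decision`.
#' @examples
#' compare_arms(builtin_choice01("ITT"))
#' @export
compare_arms <- function(spec, settings = model_settings(),
                         rule = OCCUPANCY_RULES) {
  rule <- match.arg(rule)
  arms <- lapply(stats::setNames(ARMS, ARMS), function(a) {
    run_arm(spec, a, settings, rule)
  })
  dc <- arms$toripalimab$total_cost - arms$placebo$total_cost
  de <- arms$toripalimab$total_qaly - arms$placebo$total_qaly
  nmb <- net_monetary_benefit(dc, de, settings$wtp_per_qaly)
  structure(
    list(population = spec$population,
         arms = arms,
         delta_cost = dc,
         delta_qaly = de,
         icer = icer(dc, de),
         nmb = nmb,
         decision = nmb > 0,
         wtp = settings$wtp_per_qaly,
         rule = rule,
         settings = settings),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  icer_txt <- if (is.numeric(x$icer)) sprintf("$%.0f/QALY", x$icer) else x$icer
  cat(sprintf(
    paste0("<cea_result> %s (%s rule)\n",
           "  toripalimab: $%.0f, %.3f QALYs | placebo: $%.0f, %.3f QALYs\n",
           "  delta cost $%.0f, delta QALYs %.3f, ICER %s\n",
           "  NMB at WTP $%.0f: $%.0f -> %scost-effective\n"),
    x$population, x$rule,
    x$arms$toripalimab$total_cost, x$arms$toripalimab$total_qaly,
    x$arms$placebo$total_cost, x$arms$placebo$total_qaly,
    x$delta_cost, x$delta_qaly, icer_txt,
    x$wtp, x$nmb, if (x$decision) "" else "not "
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cost-effectiveness result into a base-case table
#'
#' One row per arm and state-level quantity, mirroring the layout of a
#' published base-case table (state cost splits, totals, incrementals,
#' ICER).
#'
#' @param x A [compare_arms()] result.
#' @param ... Unused.
#' @return A tibble with columns `population`, `quantity`, `placebo`,
#'   `toripalimab`, `incremental`.
#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) {
  row <- function(quantity, f) {
    tibble::tibble(
      population = x$population, quantity = quantity,
      placebo = f(x$arms$placebo), toripalimab = f(x$arms$toripalimab),
      incremental = f(x$arms$toripalimab) - f(x$arms$placebo)
    )
  }
  dplyr::bind_rows(
    row("cost_pfs_state", function(a) a$cost_pfs),
    row("cost_pd_state", function(a) a$cost_pd),
    row("cost_total", function(a) a$total_cost),
    row("qaly_pfs_state", function(a) a$qaly_pfs),
    row("qaly_pd_state", function(a) a$qaly_pd),
    row("qaly_total", function(a) a$total_qaly)
  )
}

#' One-row summary of a cost-effectiveness result
#'
#' @inheritParams tidy.cea_result
#' @return A one-row tibble with the incrementals, ICER, NMB and decision.
#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    population = x$population,
    rule = x$rule,
    cost_placebo = x$arms$placebo$total_cost,
    cost_toripalimab = x$arms$toripalimab$total_cost,
    qaly_placebo = x$arms$placebo$total_qaly,
    qaly_toripalimab = x$arms$toripalimab$total_qaly,
    delta_cost = x$delta_cost,
    delta_qaly = x$delta_qaly,
    icer = if (is.numeric(x$icer)) x$icer else NA_real_,
    dominance = if (is.numeric(x$icer)) NA_character_ else x$icer,
    nmb = x$nmb,
    wtp = x$wtp,
    cost_effective = x$decision
  )
}

#' Reproduce the published base case across all populations
#'
#' Runs the packaged fixtures for the three study populations with the
#' survival models shared from the intention-to-treat fit (the variant the
#' published base-case table is numerically consistent with; see
#' [builtin_choice01()]) and returns one summary row per population.
#'
#' @param populations Populations to run.
#' @inheritParams run_arm
#' @return A tibble, one [glance.cea_result()] row per population.
#' @export
published_base_case <- function(populations = POPULATIONS,
                                settings = model_settings(),
                                rule = "progressive") {
  purrr::map_dfr(populations, function(pop) {
    spec <- builtin_choice01(pop, survival = "shared_itt")
    glance(compare_arms(spec, settings, rule))
  })
}
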