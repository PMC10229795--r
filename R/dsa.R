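# One-way deterministic sensitivity analysis and tornado ranking.

#' One-way (tornado) sensitivity analysis
#'
#' Varies each parameter alone to its low and high value, re-runs the
#' paired-arm comparison, and ranks parameters by the width of the
#' resulting ICER interval.
#'
#' Cost parameters are the fixture's `dsa_group`s (items sharing a group
#' are varied jointly, so e.g. every progression-free-state cost of the
#' combined arm moves as one "combined treatment cost" parameter, matching
#' how published tornado diagrams label arm-level treatment costs), varied
#' to base value times `1 - dsa_range_fraction` and `1 + dsa_range_fraction`.
#' Utilities are varied over the ranges stored in the [utility_set()]
#' (the printed +/-30% intervals), clipped to \[0, 1\] with a message if a
#' high value exceeds 1.
#'
#' @inheritParams run_arm
#' @param parameters Optional character vector restricting the sweep to a
#'   subset of parameter labels.
#' @return A tibble of class `tornado_tbl`, sorted by `spread` descending,
#'   with columns `parameter`, `low_value`, `high_value`, `icer_at_low`,
#'   `icer_at_high`, `spread`. The base-case ICER is in attribute
#'   `icer_base`. The ICER here is the plain incremental-cost over
#'   incremental-QALY ratio (it may turn negative if a variation makes the
#'   intervention cost-saving).
#' @examples
#' one_way(builtin_choice01("ITT"))
#' @export
one_way <- function(spec, settings = model_settings(), parameters = NULL,
                    rule = OCCUPANCY_RULES) {
  rule <- match.arg(rule)
  stopifnot(inherits(spec, "population_spec"))
  f <- settings$dsa_range_fraction
  base <- compare_arms(spec, settings, rule)
  icer_of <- function(s) {
    r <- compare_arms(s, settings, rule)
    r$delta_cost / r$delta_qaly
  }

  groups <- unique(spec$costs$dsa_group)
  all_params <- c(groups, "u_pfs", "u_pd")
  if (!is.null(parameters)) {
    if (length(parameters) == 0) {
      stop("empty parameter selection", call. = FALSE)
    }
    unknown <- setdiff(parameters, all_params)
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    all_params <- parameters
  }

  rows <- purrr::map_dfr(all_params, function(p) {
    if (p %in% groups) {
      sel <- spec$costs$dsa_group == p
      at <- function(mult) {
        s <- spec
        s$costs$base_value[sel] <- spec$costs$base_value[sel] * mult
        # keep low <= base <= high valid for the perturbed copy
        s$costs$low[sel] <- pmin(s$costs$low[sel], s$costs$base_value[sel])
        s$costs$high[sel] <- pmax(s$costs$high[sel], s$costs$base_value[sel])
        s
      }
      lo_val <- sum(spec$costs$base_value[sel]) * (1 - f)
      hi_val <- sum(spec$costs$base_value[sel]) * (1 + f)
      lo <- icer_of(at(1 - f))
      hi <- icer_of(at(1 + f))
    } else {
      u <- spec$utilities
      bounds <- if (p == "u_pfs") c(u$pfs_low, u$pfs_high) else c(u$pd_low, u$pd_high)
      if (bounds[2] > 1) {
        message("utility high for ", p, " clipped from ", bounds[2], " to 1")
        bounds[2] <- 1
      }
      bounds[1] <- max(bounds[1], 0)
      at <- function(value) {
        s <- spec
        s$utilities[[p]] <- value
        # preserve the ordering invariant for the perturbed copy
        if (s$utilities$u_pd > s$utilities$u_pfs) {
          if (p == "u_pd") s$utilities$u_pfs <- value else s$utilities$u_pd <- value
        }
        s
      }
      lo_val <- bounds[1]
      hi_val <- bounds[2]
      lo <- icer_of(at(bounds[1]))
      hi <- icer_of(at(bounds[2]))
    }
    tibble::tibble(parameter = p, low_value = lo_val, high_value = hi_val,
                   icer_at_low = lo, icer_at_high = hi,
                   spread = abs(hi - lo))
  })

  rows <- dplyr::arrange(rows, dplyr::desc(.data$spread))
  structure(rows,
            class = c("tornado_tbl", class(tibble::tibble())),
            icer_base = base$delta_cost / base$delta_qaly,
            population = spec$population)
}
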