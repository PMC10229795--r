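# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort trace
#'
#' Stacked state occupancy over time.
#'
#' @param object A [run_trace()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("occ_pfs", "occ_pd", "occ_dead"),
    names_to = "state", values_to = "occupancy"
  )
  long$state <- factor(long$state, levels = c("occ_dead", "occ_pd", "occ_pfs"),
                       labels = c("Dead", "Progressed", "Progression-free"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_years,
                                     y = .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Years", y = "Proportion of cohort", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars spanning each parameter's ICER interval, widest at the
#' top, with the base-case ICER marked.
#'
#' @param object A [one_way()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tornado_tbl
#' @export
autoplot.tornado_tbl <- function(object, ...) {
  base <- attr(object, "icer_base")
  df <- tibble::as_tibble(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_at_low, xend = .data$icer_at_high,
                   yend = .data$parameter),
      linewidth = 5, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL,
                  title = paste0("One-way sensitivity (",
                                 attr(object, "population"), ")")) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane scatter
#'
#' Incremental QALYs against incremental cost, one point per Monte Carlo
#' iteration, with the WTP threshold line.
#'
#' @param object A [run_psa()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, ...) {
  wtp <- object$summary$wtp
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost ($)",
                  title = sprintf("CE plane (%s), WTP $%s/QALY",
                                  object$summary$population,
                                  format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param object A [ceac()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ceac_tbl
#' @export
autoplot.ceac_tbl <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$wtp, y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}
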