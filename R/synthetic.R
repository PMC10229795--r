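# Seeded generators for everything the fitting stage consumes: Weibull
# event times with censoring, Kaplan-Meier estimates, and noisy
# digitized-coordinate emulation.

#' Simulate Weibull individual-patient data
#'
#' Event times are drawn by the inverse transform
#' `t = (-log U / lambda)^(1/gamma)`. Censoring is optional:
#' administrative (all subjects still at risk at `cens_time` are censored
#' there) or random exponential with rate `cens_rate`.
#'
#' @param n Number of subjects.
#' @param gamma,lambda Weibull shape and rate of the event-time
#'   distribution.
#' @param censoring `"none"`, `"administrative"`, or `"exponential"`.
#' @param cens_time Administrative censoring time.
#' @param cens_rate Exponential censoring rate.
#' @param seed Integer seed (required; generation is deterministic given
#'   the seed).
#' @return A tibble with columns `time` and `event`.
#' @examples
#' simulate_ipd(100, gamma = 1.4, lambda = 0.05, seed = 1)
#' @export
simulate_ipd <- function(n, gamma, lambda,
                         censoring = c("none", "administrative", "exponential"),
                         cens_time = NULL, cens_rate = NULL, seed) {
  censoring <- match.arg(censoring)
  stopifnot(n >= 1, gamma > 0, lambda > 0)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  t_event <- (-log(stats::runif(n)) / lambda)^(1 / gamma)
  if (censoring == "none") {
    return(tibble::tibble(time = t_event, event = rep(1, n)))
  }
  if (censoring == "administrative") {
    stopifnot(!is.null(cens_time), cens_time >= 0)
    t_cens <- rep(cens_time, n)
  } else {
    stopifnot(!is.null(cens_rate), cens_rate >= 0)
    t_cens <- if (cens_rate == 0) rep(Inf, n) else stats::rexp(n, cens_rate)
  }
  tibble::tibble(
    time = pmin(t_event, t_cens),
    event = as.numeric(t_event <= t_cens)
  )
}

#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator via [survival::survfit()], returned as
#' digitized-style coordinates (one row per distinct event time, plus the
#' origin at survival 1).
#'
#' @param ipd Data frame with `time` and `event` columns.
#' @return A tibble with columns `time`, `survival`, `n_risk`, `n_event`.
#' @export
km_estimate <- function(ipd) {
  stopifnot(is.data.frame(ipd), nrow(ipd) > 0,
            all(c("time", "event") %in% names(ipd)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  keep <- fit$n.event > 0
  tibble::tibble(
    time = c(0, fit$time[keep]),
    survival = c(1, fit$surv[keep]),
    n_risk = c(nrow(ipd), fit$n.risk[keep]),
    n_event = c(0, fit$n.event[keep])
  )
}

#' Emulate plot digitization of a survival curve
#'
#' Samples a (step) survival curve at the requested grid, applies
#' multiplicative noise `S * (1 + e)` with `e ~ N(0, noise_sd)`, then
#' re-monotonizes (running minimum) and clips to \[0, 1\] — mimicking the
#' error introduced when published curves are read off with digitizer
#' software.
#'
#' @param curve Data frame with `time` and `survival` columns (step
#'   coordinates, right-continuous).
#' @param grid Times at which to sample; must lie within the curve's
#'   support.
#' @param noise_sd Standard deviation of the multiplicative noise
#'   (fraction).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return A tibble with columns `time` and `survival`, non-increasing.
#' @export
digitize <- function(curve, grid, noise_sd = 0, seed = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("time", "survival") %in% names(curve)))
  if (any(grid < min(curve$time)) || any(grid > max(curve$time))) {
    stop("grid must lie within the curve's support", call. = FALSE)
  }
  step <- stats::stepfun(curve$time, c(1, curve$survival), right = FALSE)
  s <- step(grid)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0", call. = FALSE)
    set.seed(seed)
    s <- s * (1 + stats::rnorm(length(s), 0, noise_sd))
  }
  s <- pmin(pmax(cummin(s), 0), 1)
  tibble::tibble(time = grid, survival = s)
}
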