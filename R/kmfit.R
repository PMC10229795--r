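# Survival-curve-to-parameters stage: reconstruct pseudo individual
# patient data (IPD) from digitized Kaplan-Meier coordinates and fit
# Weibull accelerated-failure-time models.

#' Validate digitized Kaplan-Meier coordinates
#'
#' @param curve Data frame with numeric columns `time` and `survival`.
#' @return The curve as a tibble, invisibly validated: times strictly
#'   increasing and non-negative, survival within \[0, 1\] and
#'   non-increasing.
#' @export
as_digitized_curve <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("time", "survival") %in% names(curve)))
  curve <- tibble::as_tibble(curve[c("time", "survival")])
  if (any(curve$time < 0) || any(diff(curve$time) <= 0)) {
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(curve$survival < 0 | curve$survival > 1)) {
    stop("survival must be within [0, 1]", call. = FALSE)
  }
  if (any(diff(curve$survival) > 1e-12)) {
    stop("survival must be non-increasing", call. = FALSE)
  }
  curve
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Inverts the product-limit construction: walking the digitized
#' coordinates in order, the number of events in each interval is chosen
#' so that the Kaplan-Meier estimate of the output tracks the input curve
#' (a running-correction rounding keeps the cumulative drift below one
#' subject). Without a numbers-at-risk table no censoring is assumed
#' before the last coordinate; with one, the risk-table decrement not
#' explained by events is censored uniformly within the interval.
#' Survivors are administratively censored at the last coordinate.
#'
#' @param curve Digitized coordinates (see [as_digitized_curve()]).
#' @param initial_n Number of subjects at risk at time zero.
#' @param risk_table Optional data frame with columns `time` and
#'   `n_at_risk`.
#' @return A tibble with columns `time` and `event` (1 = event,
#'   0 = censored).
#' @export
reconstruct_ipd <- function(curve, initial_n, risk_table = NULL) {
  curve <- as_digitized_curve(curve)
  stopifnot(initial_n >= 1)
  if (curve$time[1] > 0) {
    curve <- dplyr::bind_rows(tibble::tibble(time = 0, survival = 1), curve)
  }
  if (curve$survival[1] != 1) {
    stop("curve must start at survival 1", call. = FALSE)
  }
  n_alive <- round(initial_n)
  s_hat <- 1
  times <- events <- numeric(0)
  for (i in seq_len(nrow(curve))[-1]) {
    target <- curve$survival[i]
    d <- 0
    if (n_alive > 0 && s_hat > 0 && target < s_hat) {
      d <- round(n_alive * (1 - target / s_hat))
      d <- min(d, n_alive)
      if (d > 0) {
        times <- c(times, rep(curve$time[i], d))
        events <- c(events, rep(1, d))
        s_hat <- s_hat * (1 - d / n_alive)
        n_alive <- n_alive - d
      }
    }
    if (!is.null(risk_table)) {
      nxt <- risk_table$n_at_risk[risk_table$time > curve$time[i] - 1e-9]
      if (length(nxt)) {
        n_target <- nxt[1]
        n_censor <- max(0, n_alive - n_target)
        if (n_censor > 0) {
          upper <- if (i < nrow(curve)) curve$time[i + 1] else curve$time[i]
          ct <- seq(curve$time[i], upper, length.out = n_censor + 2)
          ct <- ct[-c(1, n_censor + 2)]
          times <- c(times, ct)
          events <- c(events, rep(0, n_censor))
          n_alive <- n_alive - n_censor
        }
      }
    }
  }
  if (n_alive > 0) {
    times <- c(times, rep(max(curve$time), n_alive))
    events <- c(events, rep(0, n_alive))
  }
  dplyr::arrange(tibble::tibble(time = times, event = events), .data$time,
                 dplyr::desc(.data$event))
}

#' Least-squares Weibull fit on the log cumulative-hazard scale
#'
#' Ordinary least squares of `log(-log S)` on `log t` over the points with
#' survival strictly inside (0, 1): the slope estimates the shape `gamma`
#' and the intercept estimates `log lambda`. Exact Weibull points are
#' recovered to machine precision because the linearization is exact.
#'
#' @param curve Points with columns `time` and `survival`.
#' @return An object of class `weibull_fit` with elements `params`
#'   ([weibull_params()]), `r_squared`, `n_points` and `method = "ls"`.
#' @export
fit_weibull_ls <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("time", "survival") %in% names(curve)))
  usable <- curve$survival > 0 & curve$survival < 1 & curve$time > 0
  if (sum(usable) < 3) {
    stop("need at least 3 points with 0 < survival < 1", call. = FALSE)
  }
  x <- log(curve$time[usable])
  y <- log(-log(curve$survival[usable]))
  fit <- stats::lm(y ~ x)
  gamma <- unname(stats::coef(fit)[2])
  lambda <- exp(unname(stats::coef(fit)[1]))
  # summary.lm warns on exact fits; exact Weibull points are a legitimate
  # input here (the linearization is exact), so an R^2 of 1 is fine
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(params = weibull_params(gamma = gamma, lambda = lambda),
         r_squared = r2,
         n_points = sum(usable),
         method = "ls"),
    class = "weibull_fit"
  )
}

#' Maximum-likelihood Weibull fit on (possibly censored) survival records
#'
#' Fits the Weibull accelerated-failure-time model by maximum likelihood
#' via [survival::survreg()] and reports both the AFT form (intercept,
#' log scale) and the shape/rate form. Requires at least one event.
#'
#' @param ipd Data frame with columns `time` (> 0) and `event` (1 = event,
#'   0 = censored).
#' @return An object of class `weibull_fit` with elements `params`,
#'   `loglik`, `n`, `n_events` and `method = "mle"`.
#' @export
fit_weibull_mle <- function(ipd) {
  stopifnot(is.data.frame(ipd), all(c("time", "event") %in% names(ipd)))
  if (sum(ipd$event) < 1) {
    stop("need at least one event to fit", call. = FALSE)
  }
  if (any(ipd$time <= 0)) {
    # survreg requires strictly positive times; nudge exact zeros
    ipd$time <- pmax(ipd$time, .Machine$double.eps)
  }
  fit <- survival::survreg(survival::Surv(time, event) ~ 1, data = ipd,
                           dist = "weibull")
  intercept <- unname(stats::coef(fit)[1])
  log_scale <- log(fit$scale)
  structure(
    list(params = weibull_params(intercept = intercept,
                                 log_scale = log_scale),
         loglik = fit$loglik[1],
         n = nrow(ipd),
         n_events = sum(ipd$event),
         method = "mle"),
    class = "weibull_fit"
  )
}

#' Censored Weibull log-likelihood
#'
#' `sum over events of log(lambda gamma t^(gamma-1)) - lambda t^gamma`
#' plus `sum over censored of -lambda t^gamma`. Used as an independent
#' check that the fitted parameters sit at a stationary point.
#'
#' @param p A [weibull_params()] object.
#' @param ipd Data frame with `time` and `event` columns.
#' @return Log-likelihood value.
#' @export
weibull_loglik <- function(p, ipd) {
  stopifnot(inherits(p, "weibull_params"))
  t <- ipd$time
  d <- ipd$event
  sum(d * (log(p$lambda * p$gamma) + (p$gamma - 1) * log(t))) -
    sum(p$lambda * t^p$gamma)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> (%s) gamma = %.4g, lambda = %.4g", x$method,
              x$params$gamma, x$params$lambda))
  if (x$method == "ls") cat(sprintf(", R^2 = %.4f", x$r_squared))
  if (x$method == "mle") cat(sprintf(", loglik = %.2f", x$loglik))
  cat("\n")
  invisible(x)
}

#' @method tidy weibull_fit
#' @export
tidy.weibull_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("intercept", "log_scale", "gamma", "lambda"),
    estimate = c(p$intercept, p$log_scale, p$gamma, p$lambda)
  )
}

#' @method glance weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    gamma = x$params$gamma,
    lambda = x$params$lambda,
    r_squared = if (x$method == "ls") x$r_squared else NA_real_,
    loglik = if (x$method == "mle") x$loglik else NA_real_,
    nobs = if (x$method == "mle") x$n else x$n_points
  )
}
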