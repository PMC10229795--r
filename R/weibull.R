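# Weibull accelerated-failure-time survival mathematics.
#
# Parameterization: S(t) = exp(-lambda * t^gamma), with the AFT form
# (location `intercept` on log-time, scale exp(`log_scale`)) related by
# gamma = exp(-log_scale) and lambda = exp(-gamma * intercept).

#' @keywords internal
DAYS_PER_MONTH <- 30.4375

#' @keywords internal
DAYS_PER_YEAR <- 365.25

#' Weibull survival parameters
#'
#' Container for one Weibull survival model in both the
#' accelerated-failure-time (AFT) parameterization (location `intercept` on
#' log time, `log_scale`) and the equivalent proportional-hazards form
#' (`gamma` shape, `lambda` rate), with a declared time unit. Either pair
#' may be supplied; the other is derived. When both are supplied they must
#' agree to 1e-6 relative tolerance.
#'
#' @param intercept AFT location (log-time).
#' @param log_scale AFT log of scale.
#' @param gamma Shape parameter (> 0, dimensionless).
#' @param lambda Rate parameter (> 0, time^-gamma).
#' @param time_unit Label for the time unit of `t` ("months" by default;
#'   one 3-week model cycle is 21/30.4375 months).
#' @return An object of class `weibull_params`.
#' @examples
#' weibull_params(intercept = 3.119, log_scale = -0.539)
#' weibull_params(gamma = 1, lambda = 0.1)
#' @export
weibull_params <- function(intercept = NULL, log_scale = NULL,
                           gamma = NULL, lambda = NULL,
                           time_unit = "months") {
  have_aft <- !is.null(intercept) && !is.null(log_scale)
  have_ph  <- !is.null(gamma) && !is.null(lambda)
  if (!have_aft && !have_ph) {
    stop("supply either (intercept, log_scale) or (gamma, lambda)", call. = FALSE)
  }
  if (have_aft) {
    if (!is.finite(intercept) || !is.finite(log_scale)) {
      stop("intercept and log_scale must be finite", call. = FALSE)
    }
    g <- exp(-log_scale)
    l <- exp(-g * intercept)
    if (have_ph) {
      if (abs(g - gamma) > 1e-6 * max(1, abs(gamma)) ||
          abs(l - lambda) > 1e-6 * max(1, abs(lambda))) {
        stop("gamma/lambda inconsistent with intercept/log_scale ",
             "(derived ", signif(g, 7), ", ", signif(l, 7), ")", call. = FALSE)
      }
    }
    gamma <- g
    lambda <- l
  } else {
    if (!is.finite(gamma) || !is.finite(lambda) || gamma <= 0 || lambda <= 0) {
      stop("gamma and lambda must be finite and positive", call. = FALSE)
    }
    log_scale <- -log(gamma)
    intercept <- -log(lambda) / gamma
  }
  if (gamma <= 0 || lambda <= 0) {
    stop("gamma and lambda must be positive", call. = FALSE)
  }
  structure(
    list(intercept = intercept, log_scale = log_scale,
         gamma = gamma, lambda = lambda, time_unit = time_unit),
    class = "weibull_params"
  )
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf(
    "<weibull_params> gamma = %.4g, lambda = %.4g (intercept = %.4g, log_scale = %.4g, %s)\n",
    x$gamma, x$lambda, x$intercept, x$log_scale, x$time_unit
  ))
  invisible(x)
}

#' Convert AFT location/log-scale to shape/rate form
#'
#' `gamma = exp(-log_scale)`, `lambda = exp(-gamma * intercept)`. This is
#' the identity that links the survival-regression output (location on log
#' time and log of scale) to the `S(t) = exp(-lambda t^gamma)` form used by
#' the cohort model.
#'
#' @inheritParams weibull_params
#' @return A `weibull_params` object.
#' @examples
#' aft_to_weibull(3.119, -0.539)  # gamma 1.714, lambda 0.005
#' aft_to_weibull(0, 0)           # unit-rate exponential
#' @export
aft_to_weibull <- function(intercept, log_scale, time_unit = "months") {
  weibull_params(intercept = intercept, log_scale = log_scale,
                 time_unit = time_unit)
}

#' Weibull survival function
#'
#' @param p A [weibull_params()] object.
#' @param t Non-negative times (in `p$time_unit`).
#' @return `exp(-lambda * t^gamma)`, a probability in \[0, 1\].
#' @examples
#' p <- weibull_params(gamma = 1, lambda = 0.1)
#' weibull_survival(p, 10)  # exp(-1)
#' @export
weibull_survival <- function(p, t) {
  stopifnot(inherits(p, "weibull_params"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  exp(-p$lambda * t^p$gamma)
}

#' Median survival time
#'
#' Closed form `(log(2) / lambda)^(1/gamma)`; satisfies
#' `weibull_survival(p, weibull_median(p)) == 0.5`.
#'
#' @inheritParams weibull_survival
#' @return Median time in the model's time unit.
#' @export
weibull_median <- function(p) {
  stopifnot(inherits(p, "weibull_params"))
  (log(2) / p$lambda)^(1 / p$gamma)
}

#' Mean (restricted mean) survival time
#'
#' Uncapped: `lambda^(-1/gamma) * Gamma(1 + 1/gamma)`. With `cap`, the
#' restricted mean computed as the trapezoidal integral of S(t) over
#' `[0, cap]` at step `step`.
#'
#' @inheritParams weibull_survival
#' @param cap Optional upper limit of integration (same time unit).
#' @param step Grid step for the capped integral; defaults to one model
#'   cycle (21 days) expressed in months.
#' @return Mean time in the model's time unit.
#' @examples
#' weibull_mean(weibull_params(gamma = 1, lambda = 0.1))  # 10
#' @export
weibull_mean <- function(p, cap = NULL, step = 21 / DAYS_PER_MONTH) {
  stopifnot(inherits(p, "weibull_params"))
  if (is.null(cap)) {
    return(p$lambda^(-1 / p$gamma) * gamma(1 + 1 / p$gamma))
  }
  if (cap < 0) stop("cap must be non-negative", call. = FALSE)
  if (cap == 0) return(0)
  grid <- unique(c(seq(0, cap, by = step), cap))
  s <- weibull_survival(p, grid)
  sum(diff(grid) * (utils::head(s, -1) + utils::tail(s, -1)) / 2)
}

#' Survival probabilities on the model's cycle grid
#'
#' Evaluates S at the cycle boundaries `t_k = k * cycle_days` (converted to
#' the parameters' time unit) for `k = 0, ..., N`.
#'
#' @inheritParams weibull_survival
#' @param settings A [model_settings()] object.
#' @return A tibble with columns `cycle`, `time` (months), `time_years`,
#'   and `surv`.
#' @export
survival_grid <- function(p, settings = model_settings()) {
  stopifnot(inherits(p, "weibull_params"))
  n <- n_cycles(settings)
  k <- 0:n
  t_unit <- k * settings$cycle_days / DAYS_PER_MONTH
  tibble::tibble(
    cycle = k,
    time = t_unit,
    time_years = k * settings$cycle_days / DAYS_PER_YEAR,
    surv = weibull_survival(p, t_unit)
  )
}
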