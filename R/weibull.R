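#' Weibull survival parameters
#'
#' Parameter set for the two-parameter Weibull survival function
#' `S(t) = exp(-lambda * t^gamma)` with `lambda = exp(log_lambda)`.
#' `gamma` (shape) governs whether the hazard rises (`gamma > 1`) or
#' falls (`gamma < 1`) with time; `lambda` (scale) sets the time metric
#' and carries units of `day^-gamma`.
#'
#' @param gamma Shape, dimensionless, `> 0`.
#' @param log_lambda Natural log of the scale `lambda` (time in days).
#' @param fit_r2 Optional adjusted R-squared of a linearised fit, in `[0, 1]`.
#' @param fit_corr Optional correlation coefficient of the fit, in `[0, 1]`.
#' @param n_used,n_dropped Optional point counts from [fit_weibull_km()].
#'
#' @return An object of class `weibull_params`.
#' @export
#' @examples
#' weibull_params(gamma = 0.9359, log_lambda = -5.0757)
weibull_params <- function(gamma, log_lambda, fit_r2 = NA_real_,
                           fit_corr = NA_real_, n_used = NA_integer_,
                           n_dropped = NA_integer_) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L,
            is.numeric(log_lambda), length(log_lambda) == 1L)
  if (!is.finite(gamma) || gamma <= 0) {
    stop("`gamma` (Weibull shape) must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(log_lambda)) stop("`log_lambda` must be finite", call. = FALSE)
  for (v in c(fit_r2, fit_corr)) {
    if (!is.na(v) && (v < 0 || v > 1)) {
      stop("fit statistics must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(gamma = gamma, log_lambda = log_lambda, fit_r2 = fit_r2,
         fit_corr = fit_corr, n_used = n_used, n_dropped = n_dropped),
    class = "weibull_params"
  )
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull survival parameters: gamma = %.4f, ln(lambda) = %.4f\n",
              x$gamma, x$log_lambda))
  if (!is.na(x$fit_r2)) {
    cat(sprintf("  linearised fit: adj. R^2 = %.4f, corr = %.4f (%d points used, %d dropped)\n",
                x$fit_r2, x$fit_corr, x$n_used, x$n_dropped))
  }
  invisible(x)
}

#' Fit a Weibull survival function to Kaplan-Meier points
#'
#' Linearised least-squares fit: for Weibull survival,
#' `ln(-ln S(t)) = gamma * ln(t) + ln(lambda)`, so an ordinary linear
#' regression of the double-log-transformed survival on `ln(t)` yields
#' the shape as its slope and the log-scale as its intercept. Points
#' with `S >= 1` or `S <= 0` (or `t <= 0`), where the transform is
#' undefined, are excluded with a message.
#'
#' @param curve A [km_curve()] with at least 3 usable points.
#' @return A [weibull_params()] with `fit_r2` (adjusted R-squared) and
#'   `fit_corr` computed on the transformed scale.
#' @export
#' @examples
#' t <- seq(10, 200, by = 10)
#' fit_weibull_km(km_curve(t, exp(-0.01 * t)))  # recovers gamma = 1
fit_weibull_km <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  usable <- curve$time_days > 0 & curve$survival > 0 & curve$survival < 1
  n_dropped <- sum(!usable)
  if (n_dropped > 0L) {
    message(sprintf("fit_weibull_km: excluded %d point(s) with S in {0, 1} or t = 0",
                    n_dropped))
  }
  t <- curve$time_days[usable]
  s <- curve$survival[usable]
  if (length(t) < 3L) {
    stop(sprintf("Weibull fit needs at least 3 usable points with 0 < S < 1 (got %d)",
                 length(t)), call. = FALSE)
  }
  x <- log(t)
  y <- log(-log(s))
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  if (co[["x"]] <= 0) {
    stop("fitted shape is non-positive; the points are not Weibull-decreasing",
         call. = FALSE)
  }
  weibull_params(
    gamma = unname(co[["x"]]),
    log_lambda = unname(co[["(Intercept)"]]),
    fit_r2 = suppressWarnings(summary(fit))$adj.r.squared,
    fit_corr = abs(stats::cor(x, y)),
    n_used = length(t),
    n_dropped = n_dropped
  )
}

#' Weibull survival function
#'
#' `S(t) = exp(-exp(log_lambda) * t^gamma)`, with `t` in days.
#'
#' @param params A [weibull_params()].
#' @param t Non-negative time(s) in days.
#' @return Survival probabilities in `(0, 1]`; `S(0) = 1`.
#' @export
weibull_survival <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  exp(-exp(params$log_lambda) * t^params$gamma)
}

#' Closed-form Weibull median survival time
#'
#' `(ln 2 / lambda)^(1/gamma)` in days.
#'
#' @param params A [weibull_params()].
#' @export
weibull_median <- function(params) {
  stopifnot(inherits(params, "weibull_params"))
  (log(2) / exp(params$log_lambda))^(1 / params$gamma)
}

#' Time-dependent per-cycle transition probability
#'
#' Converts a Weibull survival curve (day scale) into the conditional
#' probability of leaving the state during cycle `t`:
#' `P(t) = 1 - exp(lambda_c * ((t-1)^gamma - t^gamma))` with
#' `lambda_c = lambda * cycle_length^gamma`, i.e. the scale rescaled to
#' cycle units. This equals the conditional failure probability
#' `(S((t-1)c) - S(tc)) / S((t-1)c)`. For `gamma > 1` the sequence is
#' increasing in `t` (rising hazard).
#'
#' @param params A [weibull_params()].
#' @param cycle Integer cycle index/indices, `>= 1`.
#' @param cycle_length Cycle length in days (default 21).
#' @return Probabilities in `[0, 1]`, one per cycle index.
#' @export
#' @examples
#' p <- weibull_params(gamma = 0.9359, log_lambda = -5.0757)
#' cycle_transition_prob(p, 1)  # ~0.1022
cycle_transition_prob <- function(params, cycle, cycle_length = 21) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(cycle < 1) || any(cycle != floor(cycle))) {
    stop("`cycle` must be integer(s) >= 1", call. = FALSE)
  }
  if (cycle_length <= 0) stop("`cycle_length` must be positive", call. = FALSE)
  lambda_c <- exp(params$log_lambda) * cycle_length^params$gamma
  p <- 1 - exp(lambda_c * ((cycle - 1)^params$gamma - cycle^params$gamma))
  pmin(pmax(p, 0), 1)
}
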