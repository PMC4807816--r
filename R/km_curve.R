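#' Kaplan-Meier curve points
#'
#' Container for an empirical survival function given as step points
#' `(time, survival probability)`, e.g. values read off a published
#' Kaplan-Meier plot or produced by [km_estimate()].
#'
#' @param times Numeric vector of non-negative times in days, strictly
#'   increasing.
#' @param survival Numeric vector of survival probabilities in `[0, 1]`,
#'   non-increasing in time. If a time of 0 is present its survival must
#'   be 1.
#' @param n_at_risk Optional integer vector of risk-set sizes.
#'
#' @return An object of class `km_curve`: a data frame with columns
#'   `time_days` and `survival` (and `n_at_risk` when supplied).
#' @seealso [fit_weibull_km()], [read_km_csv()], [resample_km()]
#' @export
#' @examples
#' km_curve(c(0, 30, 60), c(1, 0.8, 0.55))
km_curve <- function(times, survival, n_at_risk = NULL) {
  stopifnot(is.numeric(times), is.numeric(survival))
  if (length(times) != length(survival)) {
    stop("`times` and `survival` must have equal length", call. = FALSE)
  }
  if (length(times) < 1L) stop("a km_curve needs at least one point", call. = FALSE)
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (any(survival < 0 | survival > 1)) {
    stop("`survival` must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(survival) > 1e-12)) {
    stop("`survival` must be non-increasing in time", call. = FALSE)
  }
  if (times[1L] == 0 && abs(survival[1L] - 1) > 1e-12) {
    stop("survival at time 0 must be 1", call. = FALSE)
  }
  out <- data.frame(time_days = as.numeric(times), survival = as.numeric(survival))
  if (!is.null(n_at_risk)) {
    stopifnot(length(n_at_risk) == length(times))
    out$n_at_risk <- as.integer(n_at_risk)
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d points, t in [%g, %g] days, S in [%.3f, %.3f]\n",
              nrow(x), min(x$time_days), max(x$time_days),
              min(x$survival), max(x$survival)))
  invisible(x)
}

#' Read / write Kaplan-Meier curve points as CSV
#'
#' The on-disk format is a two-column CSV `time_days,survival` with a
#' header row (an optional `n_at_risk` column is preserved).
#'
#' @param path Path to a CSV file.
#' @export
read_km_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_days", "survival") %in% names(df))) {
    stop("KM CSV must have columns `time_days` and `survival`", call. = FALSE)
  }
  km_curve(df$time_days, df$survival,
           n_at_risk = if ("n_at_risk" %in% names(df)) df$n_at_risk)
}

#' @rdname read_km_csv
#' @param curve A [km_curve()].
#' @export
write_km_csv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Resample a Kaplan-Meier step function onto a time grid
#'
#' Evaluates the right-continuous step function at the requested times
#' (value of the last step at or before each time). Times before the
#' first step take survival 1. Used to mimic reading a published curve
#' off at cycle boundaries before parametric fitting.
#'
#' @param curve A [km_curve()].
#' @param times Numeric vector of times (days) to sample at.
#' @return A [km_curve()] on the new grid.
#' @export
resample_km <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  times <- sort(unique(as.numeric(times)))
  idx <- findInterval(times, curve$time_days)
  s <- ifelse(idx == 0L, 1, curve$survival[pmax(idx, 1L)])
  km_curve(times, s)
}
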