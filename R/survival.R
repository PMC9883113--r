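#' Weibull survival model in the rate parameterization
#'
#' Constructs a Weibull survival function `S(t) = exp(-rate * t^shape)`.
#' This is the "rate" (proportional-hazards) parameterization: `rate` plays
#' the role of lambda and `shape` the role of gamma in the transition
#' probability formula used by the Markov engine. `shape > 1` gives an
#' increasing hazard, `shape < 1` a decreasing one, `shape = 1` the
#' exponential special case.
#'
#' @param rate Scale-like rate parameter lambda, strictly positive or zero
#'   (zero encodes a no-event pathway). Units: per year^shape.
#' @param shape Dimensionless shape parameter gamma, strictly positive.
#' @return An object of class `weibull_survival`.
#' @seealso [weibull_from_scale()] to convert from the accelerated-failure
#'   scale parameterization `S(t) = exp(-(t/scale)^shape)`.
#' @export
#' @examples
#' m <- weibull_survival(rate = 0.03487, shape = 1)
#' survival_at(m, 5)
weibull_survival <- function(rate, shape) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (rate < 0) stop("'rate' must be >= 0", call. = FALSE)
  if (shape <= 0) stop("'shape' must be > 0", call. = FALSE)
  structure(list(rate = rate, shape = shape), class = "weibull_survival")
}

#' @export
print.weibull_survival <- function(x, ...) {
  cat(sprintf("Weibull survival: S(t) = exp(-%.6g * t^%.6g)\n", x$rate, x$shape))
  invisible(x)
}

#' Convert a scale-parameterized Weibull to the rate parameterization
#'
#' `S(t) = exp(-(t/scale)^shape)` is equivalent to
#' `S(t) = exp(-rate * t^shape)` with `rate = scale^(-shape)`.
#'
#' @param scale Positive scale parameter (years).
#' @param shape Positive shape parameter.
#' @return A [weibull_survival()] object.
#' @export
weibull_from_scale <- function(scale, shape) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  weibull_survival(rate = scale^(-shape), shape = shape)
}

#' Survival probability at time t
#'
#' @param model A [weibull_survival()] object.
#' @param t Non-negative time(s) in years; vectorized.
#' @return `exp(-rate * t^shape)`, with `survival_at(model, 0) == 1`.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "weibull_survival"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  exp(-model$rate * t^model$shape)
}

#' Per-cycle transition probability from a Weibull survival model
#'
#' The probability of the event occurring between cycle `t` and cycle
#' `t + 1`, conditional on being event-free at `t`:
#' `1 - exp(rate * t^shape - rate * (t+1)^shape) = 1 - S(t+1)/S(t)`.
#' `t` is a cycle index in the model's time unit; callers using cycles
#' shorter than one time unit should rescale times before calling (the
#' Markov engine uses [conditional_event_prob()] for that).
#'
#' @param model A [weibull_survival()] object.
#' @param t Non-negative cycle index (vectorized).
#' @return Probability in `[0, 1)`.
#' @export
transition_probability <- function(model, t) {
  stopifnot(inherits(model, "weibull_survival"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  1 - exp(model$rate * t^model$shape - model$rate * (t + 1)^model$shape)
}

#' Conditional event probability over an arbitrary interval
#'
#' `1 - S(t1)/S(t0)`: probability of the event in `(t0, t1]` given
#' event-free at `t0`. This is [transition_probability()] generalized to
#' non-unit cycle lengths.
#'
#' @param model A [weibull_survival()] object.
#' @param t0,t1 Interval endpoints in years, `0 <= t0 <= t1`.
#' @return Probability in `[0, 1)`.
#' @export
conditional_event_prob <- function(model, t0, t1) {
  stopifnot(inherits(model, "weibull_survival"), is.numeric(t0),
            is.numeric(t1))
  if (any(t0 < 0) || any(t1 < t0)) {
    stop("need 0 <= t0 <= t1", call. = FALSE)
  }
  # exponent form stays finite even where S(t0) underflows to 0
  1 - exp(model$rate * (t0^model$shape - t1^model$shape))
}

#' Kaplan-Meier curve container
#'
#' An ordered set of (time, survival) points, optionally with numbers at
#' risk, as produced by digitizing a published curve or by
#' [km_from_times()].
#'
#' @param time Strictly increasing non-negative times (years).
#' @param survival Non-increasing survival probabilities in `[0, 1]`.
#' @param n_at_risk Optional numbers at risk at each time.
#' @param n_events Optional event counts at each time.
#' @return An object of class `km_curve` (a data frame with columns
#'   `time`, `survival`, and optionally `n_at_risk` and `n_events`).
#' @export
km_curve <- function(time, survival, n_at_risk = NULL, n_events = NULL) {
  stopifnot(is.numeric(time), is.numeric(survival),
            length(time) == length(survival), length(time) >= 1L)
  if (any(time < 0)) stop("times must be >= 0", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(survival < 0 | survival > 1)) {
    stop("survival must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(survival) > 1e-12)) {
    stop("survival must be non-increasing in time", call. = FALSE)
  }
  if (time[1] == 0 && abs(survival[1] - 1) > 1e-12) {
    stop("survival at time 0 must equal 1", call. = FALSE)
  }
  df <- data.frame(time = time, survival = survival)
  if (!is.null(n_at_risk)) {
    stopifnot(length(n_at_risk) == length(time))
    df$n_at_risk <- n_at_risk
  }
  if (!is.null(n_events)) {
    stopifnot(length(n_events) == length(time))
    df$n_events <- n_events
  }
  structure(df, class = c("km_curve", "data.frame"))
}

#' Read a Kaplan-Meier curve from CSV
#'
#' Expects columns `time_years`, `survival`, and optionally `n_at_risk`.
#'
#' @param path CSV file path.
#' @return A [km_curve()].
#' @export
read_km_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  required <- c("time_years", "survival")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("KM CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  km_curve(df$time_years, df$survival,
           n_at_risk = if ("n_at_risk" %in% names(df)) df$n_at_risk else NULL,
           n_events = if ("n_events" %in% names(df)) df$n_events else NULL)
}

#' Write a Kaplan-Meier curve to CSV
#'
#' @param curve A [km_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  out <- data.frame(time_years = curve$time, survival = curve$survival)
  if (!is.null(curve$n_at_risk)) out$n_at_risk <- curve$n_at_risk
  if (!is.null(curve$n_events)) out$n_events <- curve$n_events
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Fit a Weibull survival model to Kaplan-Meier points
#'
#' Least squares on the complementary log-log linearization
#' `ln(-ln S) = ln(rate) + shape * ln(t)`. Points with `survival` equal to
#' 0 or 1, or with `time = 0`, carry no information under the
#' linearization and are dropped with a warning. When the curve carries
#' numbers at risk, points are weighted by the inverse Greenwood variance
#' of `ln(-ln S)` — late points estimated from few subjects then stop
#' dominating the fit; digitized curves without risk counts fall back to
#' ordinary least squares.
#'
#' @param curve A [km_curve()].
#' @return A list of class `weibull_fit` with elements `model`
#'   (a [weibull_survival()]), `r_squared`, `residuals`, and `n_used`.
#' @export
fit_weibull <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  usable <- curve$time > 0 & curve$survival > 0 & curve$survival < 1
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with survival 0/1 or time 0 dropped from fit",
            call. = FALSE)
  }
  t <- curve$time[usable]
  s <- curve$survival[usable]
  if (length(t) < 2L) {
    stop("insufficient data: need >= 2 points with 0 < survival < 1 and time > 0",
         call. = FALSE)
  }
  y <- log(-log(s))
  x <- log(t)
  w <- NULL
  if (!is.null(curve$n_at_risk)) {
    n <- curve$n_at_risk[usable]
    d <- if (!is.null(curve$n_events)) curve$n_events[usable] else rep(1, length(n))
    denom <- n * (n - d)
    if (all(denom > 0)) {
      # Greenwood variance of S, delta-method transformed to log(-log S)
      gw <- cumsum(d / denom)
      w <- (log(s))^2 / gw
    }
  }
  fit <- stats::lm(y ~ x, weights = w)
  coefs <- stats::coef(fit)
  model <- weibull_survival(rate = exp(unname(coefs[1])),
                            shape = unname(coefs[2]))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(model = model,
                 r_squared = r2,
                 residuals = unname(stats::residuals(fit)),
                 n_used = length(t)),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  fitted on %d points, R^2 = %.5f\n", x$n_used, x$r_squared))
  invisible(x)
}

#' Calibrate a Weibull survival model to two milestone survivals
#'
#' Solves `rate * t1^shape = -ln S1` and `rate * t2^shape = -ln S2`
#' exactly:
#' `shape = ln(ln S1 / ln S2) / ln(t1 / t2)`, `rate = -ln(S1) / t1^shape`.
#' Used to anchor transition pathways on published milestone survival
#' probabilities when the underlying curves are unavailable.
#'
#' @param times Two distinct positive times (years).
#' @param survivals Two survival probabilities in `(0, 1)`, strictly
#'   decreasing when times increase.
#' @return A [weibull_survival()] reproducing both milestones exactly.
#' @export
#' @examples
#' m <- calibrate_weibull(c(5, 15), c(0.84, 0.60))
#' survival_at(m, c(5, 15))
calibrate_weibull <- function(times, survivals) {
  stopifnot(length(times) == 2L, length(survivals) == 2L,
            is.numeric(times), is.numeric(survivals))
  if (any(times <= 0)) stop("milestone times must be > 0", call. = FALSE)
  if (any(survivals <= 0 | survivals >= 1)) {
    stop("milestone survivals must lie strictly in (0, 1)", call. = FALSE)
  }
  if (times[1] == times[2]) {
    stop("calibration error: milestone times must be distinct", call. = FALSE)
  }
  ord <- order(times)
  t <- times[ord]; s <- survivals[ord]
  if (s[2] >= s[1]) {
    stop("calibration error: survival must strictly decrease with time",
         call. = FALSE)
  }
  shape <- log(log(s[1]) / log(s[2])) / log(t[1] / t[2])
  rate <- -log(s[1]) / t[1]^shape
  weibull_survival(rate = rate, shape = shape)
}
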