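#' Beta shape parameters from a mean and a printed range
#'
#' Published parameter tables give a mean and a (low-high) range; the
#' range is read as an approximate 95% interval, so
#' `SE = (high - low) / 3.92`, and the beta shapes follow by method of
#' moments: `alpha = mean * (mean(1-mean)/SE^2 - 1)`,
#' `beta = (1-mean) * (mean(1-mean)/SE^2 - 1)`. The resulting
#' distribution reproduces the input mean exactly.
#'
#' @param mean Mean in `(0, 1)`.
#' @param low,high Range bounds with `low < high`.
#' @param range_divisor Divisor converting the range width to an SE;
#'   default 3.92 (95% normal interval). Alternatives in use: 4, 2*sqrt(3)
#'   (uniform).
#' @return List with `alpha`, `beta`, `se`.
#' @export
#' @examples
#' beta_from_mean_range(0.74, 0.592, 0.888)
beta_from_mean_range <- function(mean, low, high, range_divisor = 3.92) {
  stopifnot(is.numeric(mean), is.numeric(low), is.numeric(high))
  if (mean <= 0 || mean >= 1) stop("'mean' must lie in (0, 1)", call. = FALSE)
  if (low >= high) stop("need low < high", call. = FALSE)
  se <- (high - low) / range_divisor
  v <- mean * (1 - mean)
  if (se^2 >= v) {
    stop("infeasible moments: SE^2 = ", signif(se^2, 4),
         " must be < mean(1-mean) = ", signif(v, 4), call. = FALSE)
  }
  nu <- v / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu, se = se)
}

#' Gamma shape and scale from a mean and a printed range
#'
#' `SE = (high - low) / 3.92`; `shape = mean^2 / SE^2`,
#' `scale = SE^2 / mean`. The distribution mean equals the input mean
#' exactly and its variance equals `SE^2`.
#'
#' @param mean Positive mean (USD for cost parameters).
#' @param low,high Range bounds with `low < high`.
#' @param range_divisor As in [beta_from_mean_range()].
#' @return List with `shape`, `scale`, `se`.
#' @export
gamma_from_mean_range <- function(mean, low, high, range_divisor = 3.92) {
  stopifnot(is.numeric(mean), is.numeric(low), is.numeric(high))
  if (mean <= 0) stop("domain error: 'mean' must be > 0", call. = FALSE)
  if (low >= high) stop("need low < high", call. = FALSE)
  se <- (high - low) / range_divisor
  list(shape = mean^2 / se^2, scale = se^2 / mean, se = se)
}

#' Sample one PSA draw of every registered parameter
#'
#' Beta-family parameters are drawn from the method-of-moments beta (and
#' so lie in `[0, 1]` by construction); gamma-family parameters from the
#' method-of-moments gamma; `fixed` parameters and degenerate ranges stay
#' at base. One call produces one coherent draw applied to both arms, so
#' parameters shared between arms (unit costs, `u_ps`, the discount rate)
#' are perfectly correlated across arms, while arm-specific utilities
#' (`u_ffs_crt`, `u_ffs_uhrt`) are independent because they are separate
#' registry entries.
#'
#' @param parameters Named list of [parameter_spec()].
#' @param range_divisor As in [beta_from_mean_range()].
#' @return Named numeric vector of sampled values.
#' @keywords internal
sample_parameter_draw <- function(parameters, range_divisor = 3.92) {
  vapply(parameters, function(p) {
    if (p$dist == "fixed" || p$high <= p$low) return(p$base)
    if (p$dist == "beta") {
      sh <- beta_from_mean_range(p$base, p$low, p$high, range_divisor)
      stats::rbeta(1, sh$alpha, sh$beta)
    } else {
      sh <- gamma_from_mean_range(p$base, p$low, p$high, range_divisor)
      stats::rgamma(1, shape = sh$shape, scale = sh$scale)
    }
  }, numeric(1))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full two-arm model with each parameter at its low and at
#' its high value, all others held at base, and records the resulting
#' ICERs. Entries are sorted by decreasing spread `|icer_high -
#' icer_low|`, the ordering of a tornado diagram. A model failure at an
#' extreme is flagged in the `note` column rather than dropped; an ICER is
#' `NA` (with a dominance note) when incremental effectiveness is zero or
#' the comparison is dominance rather than a trade-off.
#'
#' @param config A [ce_config()].
#' @param parameters Character vector of registry names to vary; default
#'   all registered parameters.
#' @return A data frame of class `tornado` with columns `parameter`,
#'   `low`, `high`, `icer_low`, `icer_high`, `spread`, `note`.
#' @export
one_way_dsa <- function(config, parameters = names(config$parameters)) {
  stopifnot(inherits(config, "ce_config"))
  unknown <- setdiff(parameters, names(config$parameters))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  eval_at <- function(nm, value) {
    res <- tryCatch(evaluate_config(config, stats::setNames(value, nm)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      return(list(icer = NA_real_, note = paste0("error: ", conditionMessage(res))))
    }
    r <- res$result
    note <- if (r$dominance != "none") r$dominance else ""
    list(icer = r$icer, note = note)
  }
  rows <- lapply(parameters, function(nm) {
    p <- config$parameters[[nm]]
    lo <- eval_at(nm, p$low)
    hi <- eval_at(nm, p$high)
    spread <- abs(hi$icer - lo$icer)
    if (is.na(spread)) spread <- if (p$low == p$high) 0 else NA_real_
    note <- paste(c(if (nzchar(lo$note)) paste0("low: ", lo$note),
                    if (nzchar(hi$note)) paste0("high: ", hi$note)),
                  collapse = "; ")
    data.frame(parameter = nm, low = p$low, high = p$high,
               icer_low = lo$icer, icer_high = hi$icer, spread = spread,
               note = note)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` coherent parameter sets (see
#' [sample_parameter_draw()]), re-runs the full Markov engine for both
#' arms at each draw, and records per-arm discounted costs and QALYs
#' alongside the sampled values. Fully reproducible given `seed`.
#'
#' @param config A [ce_config()].
#' @param n_draws Number of Monte Carlo draws (1,000 in the base case).
#' @param seed Integer RNG seed.
#' @param range_divisor As in [beta_from_mean_range()].
#' @return A data frame of class `psa_samples`: columns `draw`, one per
#'   sampled parameter, then `cost_crt`, `qaly_crt`, `cost_uhrt`,
#'   `qaly_uhrt`.
#' @export
run_psa <- function(config, n_draws = 1000, seed, range_divisor = 3.92) {
  stopifnot(inherits(config, "ce_config"), n_draws >= 1)
  if (missing(seed)) stop("'seed' is required for a reproducible PSA",
                          call. = FALSE)
  # construct all distributions up front so an infeasible one fails fast
  for (p in config$parameters) {
    if (p$dist == "beta" && p$high > p$low) {
      beta_from_mean_range(p$base, p$low, p$high, range_divisor)
    } else if (p$dist == "gamma" && p$high > p$low) {
      gamma_from_mean_range(p$base, p$low, p$high, range_divisor)
    }
  }
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_draws, ncol = length(config$parameters),
                  dimnames = list(NULL, names(config$parameters)))
  outcomes <- matrix(NA_real_, nrow = n_draws, ncol = 4,
                     dimnames = list(NULL, c("cost_crt", "qaly_crt",
                                             "cost_uhrt", "qaly_uhrt")))
  for (i in seq_len(n_draws)) {
    v <- sample_parameter_draw(config$parameters, range_divisor)
    draws[i, ] <- v
    res <- evaluate_config(config, v)
    outcomes[i, ] <- c(res$arms$crt$cost, res$arms$crt$qaly,
                       res$arms$uhrt$cost, res$arms$uhrt$qaly)
  }
  out <- cbind(data.frame(draw = seq_len(n_draws)),
               as.data.frame(draws), as.data.frame(outcomes))
  class(out) <- c("psa_samples", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability (fraction of PSA
#' draws) that the reference arm has the higher net monetary benefit;
#' exact NMB ties count as 0.5. By construction the probabilities for the
#' two arms sum to 1 at every threshold.
#'
#' @param samples A `psa_samples` data frame from [run_psa()].
#' @param wtp_grid Non-empty numeric vector of WTP thresholds (USD/QALY).
#' @param reference `"crt"` or `"uhrt"`.
#' @return A data frame of class `ceac` with columns `wtp` and
#'   `probability`.
#' @export
ceac <- function(samples, wtp_grid, reference = c("crt", "uhrt")) {
  reference <- match.arg(reference)
  stopifnot(inherits(samples, "data.frame"), nrow(samples) >= 1)
  if (length(wtp_grid) == 0) stop("'wtp_grid' must be non-empty", call. = FALSE)
  if (any(wtp_grid < 0)) stop("'wtp_grid' must be >= 0", call. = FALSE)
  comparator <- setdiff(c("crt", "uhrt"), reference)
  prob <- vapply(wtp_grid, function(w) {
    nmb_ref <- net_monetary_benefit(samples[[paste0("cost_", reference)]],
                                    samples[[paste0("qaly_", reference)]], w)
    nmb_cmp <- net_monetary_benefit(samples[[paste0("cost_", comparator)]],
                                    samples[[paste0("qaly_", comparator)]], w)
    mean((nmb_ref > nmb_cmp) + 0.5 * (nmb_ref == nmb_cmp))
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac", "data.frame"))
}

#' Deterministic threshold (crossover) search
#'
#' Finds the value of a scalar knob — the WTP threshold, or any
#' registered parameter (including the discount rate) — at which the
#' base-case decision flips, i.e. where the incremental net monetary
#' benefit of CRT over UHRT changes sign. Bisection to an interval
#' shorter than `tol` in the knob's units. Because NMB is linear in WTP
#' with fixed increments, the WTP crossover equals the deterministic
#' ICER.
#'
#' @param config A [ce_config()].
#' @param knob `"wtp"` or a registered parameter name.
#' @param interval Length-2 numeric search interval.
#' @param tol Bisection tolerance (default 1e-6).
#' @return A list with `crossover` (the knob value, or `NA` if the
#'   decision never changes sign on the interval), `found` (logical), and
#'   `knob`.
#' @export
threshold_search <- function(config, knob, interval, tol = 1e-6) {
  stopifnot(inherits(config, "ce_config"), length(interval) == 2L,
            interval[1] < interval[2])
  if (knob != "wtp" && !knob %in% names(config$parameters)) {
    stop("unknown knob: '", knob, "'", call. = FALSE)
  }
  decision <- function(x) {
    if (knob == "wtp") {
      res <- evaluate_config(config)
      wtp <- x
    } else {
      res <- evaluate_config(config, stats::setNames(x, knob))
      wtp <- config$settings$wtp_per_qaly
    }
    net_monetary_benefit(res$result$incremental_cost,
                         res$result$incremental_effectiveness, wtp)
  }
  lo <- interval[1]; hi <- interval[2]
  f_lo <- decision(lo); f_hi <- decision(hi)
  if (f_lo == 0) return(list(crossover = lo, found = TRUE, knob = knob))
  if (f_hi == 0) return(list(crossover = hi, found = TRUE, knob = knob))
  if (sign(f_lo) == sign(f_hi)) {
    return(list(crossover = NA_real_, found = FALSE, knob = knob))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- decision(mid)
    if (f_mid == 0) return(list(crossover = mid, found = TRUE, knob = knob))
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  list(crossover = (lo + hi) / 2, found = TRUE, knob = knob)
}
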