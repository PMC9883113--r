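#' A named model parameter with uncertainty range and distribution family
#'
#' The unit of one-way and probabilistic sensitivity analysis: a base-case
#' value, a (low, high) range, and the distribution family used to sample
#' it in PSA. Utilities are dimensionless in `[0, 1]` and use beta
#' distributions; costs are in USD and use gamma distributions; `fixed`
#' parameters never vary.
#'
#' @param name Identifier (character scalar).
#' @param base Base-case value.
#' @param low,high Range bounds, `low <= base <= high`. Default to `base`
#'   (degenerate range).
#' @param dist One of `"beta"`, `"gamma"`, `"fixed"`.
#' @param units Free-text units (e.g. `"USD"`, `"utility"`).
#' @param description Optional free text.
#' @return An object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, base, low = base, high = base,
                           dist = c("fixed", "beta", "gamma"),
                           units = "", description = "") {
  dist <- match.arg(dist)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(base), length(base) == 1L, is.finite(base),
            is.numeric(low), is.numeric(high))
  base <- unname(base); low <- unname(low); high <- unname(high)
  if (low > high) {
    stop("range error in '", name, "': low (", low, ") > high (", high, ")",
         call. = FALSE)
  }
  if (base < low || base > high) {
    stop("range error in '", name, "': base must satisfy low <= base <= high",
         call. = FALSE)
  }
  if (dist == "beta" && (low < 0 || high > 1)) {
    stop("validation error in '", name,
         "': beta-distributed parameters must have range within [0, 1]",
         call. = FALSE)
  }
  if (dist == "gamma" && low < 0) {
    stop("validation error in '", name,
         "': gamma-distributed parameters must have low >= 0", call. = FALSE)
  }
  structure(list(name = name, base = base, low = low, high = high,
                 dist = dist, units = units, description = description),
            class = "parameter_spec")
}

#' @export
print.parameter_spec <- function(x, ...) {
  cat(sprintf("%s: %.6g (%.6g-%.6g) [%s] %s\n",
              x$name, x$base, x$low, x$high, x$dist, x$units))
  invisible(x)
}

#' Base-case values of a parameter registry
#'
#' @param parameters Named list of [parameter_spec()] objects.
#' @return Named numeric vector of base values.
#' @export
parameter_values <- function(parameters) {
  vapply(parameters, function(p) p$base, numeric(1))
}

#' Radiotherapy fractionation scheme
#'
#' Total dose D, dose per fraction d, number of fractions, and the tissue
#' alpha/beta ratio used for biologically effective dose. Total dose must
#' equal dose-per-fraction times fraction count.
#'
#' @param total_dose_Gy Total physical dose D (Gy).
#' @param dose_per_fraction_Gy Single-fraction dose d (Gy).
#' @param n_fractions Integer number of fractions.
#' @param alpha_beta_Gy Tissue alpha/beta ratio (Gy); 3 Gy for prostate
#'   tumour in this model.
#' @return An object of class `fractionation_scheme`.
#' @export
#' @examples
#' crt <- fractionation_scheme(78, 2, 39)
#' bed(crt)  # 130 Gy
fractionation_scheme <- function(total_dose_Gy, dose_per_fraction_Gy,
                                 n_fractions, alpha_beta_Gy = 3) {
  stopifnot(is.numeric(total_dose_Gy), is.numeric(dose_per_fraction_Gy),
            is.numeric(n_fractions), is.numeric(alpha_beta_Gy))
  if (total_dose_Gy <= 0 || dose_per_fraction_Gy <= 0 ||
      n_fractions <= 0 || alpha_beta_Gy <= 0) {
    stop("all fractionation fields must be strictly positive", call. = FALSE)
  }
  if (abs(n_fractions - round(n_fractions)) > 1e-9) {
    stop("'n_fractions' must be an integer", call. = FALSE)
  }
  expected <- dose_per_fraction_Gy * n_fractions
  if (abs(total_dose_Gy - expected) > 1e-9 * max(1, abs(expected))) {
    stop(sprintf(
      "inconsistent scheme: total %.6g Gy != %.6g Gy/fraction x %d fractions",
      total_dose_Gy, dose_per_fraction_Gy, as.integer(round(n_fractions))),
      call. = FALSE)
  }
  structure(list(total_dose_Gy = total_dose_Gy,
                 dose_per_fraction_Gy = dose_per_fraction_Gy,
                 n_fractions = as.integer(round(n_fractions)),
                 alpha_beta_Gy = alpha_beta_Gy),
            class = "fractionation_scheme")
}

#' Biologically effective dose of a fractionation scheme
#'
#' `BED = D * (1 + d / (alpha/beta))`, the linear-quadratic-model quantity
#' that puts fractionation schedules on a common radiobiological scale.
#' With alpha/beta = 3 Gy, 78 Gy in 39 fractions gives 130 Gy and
#' 42.7 Gy in 7 fractions gives 129.52 Gy: near-isoeffective schedules.
#'
#' @param scheme A [fractionation_scheme()].
#' @return BED in Gy.
#' @export
bed <- function(scheme) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  if (scheme$alpha_beta_Gy <= 0) stop("alpha/beta must be > 0", call. = FALSE)
  scheme$total_dose_Gy *
    (1 + scheme$dose_per_fraction_Gy / scheme$alpha_beta_Gy)
}

#' Health-state utility set for one treatment arm
#'
#' `u_ffs` is the arm-specific failure-free-survival utility, already
#' incorporating the arm's grade >= 2 urinary toxicity burden. `u_ps` is
#' the progressive-survival utility, a weighted composition of the
#' biochemical-recurrence and clinical-metastasis utilities (see
#' [compose_ps_utility()]); the components and weight may be carried along
#' for provenance.
#'
#' @param u_ffs Failure-free survival utility in `[0, 1]`.
#' @param u_ps Progressive survival utility in `[0, 1]`.
#' @param u_br,u_cm,w_br Optional composition components: biochemical
#'   recurrence utility, clinical metastasis utility, and the weight of
#'   biochemical recurrence.
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_ffs, u_ps, u_br = NA_real_, u_cm = NA_real_,
                        w_br = NA_real_) {
  for (nm in c("u_ffs", "u_ps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("validation error: '", nm, "' must be a utility in [0, 1]",
           call. = FALSE)
    }
  }
  for (nm in c("u_br", "u_cm")) {
    v <- get(nm)
    if (!is.na(v) && (v < 0 || v > 1)) {
      stop("validation error: '", nm, "' must be a utility in [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.na(u_br) && !is.na(u_cm)) {
    lo <- min(u_br, u_cm) - 1e-12
    hi <- max(u_br, u_cm) + 1e-12
    if (u_ps < lo || u_ps > hi) {
      stop("validation error: composed 'u_ps' must lie between 'u_br' and 'u_cm'",
           call. = FALSE)
    }
  }
  structure(list(u_ffs = u_ffs, u_ps = u_ps, u_br = u_br, u_cm = u_cm,
                 w_br = w_br),
            class = "utility_set")
}

#' Compose the progressive-survival utility
#'
#' The post-failure state pools biochemical recurrence and clinical
#' metastasis; its utility is the mixture
#' `w_br * u_br + (1 - w_br) * u_cm`.
#'
#' @param u_br Biochemical recurrence utility in `[0, 1]`.
#' @param u_cm Clinical metastasis utility in `[0, 1]`.
#' @param w_br Weight of biochemical recurrence in `[0, 1]`.
#' @return The mixed utility.
#' @export
#' @examples
#' compose_ps_utility(0.74, 0.25, 0.7347)  # ~0.61
compose_ps_utility <- function(u_br, u_cm, w_br) {
  stopifnot(is.numeric(u_br), is.numeric(u_cm), is.numeric(w_br))
  if (any(u_br < 0 | u_br > 1) || any(u_cm < 0 | u_cm > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(w_br < 0 | w_br > 1)) {
    stop("domain error: 'w_br' must lie in [0, 1]", call. = FALSE)
  }
  w_br * u_br + (1 - w_br) * u_cm
}

#' Cost schedule for one treatment arm
#'
#' One-time costs are charged at model entry (the radiotherapy course);
#' the toxicity cost is charged once, scaled by the arm's grade >= 2
#' urinary toxicity incidence. Per-cycle costs accrue with state
#' occupancy; adjuvant androgen deprivation therapy (ADT) accrues monthly
#' against FFS occupancy for `adt_duration_months` months.
#'
#' @param one_time_costs Named numeric vector of USD amounts applied at
#'   model entry.
#' @param per_cycle_ffs USD per cycle while in FFS (follow-up care).
#' @param per_cycle_ps USD per cycle while in PS.
#' @param adt_monthly USD per month of ADT.
#' @param adt_duration_months Integer months of adjuvant ADT (24 in the
#'   base case).
#' @param toxicity_cost One-time USD cost of grade >= 2 urinary toxicity.
#' @param toxicity_incidence Probability of that toxicity.
#' @return An object of class `cost_schedule`.
#' @export
cost_schedule <- function(one_time_costs = c(entry = 0), per_cycle_ffs = 0,
                          per_cycle_ps = 0, adt_monthly = 0,
                          adt_duration_months = 0L, toxicity_cost = 0,
                          toxicity_incidence = 0) {
  vals <- c(one_time_costs, per_cycle_ffs, per_cycle_ps, adt_monthly,
            adt_duration_months, toxicity_cost)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("validation error: all cost components must be finite and >= 0",
         call. = FALSE)
  }
  if (toxicity_incidence < 0 || toxicity_incidence > 1) {
    stop("validation error: 'toxicity_incidence' must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(one_time_costs = one_time_costs,
                 per_cycle_ffs = per_cycle_ffs,
                 per_cycle_ps = per_cycle_ps,
                 adt_monthly = adt_monthly,
                 adt_duration_months = as.integer(adt_duration_months),
                 toxicity_cost = toxicity_cost,
                 toxicity_incidence = toxicity_incidence),
            class = "cost_schedule")
}

#' Global model settings
#'
#' @param horizon_years Model horizon (15 years in the base case, by which
#'   time nearly the whole cohort is assumed to have died).
#' @param cycle_length_years Cycle length; must divide the horizon into an
#'   integer number of cycles. Default 1 year.
#' @param annual_discount_rate Annual discount rate applied to both costs
#'   and QALYs (0.03 base case, varied over 0-0.08).
#' @param background_mortality Background (other-cause) death probability
#'   applied to the FFS state, 0.0003 in the base case.
#' @param background_mortality_timescale Either `"cycle"` (the default:
#'   0.0003 is a per-cycle probability) or `"year"` (converted to the
#'   cycle length via `1 - (1 - q)^cycle_length`).
#' @param wtp_per_qaly Willingness-to-pay threshold, USD per QALY
#'   (31,510 = 3x China's 2020 per-capita GDP).
#' @param half_cycle_correction Average adjacent cycle occupancies when
#'   accruing costs and QALYs. Default `FALSE`.
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(horizon_years = 15, cycle_length_years = 1,
                           annual_discount_rate = 0.03,
                           background_mortality = 3e-4,
                           background_mortality_timescale = c("cycle", "year"),
                           wtp_per_qaly = 31510,
                           half_cycle_correction = FALSE) {
  background_mortality_timescale <- match.arg(background_mortality_timescale)
  if (horizon_years <= 0) stop("'horizon_years' must be > 0", call. = FALSE)
  if (cycle_length_years <= 0) {
    stop("'cycle_length_years' must be > 0", call. = FALSE)
  }
  n <- horizon_years / cycle_length_years
  if (abs(n - round(n)) > 1e-9) {
    stop("configuration error: cycle length must divide the horizon into ",
         "an integer number of cycles", call. = FALSE)
  }
  if (annual_discount_rate < 0 || annual_discount_rate > 1) {
    stop("'annual_discount_rate' must lie in [0, 1]", call. = FALSE)
  }
  if (background_mortality < 0 || background_mortality > 1) {
    stop("'background_mortality' must lie in [0, 1]", call. = FALSE)
  }
  if (wtp_per_qaly < 0) stop("'wtp_per_qaly' must be >= 0", call. = FALSE)
  structure(list(horizon_years = horizon_years,
                 cycle_length_years = cycle_length_years,
                 annual_discount_rate = annual_discount_rate,
                 background_mortality = background_mortality,
                 background_mortality_timescale = background_mortality_timescale,
                 wtp_per_qaly = wtp_per_qaly,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "model_settings")
}

#' Number of cycles implied by the settings
#'
#' @param settings A [model_settings()] object.
#' @return Integer cycle count.
#' @export
n_cycles <- function(settings) {
  stopifnot(inherits(settings, "model_settings"))
  as.integer(round(settings$horizon_years / settings$cycle_length_years))
}

#' Per-cycle background mortality implied by the settings
#'
#' @param settings A [model_settings()] object.
#' @return Probability per cycle.
#' @keywords internal
background_mortality_per_cycle <- function(settings) {
  q <- settings$background_mortality
  if (settings$background_mortality_timescale == "year") {
    1 - (1 - q)^settings$cycle_length_years
  } else {
    q
  }
}

#' A fully specified treatment arm
#'
#' Bundles everything the Markov engine and the economics layer need for
#' one strategy: the fractionation scheme, the FFS->PS and PS->death
#' Weibull survival models, the utility set, and the cost schedule.
#'
#' @param name Arm label, e.g. `"crt"` or `"uhrt"`.
#' @param scheme A [fractionation_scheme()].
#' @param ffs_model [weibull_survival()] for the FFS->PS pathway.
#' @param ps_death_model [weibull_survival()] for the PS->death pathway.
#' @param utilities A [utility_set()].
#' @param costs A [cost_schedule()].
#' @return An object of class `arm_model`.
#' @export
arm_model <- function(name, scheme, ffs_model, ps_death_model, utilities,
                      costs) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(scheme, "fractionation_scheme"),
            inherits(ffs_model, "weibull_survival"),
            inherits(ps_death_model, "weibull_survival"),
            inherits(utilities, "utility_set"),
            inherits(costs, "cost_schedule"))
  structure(list(name = name, scheme = scheme, ffs_model = ffs_model,
                 ps_death_model = ps_death_model, utilities = utilities,
                 costs = costs),
            class = "arm_model")
}
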