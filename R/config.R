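#' Canonical parameter names the model engine reads
#'
#' The two-arm model is driven by a registry of [parameter_spec()]s; these
#' names are the ones the engine consumes when building arm models.
#' Additional registry entries (e.g. the progressive-survival composition
#' components `u_br`, `u_cm`, `w_br`) are carried through sensitivity
#' analyses but do not enter the base-case computation directly.
#'
#' @return Character vector of required parameter names.
#' @export
required_parameter_names <- function() {
  c("u_ffs_crt", "u_ffs_uhrt", "u_ps", "discount_rate",
    "c_rt_crt", "c_rt_uhrt", "c_adt_monthly", "c_ps_monthly",
    "c_fu_annual", "c_ut")
}

#' Assemble a full two-arm model configuration
#'
#' @param settings A [model_settings()].
#' @param arms Named list with elements `crt` and `uhrt`; each a list with
#'   `label`, `scheme` ([fractionation_scheme()]), `ffs_model` and
#'   `ps_death_model` ([weibull_survival()]), and `toxicity_incidence`.
#' @param parameters Named list of [parameter_spec()] containing at least
#'   [required_parameter_names()].
#' @param adt_duration_months Months of adjuvant androgen deprivation
#'   therapy charged to both arms (24 in the base case).
#' @return An object of class `ce_config`.
#' @export
ce_config <- function(settings, arms, parameters, adt_duration_months = 24L) {
  stopifnot(inherits(settings, "model_settings"), is.list(arms),
            is.list(parameters))
  if (!all(c("crt", "uhrt") %in% names(arms))) {
    stop("validation error: 'arms' must contain elements 'crt' and 'uhrt'",
         call. = FALSE)
  }
  for (id in c("crt", "uhrt")) {
    arm <- arms[[id]]
    if (!inherits(arm$scheme, "fractionation_scheme")) {
      stop("validation error: arms$", id, "$scheme must be a fractionation_scheme",
           call. = FALSE)
    }
    for (f in c("ffs_model", "ps_death_model")) {
      if (!inherits(arm[[f]], "weibull_survival")) {
        stop("validation error: arms$", id, "$", f,
             " must be a weibull_survival", call. = FALSE)
      }
    }
    ti <- arm$toxicity_incidence
    if (!is.numeric(ti) || length(ti) != 1L || ti < 0 || ti > 1) {
      stop("validation error: arms$", id,
           "$toxicity_incidence must lie in [0, 1]", call. = FALSE)
    }
  }
  if (is.null(names(parameters)) || any(!nzchar(names(parameters)))) {
    stop("validation error: 'parameters' must be a named list", call. = FALSE)
  }
  bad <- !vapply(parameters, inherits, logical(1), "parameter_spec")
  if (any(bad)) {
    stop("validation error: parameters not of class parameter_spec: ",
         paste(names(parameters)[bad], collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(required_parameter_names(), names(parameters))
  if (length(missing)) {
    stop("validation error: missing required parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in names(parameters)) {
    p <- parameters[[nm]]
    if (startsWith(nm, "u_") || nm == "w_br") {
      if (p$base < 0 || p$base > 1 || p$low < 0 || p$high > 1) {
        stop("validation error in '", nm,
             "': utilities and weights must lie in [0, 1]", call. = FALSE)
      }
    }
    if (startsWith(nm, "c_") && p$low < 0) {
      stop("validation error in '", nm, "': costs must be >= 0", call. = FALSE)
    }
    if (nm == "discount_rate" && (p$low < 0 || p$high > 1)) {
      stop("validation error in 'discount_rate': rate range must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (adt_duration_months < 0) {
    stop("validation error: 'adt_duration_months' must be >= 0", call. = FALSE)
  }
  structure(list(settings = settings, arms = arms, parameters = parameters,
                 adt_duration_months = as.integer(adt_duration_months)),
            class = "ce_config")
}

#' @export
print.ce_config <- function(x, ...) {
  cat("Two-arm cost-effectiveness model configuration\n")
  cat(sprintf("  horizon %g y, cycle %g y, discount %.3g, WTP $%g/QALY\n",
              x$settings$horizon_years, x$settings$cycle_length_years,
              x$settings$annual_discount_rate, x$settings$wtp_per_qaly))
  for (id in c("crt", "uhrt")) {
    s <- x$arms[[id]]$scheme
    cat(sprintf("  %-5s %g Gy in %d x %g Gy (BED %.2f Gy), toxicity %.3g\n",
                id, s$total_dose_Gy, s$n_fractions, s$dose_per_fraction_Gy,
                bed(s), x$arms[[id]]$toxicity_incidence))
  }
  cat(sprintf("  %d registered parameters\n", length(x$parameters)))
  invisible(x)
}

#' Load a model configuration from JSON
#'
#' Reads and validates the documented configuration schema: sections
#' `settings`, `arms` (with `crt` and `uhrt`), `parameters`, and
#' `adt_duration_months`. Missing optional settings fall back to the
#' [model_settings()] defaults. Every parameter entry is validated
#' through [parameter_spec()]; schema or range violations raise errors
#' naming the offending field.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated [ce_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (section in c("settings", "arms", "parameters")) {
    if (is.null(raw[[section]])) {
      stop("schema violation: missing section '", section, "'", call. = FALSE)
    }
  }
  s <- raw$settings
  settings <- model_settings(
    horizon_years = s$horizon_years %||% 15,
    cycle_length_years = s$cycle_length_years %||% 1,
    annual_discount_rate = s$annual_discount_rate %||% 0.03,
    background_mortality = s$background_mortality %||% 3e-4,
    background_mortality_timescale = s$background_mortality_timescale %||% "cycle",
    wtp_per_qaly = s$wtp_per_qaly %||% 31510,
    half_cycle_correction = s$half_cycle_correction %||% FALSE)
  arms <- lapply(raw$arms[c("crt", "uhrt")], function(a) {
    if (is.null(a)) stop("schema violation: arms must include crt and uhrt",
                         call. = FALSE)
    list(label = a$label %||% "",
         scheme = fractionation_scheme(a$scheme$total_dose_Gy,
                                       a$scheme$dose_per_fraction_Gy,
                                       a$scheme$n_fractions,
                                       a$scheme$alpha_beta_Gy %||% 3),
         ffs_model = weibull_survival(a$ffs_model$rate, a$ffs_model$shape),
         ps_death_model = weibull_survival(a$ps_death_model$rate,
                                           a$ps_death_model$shape),
         toxicity_incidence = a$toxicity_incidence)
  })
  parameters <- lapply(names(raw$parameters), function(nm) {
    p <- raw$parameters[[nm]]
    parameter_spec(nm, base = p$base, low = p$low %||% p$base,
                   high = p$high %||% p$base, dist = p$dist %||% "fixed",
                   units = p$units %||% "", description = p$description %||% "")
  })
  names(parameters) <- names(raw$parameters)
  ce_config(settings, arms, parameters,
            adt_duration_months = raw$adt_duration_months %||% 24L)
}

#' Write a model configuration to JSON
#'
#' Produces the canonical normalized dump readable by [load_config()];
#' a write/load round trip reproduces the configuration exactly.
#'
#' @param config A [ce_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ce_config"))
  out <- list(
    settings = unclass(config$settings),
    adt_duration_months = config$adt_duration_months,
    arms = lapply(config$arms[c("crt", "uhrt")], function(a) {
      list(label = a$label,
           scheme = unclass(a$scheme),
           ffs_model = unclass(a$ffs_model),
           ps_death_model = unclass(a$ps_death_model),
           toxicity_incidence = a$toxicity_incidence)
    }),
    parameters = lapply(config$parameters, function(p) {
      unclass(p)[c("base", "low", "high", "dist", "units", "description")]
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Materialize an arm model from the configuration and parameter values
#'
#' @param config A [ce_config()].
#' @param arm_id `"crt"` or `"uhrt"`.
#' @param values Named numeric vector of parameter values (defaults to the
#'   registry base case).
#' @return An [arm_model()].
#' @export
build_arm <- function(config, arm_id = c("crt", "uhrt"),
                      values = parameter_values(config$parameters)) {
  arm_id <- match.arg(arm_id)
  a <- config$arms[[arm_id]]
  cl <- config$settings$cycle_length_years
  utilities <- utility_set(u_ffs = unname(values[paste0("u_ffs_", arm_id)]),
                           u_ps = unname(values["u_ps"]))
  costs <- cost_schedule(
    one_time_costs = c(radiotherapy_course = unname(values[paste0("c_rt_", arm_id)])),
    per_cycle_ffs = unname(values["c_fu_annual"]) * cl,
    per_cycle_ps = unname(values["c_ps_monthly"]) * 12 * cl,
    adt_monthly = unname(values["c_adt_monthly"]),
    adt_duration_months = config$adt_duration_months,
    toxicity_cost = unname(values["c_ut"]),
    toxicity_incidence = a$toxicity_incidence)
  arm_model(name = arm_id, scheme = a$scheme, ffs_model = a$ffs_model,
            ps_death_model = a$ps_death_model, utilities = utilities,
            costs = costs)
}

#' Evaluate the two-arm model at given parameter values
#'
#' Runs the Markov cohort for both arms, accumulates discounted costs and
#' QALYs, and computes the incremental comparison of CRT versus UHRT.
#' `overrides` replaces individual registry values — the workhorse of the
#' deterministic and probabilistic sensitivity analyses.
#'
#' @param config A [ce_config()].
#' @param overrides Optional named numeric vector of parameter values to
#'   substitute for registry base values (must name registered
#'   parameters).
#' @return A list with `arms` (per-arm list of `trace`, `cost`, `qaly`),
#'   `result` (a [compute_icer()] `ce_result`, CRT vs UHRT), and
#'   `values` (the parameter values used).
#' @export
evaluate_config <- function(config, overrides = NULL) {
  stopifnot(inherits(config, "ce_config"))
  values <- parameter_values(config$parameters)
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(values))
    if (length(unknown)) {
      stop("unknown parameter(s) in overrides: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    values[names(overrides)] <- overrides
  }
  settings <- config$settings
  settings$annual_discount_rate <- unname(values["discount_rate"])
  arms <- lapply(c(crt = "crt", uhrt = "uhrt"), function(id) {
    arm <- build_arm(config, id, values)
    trace <- run_cohort(arm, settings)
    acc <- accumulate(trace, arm$utilities, arm$costs, settings)
    list(trace = trace, cost = acc$cost, qaly = acc$qaly)
  })
  result <- compute_icer(arms$crt, arms$uhrt, labels = c("crt", "uhrt"))
  list(arms = arms, result = result, values = values)
}
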