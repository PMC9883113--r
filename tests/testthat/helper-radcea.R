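# shared helpers: small random model generators and a bare-bones trace builder

random_weibull_models <- function(n, seed = 99) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  models <- replicate(n, weibull_survival(rate = runif(1, 0.005, 0.5),
                                          shape = runif(1, 0.4, 2.5)),
                      simplify = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  models
}

# cohort_trace from an explicit occupancy matrix (rows = cycle boundaries)
make_trace <- function(occupancy, cycle_length_years = 1) {
  colnames(occupancy) <- c("ffs", "ps", "dead")
  structure(list(occupancy = occupancy,
                 cycle_length_years = cycle_length_years),
            class = "cohort_trace")
}

# an arm whose transitions are all driven by explicit Weibull models
make_arm <- function(ffs_rate = 0, ffs_shape = 1, psd_rate = 0,
                     psd_shape = 1, u_ffs = 1, u_ps = 1) {
  arm_model(name = "toy",
            scheme = fractionation_scheme(78, 2, 39),
            ffs_model = weibull_survival(ffs_rate, ffs_shape),
            ps_death_model = weibull_survival(psd_rate, psd_shape),
            utilities = utility_set(u_ffs = u_ffs, u_ps = u_ps),
            costs = cost_schedule())
}

make_settings <- function(...) {
  defaults <- list(horizon_years = 15, cycle_length_years = 1,
                   annual_discount_rate = 0, background_mortality = 0,
                   wtp_per_qaly = 31510, half_cycle_correction = FALSE)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_settings, args)
}

# fixture with every parameter's distribution collapsed to a point
degenerate_fixture <- function() {
  cfg <- paper_fixture()
  cfg$parameters <- lapply(cfg$parameters, function(p) {
    parameter_spec(p$name, p$base, p$base, p$base, "fixed", p$units,
                   p$description)
  })
  cfg
}
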