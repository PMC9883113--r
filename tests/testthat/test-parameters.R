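test_that("parameter_spec enforces range and family constraints", {
  p <- parameter_spec("c_ut", 960, 768, 1152, "gamma", units = "USD")
  expect_s3_class(p, "parameter_spec")
  expect_error(parameter_spec("x", 1, 2, 0.5), "low")
  expect_error(parameter_spec("x", 5, 1, 2), "base")
  expect_error(parameter_spec("u", 0.5, -0.1, 1, "beta"), "\\[0, 1\\]")
  expect_error(parameter_spec("u", 0.5, 0.2, 1.2, "beta"), "\\[0, 1\\]")
  expect_error(parameter_spec("c", 10, -5, 20, "gamma"), "low >= 0")
})

test_that("fractionation schemes must be self-consistent and positive", {
  s <- fractionation_scheme(42.7, 6.1, 7)
  expect_equal(s$total_dose_Gy, 42.7)
  expect_error(fractionation_scheme(78, 2, 38), "inconsistent")
  expect_error(fractionation_scheme(-78, 2, -39), "strictly positive")
  expect_error(fractionation_scheme(10, 2.5, 4.2), "integer")
})

test_that("BED follows the linear-quadratic fractionation formula", {
  expect_equal(bed(fractionation_scheme(78, 2, 39, 3)), 130)
  expect_equal(round(bed(fractionation_scheme(42.7, 6.1, 7, 3)), 2), 129.52)
  # d -> 0 limit: BED collapses to the physical dose
  tiny_d <- fractionation_scheme(70 * 1e-4, 1e-4, 70)
  expect_equal(bed(tiny_d) / tiny_d$total_dose_Gy, 1, tolerance = 1e-4)
})

test_that("progressive-survival utility composes as a mixture", {
  # weight back-solved from 0.74 w + 0.25 (1 - w) = 0.61
  w <- 0.36 / 0.49
  expect_equal(round(compose_ps_utility(0.74, 0.25, w), 2), 0.61)
  expect_equal(compose_ps_utility(0.74, 0.25, 0.7347), 0.61,
               tolerance = 1e-4)
  expect_equal(compose_ps_utility(0.8, 0.8, 0.3), 0.8)
  expect_equal(compose_ps_utility(0.74, 0.25, 1), 0.74)
  expect_error(compose_ps_utility(0.74, 0.25, 1.2), "domain error")
  expect_error(compose_ps_utility(1.4, 0.25, 0.5), "\\[0, 1\\]")
})

test_that("utility sets and cost schedules reject invalid values", {
  expect_error(utility_set(u_ffs = 1.3, u_ps = 0.6), "u_ffs")
  expect_error(utility_set(u_ffs = 0.9, u_ps = -0.1), "u_ps")
  expect_error(utility_set(u_ffs = 0.9, u_ps = 0.8, u_br = 0.74, u_cm = 0.25),
               "between")
  expect_silent(utility_set(u_ffs = 0.9, u_ps = 0.61, u_br = 0.74,
                            u_cm = 0.25, w_br = 0.7347))
  expect_error(cost_schedule(per_cycle_ffs = -1), ">= 0")
  expect_error(cost_schedule(toxicity_incidence = 1.5), "toxicity_incidence")
})

test_that("model settings validate the cycle structure", {
  s <- model_settings()
  expect_equal(n_cycles(s), 15L)
  expect_error(model_settings(horizon_years = 15, cycle_length_years = 0.4),
               "integer number of cycles")
  expect_error(model_settings(annual_discount_rate = 1.5), "discount")
  s_month <- model_settings(cycle_length_years = 1 / 12,
                            horizon_years = 15)
  expect_equal(n_cycles(s_month), 180L)
})

test_that("the shipped fixture file loads with the published trial inputs", {
  path <- system.file("extdata", "uhrt_crt_config.json", package = "radcea")
  cfg <- load_config(path)
  expect_s3_class(cfg, "ce_config")
  expect_equal(cfg$arms$uhrt$scheme$total_dose_Gy, 42.7)
  expect_equal(cfg$arms$uhrt$scheme$n_fractions, 7L)
  expect_equal(cfg$settings$wtp_per_qaly, 31510)
  expect_equal(cfg$parameters$u_ffs_crt$base, 0.91)
  expect_equal(cfg$parameters$c_ut$base, 960)
  expect_equal(cfg$parameters$c_ut$low, 768)
  # goserelin 396.67 + bicalutamide 72.49 per ADT month
  expect_equal(cfg$parameters$c_adt_monthly$base, 396.67 + 72.49)
  expect_equal(cfg$parameters$discount_rate$base, 0.03)
  expect_equal(cfg$adt_duration_months, 24L)
})

test_that("configurations round-trip through write_config/load_config", {
  cfg <- paper_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  expect_equal(load_config(path), cfg)
})

test_that("config validation rejects perturbations violating invariants", {
  base <- paper_fixture()
  # utility out of bounds
  bad_util <- base$parameters
  bad_util$u_ffs_crt <- structure(list(name = "u_ffs_crt", base = 1.3,
                                       low = 0.7, high = 1.4, dist = "fixed",
                                       units = "", description = ""),
                                  class = "parameter_spec")
  expect_error(ce_config(base$settings, base$arms, bad_util),
               "\\[0, 1\\]")
  # missing required parameter
  expect_error(ce_config(base$settings, base$arms,
                         base$parameters[setdiff(names(base$parameters),
                                                 "c_ut")]),
               "missing required")
  # toxicity incidence outside [0,1]
  bad_arms <- base$arms
  bad_arms$crt$toxicity_incidence <- 1.2
  expect_error(ce_config(base$settings, bad_arms, base$parameters),
               "toxicity_incidence")
  # randomized low/high inversions are all rejected
  set.seed(7)
  for (i in 1:20) {
    nm <- sample(names(base$parameters), 1)
    p <- base$parameters[[nm]]
    expect_error(parameter_spec(p$name, p$base,
                                low = p$base + runif(1, 0.1, 1),
                                high = p$base - runif(1, 0.1, 1)),
                 "range error")
  }
})

test_that("unknown override names are rejected", {
  cfg <- paper_fixture()
  expect_error(evaluate_config(cfg, c(not_a_parameter = 1)), "unknown")
})
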