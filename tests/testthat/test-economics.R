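test_that("discount factors follow the compound formula", {
  s3 <- make_settings(annual_discount_rate = 0.03)
  expect_equal(discount_factor(s3, 0), 1)
  expect_equal(discount_factor(s3, 1), 1 / 1.03, tolerance = 1e-12)
  s0 <- make_settings(annual_discount_rate = 0)
  expect_equal(discount_factor(s0, c(0, 7, 15)), rep(1, 3))

  # iterative oracle: repeated division by (1 + r)
  s8 <- make_settings(annual_discount_rate = 0.08)
  f <- 1
  for (i in 1:15) f <- f / 1.08
  expect_equal(discount_factor(s8, 15), f, tolerance = 1e-12)

  # sub-annual cycles discount by elapsed years, not cycle count
  sm <- make_settings(annual_discount_rate = 0.03,
                      cycle_length_years = 0.5)
  expect_equal(discount_factor(sm, 2), 1 / 1.03, tolerance = 1e-12)
})

test_that("accumulate reproduces hand-computed limits", {
  set <- make_settings()
  # perfect health, nobody dies, no discounting: 15 undiscounted QALYs
  tr <- run_cohort(make_arm(), set)
  full <- accumulate(tr, utility_set(1, 1), cost_schedule(), set)
  expect_equal(full$qaly, 15)
  expect_equal(full$cost, 0)

  # zero utilities: QALYs 0, only the one-time costs remain
  zero <- accumulate(tr, utility_set(0, 0),
                     cost_schedule(one_time_costs = c(rt = 1234)), set)
  expect_equal(zero$qaly, 0)
  expect_equal(zero$cost, 1234)
})

test_that("accumulate matches a hand-summed toy trace", {
  occ <- rbind(c(1, 0, 0), c(0.5, 0.5, 0))
  tr <- make_trace(occ)
  set <- make_settings(horizon_years = 1)
  u <- utility_set(0.9, 0.6)
  acc <- accumulate(tr, u, cost_schedule(), set)
  expect_equal(acc$qaly, 0.9)  # cycle-start occupancy (1,0,0)

  # half-cycle correction averages the two boundaries
  set_hc <- make_settings(horizon_years = 1, half_cycle_correction = TRUE)
  acc_hc <- accumulate(tr, u, cost_schedule(), set_hc)
  expect_equal(acc_hc$qaly, 0.75 * 0.9 + 0.25 * 0.6)

  # per-cycle and ADT costs weight occupancy at the cycle start
  costs <- cost_schedule(one_time_costs = c(rt = 100), per_cycle_ffs = 10,
                         per_cycle_ps = 50, adt_monthly = 2,
                         adt_duration_months = 24, toxicity_cost = 960,
                         toxicity_incidence = 0.05)
  acc_c <- accumulate(tr, u, costs, set)
  expect_equal(acc_c$cost, 100 + 960 * 0.05 + 10 + 2 * 12)
})

test_that("accumulate with no discounting equals an independent loop oracle", {
  cfg <- paper_fixture()
  arm <- build_arm(cfg, "crt")
  set <- cfg$settings
  set$annual_discount_rate <- 0
  set$half_cycle_correction <- FALSE
  tr <- run_cohort(arm, set)
  acc <- accumulate(tr, arm$utilities, arm$costs, set)
  q <- 0; co <- sum(arm$costs$one_time_costs) +
    arm$costs$toxicity_cost * arm$costs$toxicity_incidence
  for (k in 0:(n_cycles(set) - 1)) {
    occ <- tr$occupancy[k + 1, ]
    q <- q + occ[["ffs"]] * arm$utilities$u_ffs +
      occ[["ps"]] * arm$utilities$u_ps
    adt_m <- max(0, min(arm$costs$adt_duration_months, (k + 1) * 12) - k * 12)
    co <- co + occ[["ffs"]] * arm$costs$per_cycle_ffs +
      occ[["ps"]] * arm$costs$per_cycle_ps +
      occ[["ffs"]] * arm$costs$adt_monthly * adt_m
  }
  expect_equal(acc$qaly, q, tolerance = 1e-12)
  expect_equal(acc$cost, co, tolerance = 1e-12)
})

test_that("discounted QALYs decrease as the discount rate rises", {
  cfg <- paper_fixture()
  arm <- build_arm(cfg, "crt")
  qalys <- sapply(seq(0, 0.08, by = 0.01), function(r) {
    set <- cfg$settings
    set$annual_discount_rate <- r
    tr <- run_cohort(arm, set)
    accumulate(tr, arm$utilities, arm$costs, set)$qaly
  })
  expect_true(all(diff(qalys) < 0))
})

test_that("compute_icer reproduces the published worked arithmetic", {
  res <- compute_icer(list(cost = 34411.85, qaly = 2.32),
                      list(cost = 30160.81, qaly = 2.14),
                      labels = c("crt", "uhrt"))
  expect_equal(res$incremental_cost, 4251.04, tolerance = 1e-9)
  expect_equal(res$incremental_effectiveness, 0.18, tolerance = 1e-9)
  expect_equal(round(res$icer, 2), 23616.89)
  expect_equal(res$dominance, "none")
  expect_equal(unname(res$avg_ce), unname(res$cost / res$qaly))
})

test_that("compute_icer flags dominance and equal effectiveness", {
  dom <- compute_icer(list(cost = 100, qaly = 2), list(cost = 200, qaly = 1))
  expect_equal(dom$dominance, "a_dominant")
  dom2 <- compute_icer(list(cost = 200, qaly = 1), list(cost = 100, qaly = 2))
  expect_equal(dom2$dominance, "b_dominant")
  eq <- compute_icer(list(cost = 100, qaly = 1), list(cost = 50, qaly = 1))
  expect_true(is.na(eq$icer))
  expect_match(eq$dominance, "equal effectiveness")
})

test_that("increments are antisymmetric under arm exchange", {
  a <- list(cost = 34411.85, qaly = 2.32)
  b <- list(cost = 30160.81, qaly = 2.14)
  ab <- compute_icer(a, b); ba <- compute_icer(b, a)
  expect_equal(ab$incremental_cost, -ba$incremental_cost)
  expect_equal(ab$incremental_effectiveness, -ba$incremental_effectiveness)
  expect_equal(ab$icer, ba$icer)  # ratio of two sign flips
})

test_that("net monetary benefit implements the WTP decision rule", {
  # published per-arm totals: NMB difference at the Chinese threshold
  d <- net_monetary_benefit(34411.85, 2.32, 31510) -
    net_monetary_benefit(30160.81, 2.14, 31510)
  expect_equal(d, 31510 * 0.18 - 4251.04, tolerance = 1e-9)
  expect_gt(d, 0)  # CRT preferred at the Chinese WTP
  expect_equal(net_monetary_benefit(500, 2, 0), -500)
  # at wtp equal to the ICER the two arms are indifferent
  icer <- 4251.04 / 0.18
  expect_equal(net_monetary_benefit(34411.85, 2.32, icer),
               net_monetary_benefit(30160.81, 2.14, icer), tolerance = 1e-9)
})
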