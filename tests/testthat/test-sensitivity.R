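test_that("beta method-of-moments reproduces the input mean and SE", {
  sh <- beta_from_mean_range(0.74, 0.592, 0.888)
  expect_equal(sh$se, 0.296 / 3.92)
  expect_equal(round(sh$se, 4), 0.0755)
  mean_beta <- sh$alpha / (sh$alpha + sh$beta)
  sd_beta <- sqrt(sh$alpha * sh$beta /
                    ((sh$alpha + sh$beta)^2 * (sh$alpha + sh$beta + 1)))
  expect_equal(mean_beta, 0.74, tolerance = 1e-9)
  expect_equal(sd_beta, sh$se, tolerance = 1e-9)

  # symmetric range about 0.5 gives equal shapes
  sym <- beta_from_mean_range(0.5, 0.3, 0.7)
  expect_equal(sym$alpha, sym$beta, tolerance = 1e-12)

  # SE -> 0: shapes diverge and draws concentrate at the mean
  conc <- beta_from_mean_range(0.5, 0.5 - 1.96e-4, 0.5 + 1.96e-4)
  expect_gt(conc$alpha, 1e5)
  set.seed(1)
  expect_equal(mean(rbeta(1000, conc$alpha, conc$beta)), 0.5,
               tolerance = 1e-4)

  expect_error(beta_from_mean_range(0.5, 0, 2.1), "infeasible")
  expect_error(beta_from_mean_range(1.2, 0.1, 0.9), "\\(0, 1\\)")
})

test_that("gamma method-of-moments satisfies the moment identities", {
  g <- gamma_from_mean_range(960, 768, 1152)
  expect_equal(g$shape * g$scale, 960, tolerance = 1e-9)
  expect_equal(g$shape * g$scale^2, g$se^2, tolerance = 1e-9)

  g2 <- gamma_from_mean_range(100, 80, 120)
  expect_equal(round(g2$se, 3), 10.204)
  set.seed(2)
  draws <- rgamma(1e5, shape = g2$shape, scale = g2$scale)
  expect_lt(abs(mean(draws) - 100), 3 * g2$se / sqrt(1e5))

  expect_error(gamma_from_mean_range(-5, 1, 2), "domain error")
})

test_that("one-way DSA spreads are zero for unused or fixed parameters", {
  cfg <- paper_fixture()
  tornado <- one_way_dsa(cfg)
  expect_setequal(tornado$parameter, names(cfg$parameters))
  expect_true(all(diff(tornado$spread) <= 1e-9))  # sorted non-increasing
  # u_br/u_cm feed only the u_ps composition, never the engine; w_br fixed
  for (nm in c("u_br", "u_cm", "w_br")) {
    expect_equal(tornado$spread[tornado$parameter == nm], 0)
  }
})

test_that("one-way DSA endpoints match hand arithmetic for a pure cost knob", {
  cfg <- paper_fixture()
  base <- evaluate_config(cfg)$result
  p <- cfg$parameters$c_rt_crt
  tornado <- one_way_dsa(cfg, "c_rt_crt")
  # a CRT one-time cost shifts only incremental cost, QALYs untouched
  expect_equal(tornado$icer_low,
               (base$incremental_cost - 0.2 * p$base) /
                 base$incremental_effectiveness, tolerance = 1e-9)
  expect_equal(tornado$icer_high,
               (base$incremental_cost + 0.2 * p$base) /
                 base$incremental_effectiveness, tolerance = 1e-9)
})

test_that("zero-width ranges reproduce the base-case ICER everywhere", {
  cfg <- degenerate_fixture()
  base_icer <- evaluate_config(cfg)$result$icer
  tornado <- one_way_dsa(cfg)
  expect_equal(tornado$icer_low, rep(base_icer, nrow(tornado)),
               tolerance = 1e-12)
  expect_equal(tornado$icer_high, rep(base_icer, nrow(tornado)),
               tolerance = 1e-12)
  expect_equal(tornado$spread, rep(0, nrow(tornado)))
})

test_that("PSA is seeded, reproducible, and degenerates to the base case", {
  cfg <- degenerate_fixture()
  base <- evaluate_config(cfg)
  s <- run_psa(cfg, n_draws = 20, seed = 7)
  expect_equal(nrow(s), 20)
  expect_true(all(abs(s$cost_crt - base$arms$crt$cost) < 1e-9))
  expect_true(all(abs(s$qaly_uhrt - base$arms$uhrt$qaly) < 1e-9))

  full <- paper_fixture()
  a <- run_psa(full, n_draws = 25, seed = 123)
  b <- run_psa(full, n_draws = 25, seed = 123)
  expect_identical(a, b)
  c2 <- run_psa(full, n_draws = 25, seed = 124)
  expect_false(identical(a$cost_crt, c2$cost_crt))
  expect_error(run_psa(full, n_draws = 10), "seed")
})

test_that("PSA draws respect parameter domains and converge to printed means", {
  cfg <- paper_fixture()
  s <- run_psa(cfg, n_draws = 800, seed = 31)
  for (nm in c("u_ffs_crt", "u_ffs_uhrt", "u_ps", "u_br", "u_cm")) {
    expect_true(all(s[[nm]] >= 0 & s[[nm]] <= 1))
  }
  for (nm in c("c_rt_crt", "c_ut", "c_ps_monthly")) {
    expect_true(all(s[[nm]] >= 0))
  }
  # law of large numbers at the Monte Carlo rate
  for (nm in c("u_ps", "c_ut")) {
    p <- cfg$parameters[[nm]]
    se <- (p$high - p$low) / 3.92
    expect_lt(abs(mean(s[[nm]]) - p$base), 3 * se / sqrt(800))
  }
})

test_that("CEAC matches enumeration on hand-written draws and sums to one", {
  samples <- data.frame(
    draw = 1:2,
    cost_crt = c(10, 30), qaly_crt = c(2, 2),
    cost_uhrt = c(0, 0), qaly_uhrt = c(1, 1))
  # crt wins draw 1 iff wtp > 10, draw 2 iff wtp > 30; ties at equality
  curve <- ceac(samples, c(0, 20, 40), reference = "crt")
  expect_equal(curve$probability, c(0, 0.5, 1))
  tie <- ceac(samples, 10, reference = "crt")
  expect_equal(tie$probability, 0.25)  # draw 1 exactly indifferent

  other <- ceac(samples, c(0, 10, 20, 40), reference = "uhrt")
  both <- ceac(samples, c(0, 10, 20, 40), reference = "crt")
  expect_equal(both$probability + other$probability, rep(1, 4))

  expect_error(ceac(samples, numeric(0)), "non-empty")
})

test_that("CEAC limits reduce to cost and QALY orderings", {
  cfg <- paper_fixture()
  s <- run_psa(cfg, n_draws = 100, seed = 9)
  at0 <- ceac(s, 0, reference = "crt")$probability
  expect_equal(at0, mean((s$cost_crt < s$cost_uhrt) +
                           0.5 * (s$cost_crt == s$cost_uhrt)))
  at_inf <- ceac(s, 1e9, reference = "crt")$probability
  expect_equal(at_inf, mean((s$qaly_crt > s$qaly_uhrt) +
                              0.5 * (s$qaly_crt == s$qaly_uhrt)))
})

test_that("the WTP threshold search lands exactly on the ICER", {
  cfg <- paper_fixture()
  res <- evaluate_config(cfg)$result
  found <- threshold_search(cfg, "wtp", c(100, 200000))
  expect_true(found$found)
  expect_equal(found$crossover, res$icer, tolerance = 1e-6)
})

test_that("threshold search matches a closed-form crossover and reports absence", {
  cfg <- paper_fixture()
  # NMB difference is linear in u_ffs_uhrt (QALYs are linear in utilities):
  # solve for the crossover from two evaluations
  wtp <- cfg$settings$wtp_per_qaly
  f <- function(u) {
    r <- evaluate_config(cfg, c(u_ffs_uhrt = u))$result
    net_monetary_benefit(r$incremental_cost, r$incremental_effectiveness, wtp)
  }
  u1 <- 0.75; u2 <- 0.95
  slope <- (f(u2) - f(u1)) / (u2 - u1)
  analytic <- u1 - f(u1) / slope
  found <- threshold_search(cfg, "u_ffs_uhrt", c(u1, u2))
  expect_true(found$found)
  expect_equal(found$crossover, analytic, tolerance = 1e-6)

  none <- threshold_search(cfg, "c_ut", c(768, 1152))
  expect_false(none$found)
  expect_true(is.na(none$crossover))

  expect_error(threshold_search(cfg, "nope", c(0, 1)), "unknown knob")
})
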