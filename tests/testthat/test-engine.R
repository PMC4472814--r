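test_that("discounting and time-cost arithmetic follow their closed forms", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(round(discount_factor(4, 0.03), 5), 0.97087)
  expect_equal(discount_factor(40, 0), 1)
  ps <- test_ps()
  expect_equal(time_cost_quarter("treatment_q1", context = "APM",
                                 employment_prob = 1, ps = ps), 109 * 22.33)
  expect_equal(time_cost_quarter("treatment_q1", context = "PT",
                                 employment_prob = 1, ps = ps), 79 * 22.33)
  expect_equal(time_cost_quarter("later", pain = "low",
                                 employment_prob = 1, ps = ps), 30 * 22.33)
  expect_equal(time_cost_quarter("q2", pain = "moderate",
                                 employment_prob = 0.5, ps = ps),
               87 * 22.33 * 0.5)
  expect_equal(time_cost_quarter("later", pain = "moderate",
                                 employment_prob = 0, ps = ps), 0)
  # employment schedule: flat to the decline age, then linear to the floor
  expect_equal(employment_probability(50, ps), 0.60)
  expect_equal(employment_probability(64, ps), 0.60 - 0.5 * 6 / 12)
  expect_equal(employment_probability(80, ps), 0.10)
})

test_that("a single undiscounted moderate-pain quarter accrues u/4", {
  ps <- deathless_ps()
  ps$discount_rate_annual <- 0
  ps$horizon_years <- 0.25
  r <- run_strategy("PT", ps, life_table = zero_mortality_table())
  expect_equal(r$mean_qalys, 0.771 / 4, tolerance = 1e-12)
})

test_that("a zero horizon accrues nothing", {
  r <- run_strategy("PT", test_ps(), horizon_years = 0)
  expect_equal(r$mean_qalys, 0)
  expect_equal(r$mean_direct_cost, 0)
  expect_equal(r$mean_time_cost, 0)
})

test_that("cohort occupancy is conserved every quarter", {
  for (strat in strategies()) {
    r <- run_strategy(strat, test_ps())
    expect_lt(r$occupancy_error, 1e-10)
  }
  # and under sampled parameters
  r <- run_strategy("delayed_apm", sample_psa(test_ps(), 7))
  expect_lt(r$occupancy_error, 1e-10)
})

test_that("strategy results satisfy their structural invariants", {
  ps <- test_ps()
  for (strat in strategies()) {
    r <- run_strategy(strat, ps)
    expect_gte(r$mean_qalys, 0)
    expect_lte(r$mean_qalys, ps$horizon_years * ps$utilities$low_pain)
    expect_gte(r$mean_direct_cost, 0)
    expect_gte(r$mean_time_cost, 0)
    tr <- r$trajectory
    expect_true(all(tr$frac_moderate_pain >= 0 & tr$frac_moderate_pain <= 1))
    expect_true(all(diff(tr$cum_tka) >= -1e-12))
    expect_equal(trajectory_stats(r, 2)$frac_moderate_pain,
                 tr$frac_moderate_pain[2])
    expect_equal(trajectory_stats(r, 0)$cum_tka, 0)
    expect_error(trajectory_stats(r, 99), "horizon")
  }
})

test_that("QALYs fall when the moderate-pain utility falls", {
  ps <- test_ps()
  lo <- ps
  lo$utilities$moderate_pain <- 0.60
  for (strat in strategies())
    expect_lt(run_strategy(strat, lo)$mean_qalys,
              run_strategy(strat, ps)$mean_qalys)
})

test_that("discounting never increases totals and vanishes at r = 0", {
  ps <- test_ps()
  ps0 <- ps
  ps0$discount_rate_annual <- 0
  for (strat in strategies()) {
    rd <- run_strategy(strat, ps)
    ru <- run_strategy(strat, ps0)
    expect_lt(rd$mean_qalys, ru$mean_qalys)
    expect_lt(rd$mean_direct_cost, ru$mean_direct_cost)
    expect_lt(rd$mean_time_cost, ru$mean_time_cost)
  }
})

test_that("with identical pain efficacy the strategies differ only in cost", {
  ps <- deathless_ps()
  tp <- ps$treatment_pain
  for (b in c("kl02", "kl34")) {
    tp$failed_relief$APM[[b]] <- tp$failed_relief$PT[[b]]
    # crossover subjects face a single failed-relief draw in quarter 2;
    # aligning it with one-minus-resolution makes all arms' dynamics equal
    tp$failed_relief$APM_after_PT[[b]] <-
      dist_fixed(1 - tp$resolution_q2$PT[[b]]$mean)
    tp$incidence_q2$APM[[b]] <- tp$incidence_q2$PT[[b]]
    tp$resolution_q2$APM[[b]] <- tp$resolution_q2$PT[[b]]
  }
  ps$treatment_pain <- tp
  res <- lapply(strategies(), function(s) run_strategy(s, ps))
  q <- vapply(res, `[[`, numeric(1), "mean_qalys")
  expect_equal(q[2], q[1], tolerance = 1e-10)
  expect_equal(q[3], q[1], tolerance = 1e-10)
  cost <- vapply(res, `[[`, numeric(1), "mean_direct_cost")
  expect_gt(cost[3], cost[1])   # same health, extra procedure spending
})

test_that("microsimulation converges to the cohort expectation", {
  ps <- test_ps()
  n <- 50000
  co <- run_strategy("PT", ps)
  ms <- run_strategy("PT", ps, mode = "microsim", n_subjects = n, seed = 2024)
  expect_lt(abs(ms$mean_qalys - co$mean_qalys),
            3 * ms$sd_qalys / sqrt(n))
  expect_lt(abs(ms$mean_direct_cost - co$mean_direct_cost),
            3 * ms$sd_direct_cost / sqrt(n))
  # time costs carry a small systematic banding difference (entry-age bands
  # versus continuous ages in the employment schedule): allow 2% relative
  expect_lt(abs(ms$mean_time_cost - co$mean_time_cost) / co$mean_time_cost,
            0.02)
  expect_lt(abs(ms$trajectory$frac_moderate_pain[2] -
                  co$trajectory$frac_moderate_pain[2]), 0.01)
  expect_lt(abs(ms$trajectory$cum_tka[40] - co$trajectory$cum_tka[40]), 0.01)
  expect_error(run_strategy("PT", ps, mode = "microsim"), "n_subjects")
})

test_that("the delayed-efficacy scenario substitutes the immediate column", {
  ps <- test_ps()
  base <- run_strategy("delayed_apm", ps)
  same <- run_strategy("delayed_apm", ps,
                       delayed_efficacy = "same_as_immediate")
  # immediate APM relieves pain more often than APM after failed PT, so the
  # optimistic scenario must gain QALYs
  expect_gt(same$mean_qalys, base$mean_qalys)
  # other strategies unaffected
  expect_equal(run_strategy("PT", ps, delayed_efficacy = "same_as_immediate")
               $mean_qalys,
               run_strategy("PT", ps)$mean_qalys)
})

test_that("an APM progression penalty reduces QALYs only for APM strategies", {
  ps <- test_ps()
  for (strat in c("immediate_apm", "delayed_apm"))
    expect_lt(run_strategy(strat, ps, apm_progression_multiplier = 3)
              $mean_qalys,
              run_strategy(strat, ps)$mean_qalys)
  expect_equal(run_strategy("PT", ps, apm_progression_multiplier = 3)
               $mean_qalys,
               run_strategy("PT", ps)$mean_qalys)
})
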