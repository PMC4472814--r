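test_that("annual-to-quarterly conversion is the constant-hazard closed form", {
  expect_equal(to_quarterly(0), 0)
  expect_equal(to_quarterly(1), 1)
  expect_equal(to_quarterly(0.0735), 1 - (1 - 0.0735)^0.25)
  expect_equal(to_quarterly(0.0735), 0.01889, tolerance = 1e-3)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(to_quarterly(p)) > 0))
  expect_true(all(to_quarterly(p) <= p))
  expect_error(to_quarterly(1.1), "\\[0, 1\\]")
})

test_that("treatment-window pain transitions follow the published strata", {
  ps <- test_ps()
  expect_equal(pain_transition_treatment("APM", "kl02", "quarter1", ps = ps),
               29 / 90)
  expect_equal(pain_transition_treatment("PT", "kl34", "quarter1", ps = ps),
               26 / 37)
  expect_equal(
    pain_transition_treatment("APM", "kl02", "quarter2", "moderate", ps),
    1 - 14 / 29)
  expect_equal(
    pain_transition_treatment("APM", "kl02", "quarter2", "low", ps),
    14 / 61)
  # the crossover context has no months-3-6 window
  expect_equal(
    pain_transition_treatment("APM_after_PT", "kl34", "quarter1", ps = ps),
    6 / 9)
  expect_error(
    pain_transition_treatment("APM_after_PT", "kl02", "quarter2",
                              "moderate", ps),
    "no months-3-6")
  expect_error(pain_transition_treatment("TKA", "kl02", "quarter1", ps = ps))
})

test_that("OA-driven pain transitions apply quarterly-converted annual rates", {
  ps <- test_ps()
  expect_equal(round(pain_transition_oa(3, "low", ps), 5), 0.05783)
  expect_equal(round(pain_transition_oa(4, "moderate", ps), 5), 0.99875)
  ps0 <- ps
  ps0$oa_pain$incidence <- lapply(ps0$oa_pain$incidence, function(x) 0)
  expect_equal(pain_transition_oa(2, "low", ps0), 0)
})

test_that("KL progression steps one grade with age-banded incidence", {
  ps <- test_ps()
  expect_equal(kl_transition(4, 60, ps), c(kl01 = 0, kl2 = 0, kl3 = 0, kl4 = 1))
  tr2 <- kl_transition(2, 60, ps)
  expect_equal(unname(tr2["kl3"]), to_quarterly(0.0735))
  tr1 <- kl_transition(1, 58, ps)
  expect_equal(unname(tr1["kl2"]), to_quarterly(0.00668))
  expect_equal(sum(tr1), 1)
  # progression multiplier only acts on post-APM knees
  tr_m <- kl_transition(3, 60, ps, apm_progression_multiplier = 2,
                        had_apm = TRUE)
  expect_equal(unname(tr_m["kl4"]), to_quarterly(2 * 0.0267))
  expect_equal(kl_transition(3, 60, ps, 2, had_apm = FALSE),
               kl_transition(3, 60, ps))
  expect_warning(kl_transition(3, 60, ps, 100, had_apm = TRUE), "clamped")
})

test_that("the TKA gate requires advanced OA and six months of pain", {
  ps <- test_ps()
  expect_equal(tka_gate(2, 4, 58, ps), 0)
  expect_equal(tka_gate(3, 1, 58, ps), 0)
  expect_equal(round(tka_gate(3, 2, 58, ps), 5), 0.01640)
  expect_equal(tka_gate(4, 2, 70, ps), to_quarterly(0.119))
  expect_equal(tka_outcome(2, ps), 0.862)
  expect_equal(tka_outcome(9, ps), 0.960)
  ps1 <- ps
  ps1$tka_efficacy$first_year <- ps1$tka_efficacy$subsequent <- 1
  expect_equal(tka_outcome(1, ps1), 1)
})

test_that("adverse-event burdens match the published rates", {
  ps <- test_ps()
  apm <- adverse_event_burden("APM", ps)
  expect_equal(apm, list(prob = 0.015, cost = 11589, mortality = 0.011))
  tka <- adverse_event_burden("TKA", ps)
  expect_equal(tka$prob * tka$mortality, 0.036 * 0.006)
  pharm <- adverse_event_burden("pharm", ps)
  expect_equal(to_quarterly(pharm$prob), 0.02898, tolerance = 1e-3)
})

test_that("quarterly mortality uses floor age and errors below the table", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(age = 40:110,
                       annual_death_prob = c(rep(0.008, 70), 1)),
            path, row.names = FALSE)
  lt <- load_life_table(path)
  expect_equal(round(mortality_quarterly(58.9, lt), 6), 0.002006)
  expect_equal(mortality_quarterly(110, lt), 1)
  expect_equal(mortality_quarterly(115, lt), 1)  # beyond-cap ages use cap row
  expect_error(mortality_quarterly(35, lt), "below life-table range")
  lt0 <- zero_mortality_table()
  expect_equal(mortality_quarterly(60, lt0), 0)
})

test_that("every transition-matrix row is a probability distribution", {
  ps <- test_ps()
  lt <- load_life_table()
  for (age in c(47.5, 58, 64.75, 70, 86, 109)) {
    for (m in c(1, 2.5)) {
      M <- mtcea:::build_quarter_matrix(ps, age, lt, m)
      expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
      expect_true(all(M >= 0))
    }
  }
})

test_that("pain dynamics beyond month six are treatment-blind", {
  # the late-phase transition matrix has no dependence on which treatment
  # was received except through the APM flag, which only rescales KL
  # progression; with multiplier 1 the two flag blocks must be identical
  ps <- test_ps()
  lt <- load_life_table()
  M <- mtcea:::build_quarter_matrix(ps, 60, lt, 1)
  st <- mtcea:::.ss$states
  for (kl in 1:4) for (pain in 0:1) {
    i0 <- mtcea:::sidx(kl, pain, 0L, 0L, 0L)
    i1 <- mtcea:::sidx(kl, pain, 0L, 0L, 1L)
    # same outcome probabilities, targets differing only in the flag
    p0 <- M[i0, ]; p1 <- M[i1, ]
    expect_equal(sort(p0[p0 > 0]), sort(p1[p1 > 0]))
  }
})

test_that("a deathless, fully effective treatment clears pain from quarter 2", {
  ps <- deathless_ps()
  lt0 <- zero_mortality_table()
  # perfect treatment, no OA pain incidence, no progression back to pain
  for (cx in c("APM", "APM_after_PT", "PT")) for (b in c("kl02", "kl34")) {
    ps$treatment_pain$failed_relief[[cx]][[b]] <- dist_fixed(0)
    ps$treatment_pain$incidence_q2[[cx]][[b]] <- dist_fixed(0)
  }
  ps$oa_pain$incidence <- lapply(ps$oa_pain$incidence, function(x) 0)
  ps$discount_rate_annual <- 0
  for (strat in strategies()) {
    r <- run_strategy(strat, ps, life_table = lt0)
    expect_equal(max(r$trajectory$frac_moderate_pain), 0)
    expect_equal(max(r$trajectory$cum_tka), 0)
    # hand accrual: one moderate quarter, then 39 low-pain quarters
    expect_equal(r$mean_qalys, 0.25 * 0.771 + 39 * 0.25 * 0.869,
                 tolerance = 1e-10)
  }
})
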