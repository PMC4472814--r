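test_that("beta specs reproduce the published count parameterisation", {
  # (events, non-events, published mean) for every pain-transition stratum
  tab <- list(
    c(29, 61, 0.322), c(21, 22, 0.488), c(6, 9, 0.400), c(6, 3, 0.667),
    c(58, 44, 0.569), c(26, 11, 0.703),
    c(14, 47, 0.230), c(8, 14, 0.364), c(10, 34, 0.227), c(2, 9, 0.182),
    c(14, 15, 0.483), c(7, 14, 0.333), c(9, 49, 0.155), c(3, 23, 0.115))
  for (row in tab) {
    spec <- beta_from_counts(row[1], row[2])
    expect_equal(spec$a, row[1])
    expect_equal(spec$b, row[2])
    expect_equal(spec$mean, row[1] / (row[1] + row[2]))
    expect_lt(abs(spec$mean - row[3]), 5e-4)
  }
  expect_equal(beta_from_counts(1, 0)$mean, 1)
  expect_equal(beta_from_counts(0, 5)$mean, 0)
  expect_error(beta_from_counts(0, 0), "empty stratum")
  expect_error(beta_from_counts(-1, 2), "non-negative")
})

test_that("gamma specs expose both the distribution and the published mean", {
  g <- dist_gamma(351, 0.8, mean = 439)
  expect_equal(g$a / g$b, 438.75)
  expect_equal(g$mean, 439)
  expect_equal(dist_gamma(1, 1)$mean, 1)
  # several published rows disagree with alpha/lambda; they must be flagged
  expect_warning(dist_gamma(129, 0.5, mean = 276), "PSA samples use")
  expect_error(dist_gamma(-1, 1), "alpha > 0")
  expect_error(dist_gamma(1, 0), "alpha > 0")
})

test_that("the packaged configuration reproduces the published table", {
  ps <- test_ps()
  expect_s3_class(ps, "mt_params")
  expect_equal(ps$utilities$low_pain, 0.869)
  expect_equal(ps$utilities$moderate_pain, 0.771)
  expect_equal(ps$cohort$kl_shares, c(0.448, 0.264, 0.288, 0))
  expect_equal(ps$treatment_pain$failed_relief$APM$kl02$a, 29)
  expect_equal(ps$costs$pt_rehab$mean, 568)
  expect_equal(ps$time_costs$wage, 22.33)
  expect_equal(ps$discount_rate_annual, 0.03)
  expect_equal(ps$horizon_years, 10)
  # loading the same file again gives the identical structure
  ps2 <- suppressWarnings(load_parameters(default_config_path()))
  attr(ps2, "config_path") <- attr(ps, "config_path")
  expect_identical(ps, ps2)
})

test_that("configuration validation names the offending key", {
  bad_shares <- config_with(function(cfg) {
    cfg$cohort$kl_shares <- c(0.4, 0.2, 0.3, 0.0)
    cfg
  })
  expect_error(suppressWarnings(load_parameters(bad_shares)),
               "kl_shares.*sum to 1")
  bad_cost <- config_with(function(cfg) {
    cfg$costs$apm_procedure <- -10
    cfg
  })
  expect_error(suppressWarnings(load_parameters(bad_cost)),
               "costs.apm_procedure")
  missing_key <- config_with(function(cfg) {
    cfg$costs$pt_rehab <- NULL
    cfg
  })
  expect_error(suppressWarnings(load_parameters(missing_key)),
               "costs.pt_rehab")
  bad_prob <- config_with(function(cfg) {
    cfg$oa_pain$incidence$kl3 <- 1.2
    cfg
  })
  expect_error(suppressWarnings(load_parameters(bad_prob)), "oa_pain")
  expect_error(load_parameters(tempfile()), "not found")
})

test_that("PSA sampling is seed-reproducible and leaves fixed entries alone", {
  ps <- test_ps()
  d1 <- sample_psa(ps, 42)
  d2 <- sample_psa(ps, 42)
  attr(d1, "config_path") <- attr(d2, "config_path") <- NULL
  expect_identical(d1, d2)
  d3 <- sample_psa(ps, 43)
  expect_false(identical(
    d1$treatment_pain$failed_relief$APM$kl02$mean,
    d3$treatment_pain$failed_relief$APM$kl02$mean))
  # fixed entries unchanged
  expect_equal(d1$costs$apm_procedure$mean, 2867)
  expect_equal(d1$kl_progression$kl2_to_kl3, 0.0735)
  # a fully fixed set is a fixed point of sampling
  fixed <- ps
  for (p in psa_sampled_paths(ps))
    fixed <- mtcea:::set_path(fixed, p,
                              dist_fixed(mtcea:::get_path(fixed, p)$mean))
  expect_length(psa_sampled_paths(fixed), 0)
  refixed <- sample_psa(fixed, 7)
  expect_equal(mtcea:::extract_engine_params(refixed),
               mtcea:::extract_engine_params(fixed))
})

test_that("every sampled parameter set satisfies the structural invariants", {
  ps <- test_ps()
  for (seed in 1:300)
    expect_silent(validate_parameters(sample_psa(ps, seed)))
})

test_that("beta draws match their analytic moments", {
  spec <- dist_beta(29, 61)
  n <- 5e4
  set.seed(99)
  x <- vapply(seq_len(n), function(i) mtcea:::draw_dist(spec), numeric(1))
  m <- 29 / 90
  v <- 29 * 61 / (90^2 * 91)
  se_mean <- sqrt(v / n)
  # SE of the sample variance of an approximately normal variate
  se_var <- v * sqrt(2 / (n - 1))
  expect_lt(abs(mean(x) - m), 3 * se_mean)
  expect_lt(abs(var(x) - v), 4 * se_var)

  # through the full sampling path: law of large numbers on one leaf
  draws <- vapply(1:5000, function(i)
    sample_psa(test_ps(), child_seed(5, i))$treatment_pain$
      failed_relief$APM$kl02$mean, numeric(1))
  expect_lt(abs(mean(draws) - m), 0.005)
})
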