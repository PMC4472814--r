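#' Per-person expected value of perfect information
#'
#' The mean (over PSA iterations) of the best attainable net monetary
#' benefit, minus the net monetary benefit of the best decision made with
#' current information: `mean(max_s NMB) - max_s(mean NMB)`. This is the
#' expected cost, per treated person, of decision uncertainty.
#'
#' @param nmb_mat An iterations x strategies NMB matrix (e.g. from
#'   [nmb_matrix()]), at least 2 x 2.
#' @return USD per person (non-negative).
#' @examples
#' evpi(matrix(c(1, 0, 0, 1), 2, 2))  # 0.5
#' @export
evpi <- function(nmb_mat) {
  nmb_mat <- as.matrix(nmb_mat)
  if (!nrow(nmb_mat) || ncol(nmb_mat) < 2L)
    stop("EVPI needs at least 2 strategies and 1 iteration", call. = FALSE)
  mean(do.call(pmax, as.data.frame(nmb_mat))) - max(colMeans(nmb_mat))
}

#' EVPI as a function of willingness to pay
#'
#' @param psa An `mt_psa` object.
#' @param wtp_grid Thresholds (USD/QALY).
#' @param include_time_costs See [psa_costs()].
#' @return A data.frame `wtp`, `evpi_pp`.
#' @export
evpi_curve <- function(psa, wtp_grid = wtp_grid_default(),
                       include_time_costs = psa$include_time_costs) {
  cost <- psa_costs(psa, include_time_costs)
  data.frame(wtp = wtp_grid,
             evpi_pp = vapply(wtp_grid,
                              function(w) evpi(nmb(cost, psa$qalys, w)),
                              numeric(1L)))
}

#' Parameter groups available for partial value-of-information analysis
#'
#' @return Named list mapping group names to the sampled parameter leaves
#'   they contain: `delayed_apm_efficacy` (the APM-after-PT failed-relief
#'   distributions), `apm_progression` (the progression multiplier; not
#'   sampled in the default configuration, so its EVPPI is 0),
#'   `pain_management_costs`, `time_costs`, and `all` (every sampled leaf).
#' @export
evppi_groups <- function() {
  list(
    delayed_apm_efficacy = c(
      "treatment_pain.failed_relief.APM_after_PT.kl02",
      "treatment_pain.failed_relief.APM_after_PT.kl34"),
    apm_progression = character(0),
    pain_management_costs = c("costs.pain_mgmt_moderate",
                              "costs.pain_mgmt_low"),
    time_costs = paste0("time_costs.", c(
      "hours_q1_apm", "hours_q1_pt", "hours_q2_moderate", "hours_q2_low",
      "hours_later_moderate", "hours_later_low")),
    all = .dist_paths)
}

#' Nested Monte Carlo estimator of partial perfect information value
#'
#' Two-level estimator for the expected value of perfect information about a
#' subset ("group") of parameters: the outer loop fixes the group at a
#' fresh draw, the inner loop samples the remaining parameters and averages
#' strategy NMBs; EVPPI is the mean over outer draws of the best
#' conditional-mean NMB, minus the best overall-mean NMB (floored at zero).
#' This is assumption-free (no regression smoothing) but quadratic in cost.
#'
#' @param ps An `mt_params` object.
#' @param group A group name from [evppi_groups()] or a character vector of
#'   sampled-parameter paths (empty vector: EVPPI is 0 by definition).
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param outer_n,inner_n Outer / inner sample sizes (>= 2).
#' @param seed Master seed.
#' @param ... Engine options (see [run_strategy()]).
#' @return USD per person.
#' @export
evppi_nested <- function(ps, group, wtp, outer_n = 500, inner_n = 500,
                         seed = 1, ...) {
  stopifnot(inherits(ps, "mt_params"), outer_n >= 2, inner_n >= 2)
  if (length(group) == 1L && group %in% names(evppi_groups()))
    group <- evppi_groups()[[group]]
  bad <- setdiff(group, .dist_paths)
  if (length(bad))
    stop(sprintf("unknown parameter group member(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (!length(group)) return(0)
  opts <- engine_options(ps, ...)
  gcols <- engine_cols_for_paths(group)

  inner_nmb <- matrix(NA_real_, outer_n, length(strategies()))
  for (o in seq_len(outer_n)) {
    outer_draw <- extract_engine_params(
      sample_psa(ps, child_seed(seed, 1000000 + o)))
    seeds <- vapply(seq_len(inner_n),
                    function(i) child_seed(seed, o * 10000L + i), integer(1L))
    P <- t(vapply(seeds,
                  function(s) extract_engine_params(sample_psa(ps, s)),
                  numeric(length(.engine_par_names))))
    colnames(P) <- .engine_par_names
    P[, gcols] <- rep(outer_draw[gcols], each = inner_n)  # group held fixed
    res <- lapply(strategies(), function(strat)
      cohort_run_multi(strat, ps, P, opts, keep_trajectory = FALSE))
    cost <- vapply(res, function(r) mean(r$direct_cost +
      if (isTRUE(opts$include_time_costs)) r$time_cost else 0), numeric(1L))
    q <- vapply(res, function(r) mean(r$qalys), numeric(1L))
    inner_nmb[o, ] <- nmb(cost, q, wtp)
  }
  max(0, mean(apply(inner_nmb, 1L, max)) - max(colMeans(inner_nmb)))
}

# map parameter-set leaf paths to engine parameter-matrix columns
engine_cols_for_paths <- function(paths) {
  map <- c(
    "treatment_pain.failed_relief.APM.kl02" = "pfail_APM_kl02",
    "treatment_pain.failed_relief.APM.kl34" = "pfail_APM_kl34",
    "treatment_pain.failed_relief.APM_after_PT.kl02" = "pfail_XO_kl02",
    "treatment_pain.failed_relief.APM_after_PT.kl34" = "pfail_XO_kl34",
    "treatment_pain.failed_relief.PT.kl02" = "pfail_PT_kl02",
    "treatment_pain.failed_relief.PT.kl34" = "pfail_PT_kl34",
    "treatment_pain.incidence_q2.APM.kl02" = "inc_APM_kl02",
    "treatment_pain.incidence_q2.APM.kl34" = "inc_APM_kl34",
    "treatment_pain.incidence_q2.PT.kl02" = "inc_PT_kl02",
    "treatment_pain.incidence_q2.PT.kl34" = "inc_PT_kl34",
    "treatment_pain.resolution_q2.APM.kl02" = "res_APM_kl02",
    "treatment_pain.resolution_q2.APM.kl34" = "res_APM_kl34",
    "treatment_pain.resolution_q2.PT.kl02" = "res_PT_kl02",
    "treatment_pain.resolution_q2.PT.kl34" = "res_PT_kl34",
    "costs.apm_healthcare" = "c_apm_health",
    "costs.apm_rehab" = "c_apm_rehab",
    "costs.pt_healthcare" = "c_pt_health",
    "costs.pt_rehab" = "c_pt_rehab",
    "costs.pain_mgmt_moderate" = "c_pm_mod",
    "costs.pain_mgmt_low" = "c_pm_low",
    "time_costs.hours_q1_apm" = "h_q1_apm",
    "time_costs.hours_q1_pt" = "h_q1_pt",
    "time_costs.hours_q2_moderate" = "h_q2_mod",
    "time_costs.hours_q2_low" = "h_q2_low",
    "time_costs.hours_later_moderate" = "h_late_mod",
    "time_costs.hours_later_low" = "h_late_low")
  unname(map[intersect(paths, names(map))])
}

#' Generic nested-MC EVPPI for an arbitrary decision problem
#'
#' Used for validating the nested estimator against decision problems with
#' closed-form information value; the packaged model uses [evppi_nested()].
#'
#' @param draw_group,draw_rest Functions `(n)` returning an n-row matrix /
#'   vector of draws of the group and of the complementary parameters.
#' @param nmb_fun Function `(group_draws, rest_draws)` returning an
#'   n x strategies NMB matrix.
#' @param outer_n,inner_n Sample sizes.
#' @param seed Seed.
#' @return USD per person.
#' @export
evppi_nested_generic <- function(draw_group, draw_rest, nmb_fun,
                                 outer_n = 500, inner_n = 500, seed = 1) {
  set.seed(as.integer(seed))
  g <- draw_group(outer_n)
  if (is.null(dim(g))) g <- matrix(g, ncol = 1L)
  cond_max <- numeric(outer_n)
  cond_mean <- NULL
  for (o in seq_len(outer_n)) {
    rest <- draw_rest(inner_n)
    gm <- matrix(rep(g[o, ], each = inner_n), nrow = inner_n)
    nm <- colMeans(nmb_fun(gm, rest))
    cond_max[o] <- max(nm)
    cond_mean <- if (is.null(cond_mean)) nm / outer_n else cond_mean + nm / outer_n
  }
  max(0, mean(cond_max) - max(cond_mean))
}

#' Population value of information
#'
#' Scales per-person EVPI to the population facing the treatment decision
#' over the usable life of the information, discounting successive annual
#' cohorts: `evpi_pp * annual_count * sum_{t=0}^{years-1} (1+r)^-t`.
#'
#' @param evpi_pp Per-person EVPI (USD).
#' @param annual_count Persons facing the decision per year.
#' @param usable_years Usable life of the information (years).
#' @param r_annual Annual discount rate.
#' @return USD.
#' @examples
#' population_voi(734, 352000, 3, 0.03)  # about $752.7 million
#' @export
population_voi <- function(evpi_pp, annual_count, usable_years, r_annual = 0.03) {
  stopifnot(evpi_pp >= 0, annual_count >= 0, usable_years >= 0, r_annual >= 0)
  if (usable_years == 0) return(0)
  ann <- sum((1 + r_annual)^(-(seq_len(usable_years) - 1)))
  evpi_pp * annual_count * ann
}

#' Full value-of-information summary at one threshold
#'
#' @param psa An `mt_psa` object.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param annual_count Persons facing the decision annually.
#' @param usable_years Usable life of information (years).
#' @param r_annual Discount rate for population scaling.
#' @param include_time_costs See [psa_costs()].
#' @return List of class `mt_voi`: `wtp`, `evpi_pp`, `population_voi`,
#'   `qaly_equivalent` (population VOI / WTP) and the scaling assumptions.
#' @export
voi_summary <- function(psa, wtp, annual_count = 352000, usable_years = 3,
                        r_annual = 0.03,
                        include_time_costs = psa$include_time_costs) {
  e <- evpi(nmb_matrix(psa, wtp, include_time_costs))
  pv <- population_voi(e, annual_count, usable_years, r_annual)
  structure(list(wtp = wtp, evpi_pp = e, population_voi = pv,
                 qaly_equivalent = pv / wtp,
                 assumptions = list(annual_count = annual_count,
                                    usable_years = usable_years,
                                    r_annual = r_annual)),
            class = "mt_voi")
}

#' @export
print.mt_voi <- function(x, ...) {
  cat(sprintf("<mt_voi> WTP $%s/QALY\n", format(x$wtp, big.mark = ",")))
  cat(sprintf("  EVPI: $%.0f per person\n", x$evpi_pp))
  cat(sprintf("  population VOI: $%.1f million (%d persons/yr, %g yr, %g%%/yr)\n",
              x$population_voi / 1e6, x$assumptions$annual_count,
              x$assumptions$usable_years, 100 * x$assumptions$r_annual))
  cat(sprintf("  QALY equivalent: %.0f QALYs\n", x$qaly_equivalent))
  invisible(x)
}
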