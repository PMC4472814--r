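#' Generate synthetic individual-level trial records
#'
#' Produces subject-level records with the statistical structure the model's
#' first-year parameters assume: KL strata drawn from the cohort shares,
#' binomial 3-month pain outcomes per arm x KL band, 6-month outcomes from
#' the months-3-6 incidence/resolution probabilities, and gamma-distributed
#' quarterly costs and hours lost. The crossover arm mirrors the delayed
#' strategy: PT first-quarter probabilities, then — for subjects still in
#' moderate pain — the APM-after-PT failed-relief draw.
#'
#' No real trial data enter the package; these records exist so that the
#' estimation path from raw outcomes back to the parameter table can be
#' tested end to end.
#'
#' @param ps An `mt_params` object supplying the generating values.
#' @param n_per_arm Subjects per arm (>= 0).
#' @param employment_rate Probability a subject is employed.
#' @param seed Integer seed.
#' @return A data.frame of class `mt_trial` with one row per subject:
#'   `subject`, `arm` (`"APM"`, `"PT"`, `"PT_crossover_APM"`), `kl_band`,
#'   `pain_3mo`, `pain_6mo` (`"low"`/`"moderate"`), quarterly healthcare and
#'   rehab costs, `hours_lost_q1`, `hours_lost_q2`, `employed`.
#' @export
generate_trial <- function(ps, n_per_arm, employment_rate = 0.60, seed = 1) {
  stopifnot(inherits(ps, "mt_params"), n_per_arm >= 0)
  set.seed(as.integer(seed))
  arms <- c("APM", "PT", "PT_crossover_APM")
  if (n_per_arm == 0)
    return(structure(data.frame(subject = integer(0), arm = character(0),
                                kl_band = character(0), pain_3mo = character(0),
                                pain_6mo = character(0),
                                quarterly_cost_healthcare = numeric(0),
                                quarterly_cost_rehab = numeric(0),
                                hours_lost_q1 = numeric(0),
                                hours_lost_q2 = numeric(0),
                                employed = logical(0)),
                     class = c("mt_trial", "data.frame")))

  n <- 3L * n_per_arm
  arm <- rep(arms, each = n_per_arm)
  kl <- sample.int(4L, n, replace = TRUE, prob = ps$cohort$kl_shares)
  band <- ifelse(kl <= 2L, "kl02", "kl34")
  tp <- ps$treatment_pain
  pr <- function(block, ctx) {
    vapply(seq_len(n), function(i) block[[ctx[i]]][[band[i]]]$mean,
           numeric(1L))
  }

  ctx1 <- ifelse(arm == "APM", "APM", "PT")
  pain3 <- stats::runif(n) < pr(tp$failed_relief, ctx1)

  # months 3-6: crossover subjects in moderate pain receive APM
  cross <- arm == "PT_crossover_APM" & pain3
  p6 <- ifelse(pain3, 1 - pr(tp$resolution_q2, ctx1),
               pr(tp$incidence_q2, ctx1))
  p6[cross] <- pr(tp$failed_relief,
                  rep("APM_after_PT", n))[cross]
  pain6 <- stats::runif(n) < p6

  draw_g <- function(spec, k) stats::rgamma(k, shape = spec$a, rate = spec$b)
  hc <- ifelse(arm == "APM",
               draw_g(ps$costs$apm_healthcare, n),
               draw_g(ps$costs$pt_healthcare, n))
  rehab <- ifelse(arm == "APM",
                  draw_g(ps$costs$apm_rehab, n),
                  draw_g(ps$costs$pt_rehab, n))
  h1 <- ifelse(arm == "APM",
               draw_g(ps$time_costs$hours_q1_apm, n),
               draw_g(ps$time_costs$hours_q1_pt, n))
  h2 <- ifelse(pain3,
               draw_g(ps$time_costs$hours_q2_moderate, n),
               draw_g(ps$time_costs$hours_q2_low, n))

  structure(data.frame(
    subject = seq_len(n), arm = arm, kl_band = band,
    pain_3mo = ifelse(pain3, "moderate", "low"),
    pain_6mo = ifelse(pain6, "moderate", "low"),
    quarterly_cost_healthcare = hc,
    quarterly_cost_rehab = rehab,
    hours_lost_q1 = h1, hours_lost_q2 = h2,
    employed = stats::runif(n) < employment_rate),
    class = c("mt_trial", "data.frame"))
}

#' Method-of-moments gamma fit
#'
#' `alpha = mean^2 / var`, `lambda = mean / var`; degenerate samples (zero
#' variance) are unestimable.
#'
#' @param x Non-negative sample.
#' @return An `mt_dist` gamma spec, or `NULL` if unestimable.
#' @export
gamma_mom <- function(x) {
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= 0 || m <= 0) return(NULL)
  dist_gamma(m^2 / v, m / v, mean = m, mean_tol = Inf)
}

#' Re-estimate model parameters from trial records
#'
#' Closes the loop from individual-level outcomes back to the parameter
#' table: 3-month failed-relief and months-3-6 incidence/resolution
#' probabilities become beta distributions from stratum counts
#' ([beta_from_counts()]), and cost/hours distributions are fitted by gamma
#' method of moments. Strata with no subjects, and degenerate cost samples,
#' are flagged unestimable and left at the values in `ps`.
#'
#' @param records An `mt_trial` data.frame from [generate_trial()].
#' @param ps Parameter set to update (defaults to the packaged set).
#' @return A list: `params` (an `mt_params` with estimated leaves replaced),
#'   `estimated` (character vector of updated leaf paths), `unestimable`
#'   (paths that could not be estimated).
#' @export
estimate_from_trial <- function(records, ps = default_parameters()) {
  stopifnot(is.data.frame(records))
  est <- character(0); un <- character(0)
  put <- function(path, spec) {
    if (is.null(spec)) un <<- c(un, path)
    else { ps <<- set_path(ps, path, spec); est <<- c(est, path) }
  }
  count_beta <- function(success, total, path) {
    if (total == 0) un <<- c(un, path)
    else put(path, beta_from_counts(success, total - success))
  }

  for (bd in c("kl02", "kl34")) {
    # 3-month failed relief per treatment context
    sub <- records[records$arm == "APM" & records$kl_band == bd, ]
    count_beta(sum(sub$pain_3mo == "moderate"), nrow(sub),
               paste0("treatment_pain.failed_relief.APM.", bd))
    sub <- records[records$arm == "PT" & records$kl_band == bd, ]
    count_beta(sum(sub$pain_3mo == "moderate"), nrow(sub),
               paste0("treatment_pain.failed_relief.PT.", bd))
    xo <- records[records$arm == "PT_crossover_APM" &
                    records$kl_band == bd &
                    records$pain_3mo == "moderate", ]
    count_beta(sum(xo$pain_6mo == "moderate"), nrow(xo),
               paste0("treatment_pain.failed_relief.APM_after_PT.", bd))

    # months 3-6 incidence (among relieved) / resolution (among unrelieved)
    for (a in c("APM", "PT")) {
      sub <- records[records$arm == a & records$kl_band == bd, ]
      lo <- sub[sub$pain_3mo == "low", ]
      count_beta(sum(lo$pain_6mo == "moderate"), nrow(lo),
                 paste0("treatment_pain.incidence_q2.", a, ".", bd))
      hi <- sub[sub$pain_3mo == "moderate", ]
      count_beta(sum(hi$pain_6mo == "low"), nrow(hi),
                 paste0("treatment_pain.resolution_q2.", a, ".", bd))
    }
  }

  apm <- records[records$arm == "APM", ]
  pt <- records[records$arm %in% c("PT", "PT_crossover_APM"), ]
  put("costs.apm_healthcare", gamma_mom(apm$quarterly_cost_healthcare))
  put("costs.apm_rehab", gamma_mom(apm$quarterly_cost_rehab))
  put("costs.pt_healthcare", gamma_mom(pt$quarterly_cost_healthcare))
  put("costs.pt_rehab", gamma_mom(pt$quarterly_cost_rehab))
  put("time_costs.hours_q1_apm", gamma_mom(apm$hours_lost_q1))
  put("time_costs.hours_q1_pt", gamma_mom(pt$hours_lost_q1))
  put("time_costs.hours_q2_moderate",
      gamma_mom(records$hours_lost_q2[records$pain_3mo == "moderate"]))
  put("time_costs.hours_q2_low",
      gamma_mom(records$hours_lost_q2[records$pain_3mo == "low"]))

  validate_parameters(ps)
  list(params = ps, estimated = est, unestimable = un)
}
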