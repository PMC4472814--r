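#' Run one treatment strategy over the model horizon
#'
#' Evaluates a strategy under one parameter set, accruing discounted QALYs,
#' direct medical costs and productivity (time) costs over quarterly cycles.
#' In `"cohort"` mode the run is the exact expectation over the stratified
#' state distribution (entry-age bands x KL grade x pain x TKA status x
#' pain-duration counter); in `"microsim"` mode it is the mean over
#' `n_subjects` simulated individuals with sampled ages and KL grades.
#'
#' @param strategy `"PT"`, `"delayed_apm"` or `"immediate_apm"`.
#' @param ps An `mt_params` object (point estimates, or a [sample_psa()]
#'   draw).
#' @param ... Engine options: `horizon_years`, `include_time_costs`,
#'   `delayed_efficacy` (`"crossover"` uses the APM-after-PT efficacy for
#'   crossed-over subjects; `"same_as_immediate"` substitutes the immediate
#'   APM efficacy), `apm_progression_multiplier`, `mode`, `n_subjects`,
#'   `seed` (microsim), `life_table`. A single list may also be supplied.
#' @return An object of class `mt_strategy_result`: `mean_qalys` (discounted),
#'   `mean_direct_cost`, `mean_time_cost` (USD), a per-quarter `trajectory`
#'   data.frame (`frac_moderate_pain` among survivors, cumulative TKA
#'   fraction of the entry cohort) and run metadata.
#' @examples
#' \donttest{
#' ps <- default_parameters()
#' run_strategy("PT", ps)
#' }
#' @export
run_strategy <- function(strategy, ps, ...) {
  strategy <- match.arg(strategy, strategies())
  stopifnot(inherits(ps, "mt_params"))
  opts <- engine_options(ps, ...)
  if (opts$mode == "microsim") {
    if (is.null(opts$n_subjects))
      stop("microsim mode requires n_subjects", call. = FALSE)
    res <- microsim_run(strategy, ps, opts)
  } else {
    P <- matrix(extract_engine_params(ps), nrow = 1L,
                dimnames = list(NULL, .engine_par_names))
    res <- cohort_run_multi(strategy, ps, P, opts, keep_trajectory = TRUE)
  }
  structure(list(
    strategy = strategy,
    mode = opts$mode,
    n_subjects = opts$n_subjects,
    mean_qalys = unname(res$qalys[1L]),
    mean_direct_cost = unname(res$direct_cost[1L]),
    mean_time_cost = unname(res$time_cost[1L]),
    trajectory = res$trajectory,
    occupancy_error = res$occupancy_error,
    sd_qalys = res$sd_qalys,
    sd_direct_cost = res$sd_direct_cost,
    sd_time_cost = res$sd_time_cost,
    options = opts[c("horizon_years", "include_time_costs",
                     "delayed_efficacy", "apm_progression_multiplier")]
  ), class = "mt_strategy_result")
}

#' @export
print.mt_strategy_result <- function(x, ...) {
  cat(sprintf("<mt_strategy_result> %s (%s%s)\n",
              strategy_label(x$strategy), x$mode,
              if (!is.null(x$n_subjects)) paste0(", n=", x$n_subjects) else ""))
  cat(sprintf("  discounted QALYs: %.3f\n", x$mean_qalys))
  cat(sprintf("  direct medical cost: $%s\n",
              format(round(x$mean_direct_cost), big.mark = ",")))
  cat(sprintf("  time cost: $%s\n",
              format(round(x$mean_time_cost), big.mark = ",")))
  invisible(x)
}

#' Read a trajectory point from a strategy result
#'
#' @param result An `mt_strategy_result`.
#' @param quarter Quarter index (1-based, up to the horizon).
#' @return List with `frac_moderate_pain` (among survivors) and `cum_tka`
#'   (cumulative TKA fraction of the entry cohort) at the end of that
#'   quarter; `quarter = 0` returns the entry state.
#' @export
trajectory_stats <- function(result, quarter) {
  stopifnot(inherits(result, "mt_strategy_result"))
  if (quarter == 0)
    return(list(frac_moderate_pain = 1, cum_tka = 0))
  tr <- result$trajectory
  if (is.null(tr) || quarter < 0 || quarter > nrow(tr))
    stop("quarter outside the simulated horizon", call. = FALSE)
  list(frac_moderate_pain = tr$frac_moderate_pain[quarter],
       cum_tka = tr$cum_tka[quarter])
}

#' Run all three strategies and tabulate costs and effects
#'
#' @param ps An `mt_params` object.
#' @param ... Engine options passed to [run_strategy()].
#' @return A data.frame with one row per strategy: QALYs, direct cost, time
#'   cost, and total cost (direct plus time cost when
#'   `include_time_costs = TRUE`, otherwise direct only).
#' @export
run_all_strategies <- function(ps, ...) {
  opts <- engine_options(ps, ...)
  rows <- lapply(strategies(), function(s) {
    r <- run_strategy(s, ps, opts)
    data.frame(strategy = s, qalys = r$mean_qalys,
               direct_cost = r$mean_direct_cost,
               time_cost = r$mean_time_cost)
  })
  out <- do.call(rbind, rows)
  out$cost <- out$direct_cost +
    if (isTRUE(opts$include_time_costs)) out$time_cost else 0
  attr(out, "include_time_costs") <- isTRUE(opts$include_time_costs)
  out
}

# ---- patient-level microsimulation ----------------------------------------

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm((lo - mean) / sd),
                    stats::pnorm((hi - mean) / sd))
  mean + sd * stats::qnorm(u)
}

microsim_run <- function(strategy, ps, opts) {
  if (!is.null(opts$seed)) set.seed(as.integer(opts$seed))
  n <- as.integer(opts$n_subjects)
  lt <- opts$life_table
  m <- opts$apm_progression_multiplier
  nq <- as.integer(round(opts$horizon_years * 4))
  r <- ps$discount_rate_annual
  u_low <- ps$utilities$low_pain; u_mod <- ps$utilities$moderate_pain
  par <- extract_engine_params(ps)

  pharm_q <- to_quarterly(ps$adverse_events$pharm$prob_annual)
  pharm_mort <- pharm_q * ps$adverse_events$pharm$mortality
  pharm_cost <- pharm_q * ps$adverse_events$pharm$cost
  apm_ae_mort <- ps$adverse_events$APM$prob * ps$adverse_events$APM$mortality
  apm_ae_cost <- ps$adverse_events$APM$prob * ps$adverse_events$APM$cost
  tka_ae_mort <- ps$adverse_events$TKA$prob * ps$adverse_events$TKA$mortality
  tka_event_cost <- ps$costs$tka_procedure$mean +
    ps$adverse_events$TKA$prob * ps$adverse_events$TKA$cost
  apm_bundle <- ps$costs$apm_procedure$mean + par["c_apm_health"] +
    par["c_apm_rehab"] + apm_ae_cost
  pt_bundle <- par["c_pt_health"] + par["c_pt_rehab"]
  wage <- ps$time_costs$wage
  inc_q <- to_quarterly(unlist(ps$oa_pain$incidence))
  res_q <- to_quarterly(unlist(ps$oa_pain$resolution))
  e_first <- ps$tka_efficacy$first_year
  e_later <- ps$tka_efficacy$subsequent
  xo <- if (opts$delayed_efficacy == "same_as_immediate")
    c(par["pfail_APM_kl02"], par["pfail_APM_kl34"])
  else c(par["pfail_XO_kl02"], par["pfail_XO_kl34"])

  a0 <- strategy == "immediate_apm"
  age0 <- rtrunc_norm(n, ps$cohort$age_mean, ps$cohort$age_sd,
                      ps$cohort$age_min, ps$cohort$age_max)
  kl <- sample.int(4L, n, replace = TRUE, prob = ps$cohort$kl_shares)
  pain <- rep(TRUE, n)
  tka <- integer(n)          # quarters since TKA, 0 = none
  consec <- integer(n)
  apm <- rep(a0, n)
  alive <- rep(TRUE, n)

  qaly <- dcost <- tcost <- numeric(n)
  traj <- data.frame(quarter = seq_len(nq), frac_moderate_pain = NA_real_,
                     cum_tka = NA_real_)
  had_tka_count <- 0L

  klstep_p <- function(kl, age, apm)
    vapply(seq_along(kl), function(i)
      kl_step_quarterly(kl[i], age[i], ps, m, had_apm = apm[i]), numeric(1L))

  for (t in seq_len(nq)) {
    age_t <- age0 + (t - 1) / 4
    disc <- discount_factor(t - 1, r)

    # accrue the state occupied during this quarter
    qaly <- qaly + alive * disc * 0.25 * ifelse(pain, u_mod, u_low)
    dc <- alive * ifelse(pain, par["c_pm_mod"] + pharm_cost, par["c_pm_low"])
    if (t == 1L) dc <- dc + alive * (if (a0) apm_bundle else pt_bundle)
    if (t == 2L && strategy == "delayed_apm")
      dc <- dc + (alive & pain) * apm_bundle
    dcost <- dcost + disc * dc
    emp <- employment_relative(age_t, age0, ps)
    th <- if (t == 1L) {
      alive * par[if (a0) "h_q1_apm" else "h_q1_pt"]
    } else if (t == 2L && strategy == "delayed_apm") {
      alive * ifelse(pain, par["h_q1_apm"], par["h_q2_low"])
    } else if (t == 2L) {
      alive * ifelse(pain, par["h_q2_mod"], par["h_q2_low"])
    } else if (t == 3L && strategy == "delayed_apm") {
      # crossovers (operated at month 3) are in their months 3-6 phase
      alive * ifelse(apm,
                     ifelse(pain, par["h_q2_mod"], par["h_q2_low"]),
                     ifelse(pain, par["h_late_mod"], par["h_late_low"]))
    } else {
      alive * ifelse(pain, par["h_late_mod"], par["h_late_low"])
    }
    tcost <- tcost + disc * wage * emp * th

    # transitions: death, KL progression, treatment / TKA election, pain
    idx <- which(alive)
    if (length(idx)) {
      p_die <- mortality_quarterly(age_t[idx], lt) + pain[idx] * pharm_mort
      if (t == 1L && a0) p_die <- p_die + apm_ae_mort
      if (t == 2L && strategy == "delayed_apm")
        p_die <- p_die + pain[idx] * apm_ae_mort
      dies <- stats::runif(length(idx)) < pmin(1, p_die)
      alive[idx[dies]] <- FALSE
      idx <- idx[!dies]
    }
    if (length(idx)) {
      native <- idx[tka[idx] == 0L]
      if (length(native)) {
        up <- stats::runif(length(native)) <
          klstep_p(kl[native], age_t[native], apm[native])
        kl[native[up]] <- pmin(kl[native[up]] + 1L, 4L)
      }
      band <- ifelse(kl[idx] <= 2L, 1L, 2L)

      if (t == 1L) {
        pf <- par[c("pfail_PT_kl02", "pfail_PT_kl34")]
        if (a0) pf <- par[c("pfail_APM_kl02", "pfail_APM_kl34")]
        pain[idx] <- stats::runif(length(idx)) < pf[band]
        consec[idx] <- as.integer(pain[idx])
      } else if (t == 2L) {
        arm <- if (a0) "APM" else "PT"
        p_mod <- ifelse(pain[idx],
                        1 - par[paste0("res_", arm, "_kl", c("02", "34"))][band],
                        par[paste0("inc_", arm, "_kl", c("02", "34"))][band])
        if (strategy == "delayed_apm") {
          cross <- pain[idx]
          p_mod[cross] <- xo[band[cross]]
          apm[idx[cross]] <- TRUE
        }
        pain[idx] <- stats::runif(length(idx)) < p_mod
        consec[idx] <- ifelse(pain[idx], pmin(consec[idx] + 1L, 2L), 0L)
      } else {
        post <- idx[tka[idx] > 0L]
        if (length(post)) {
          eff <- ifelse(tka[post] + 1L <= 4L, e_first, e_later)
          tka[post] <- pmin(tka[post] + 1L, 5L)
          pain[post] <- stats::runif(length(post)) >= eff
        }
        nat <- idx[tka[idx] == 0L]
        if (length(nat)) {
          elig <- kl[nat] >= 3L & consec[nat] >= 2L
          p_tka <- ifelse(elig,
                          to_quarterly(band_lookup(ps$tka_uptake_by_age,
                                                   age_t[nat])), 0)
          elect <- stats::runif(length(nat)) < p_tka
          el <- nat[elect]
          if (length(el)) {
            had_tka_count <- had_tka_count + length(el)
            dcost[el] <- dcost[el] + disc * tka_event_cost
            peri_die <- stats::runif(length(el)) < tka_ae_mort
            alive[el[peri_die]] <- FALSE
            el <- el[!peri_die]
            tka[el] <- 1L
            pain[el] <- stats::runif(length(el)) >= e_first
            consec[el] <- 0L
          }
          nn <- nat[!elect]
          if (length(nn)) {
            p_mod <- ifelse(pain[nn], 1 - res_q[kl[nn]], inc_q[kl[nn]])
            pain[nn] <- stats::runif(length(nn)) < p_mod
            consec[nn] <- ifelse(pain[nn], pmin(consec[nn] + 1L, 2L), 0L)
          }
        }
      }
    }
    traj$frac_moderate_pain[t] <- if (any(alive))
      mean(pain[alive]) else NA_real_
    traj$cum_tka[t] <- had_tka_count / n
  }

  list(qalys = mean(qaly), direct_cost = mean(dcost), time_cost = mean(tcost),
       trajectory = traj, occupancy_error = 0,
       sd_qalys = stats::sd(qaly), sd_direct_cost = stats::sd(dcost),
       sd_time_cost = stats::sd(tcost))
}
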