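#' Strategy identifiers
#'
#' The three modelled strategies: physical therapy alone (`"PT"`), PT
#' followed by APM for subjects still in moderate pain after the first
#' quarter (`"delayed_apm"`), and APM as first-line treatment
#' (`"immediate_apm"`).
#' @export
strategies <- function() c("PT", "delayed_apm", "immediate_apm")

#' Strategy display labels
#' @param ids Character vector of strategy ids.
#' @return Labels used in published-style tables.
#' @export
strategy_label <- function(ids) {
  c(PT = "PT", delayed_apm = "Delayed APM",
    immediate_apm = "Immediate APM")[ids]
}

#' Present-value discount factor for a quarterly cycle
#'
#' @param quarter_index 0-based quarter index (the first cycle is
#'   undiscounted).
#' @param r_annual Annual discount rate.
#' @return `(1 + r_annual)^(-quarter_index / 4)`.
#' @examples
#' discount_factor(4, 0.03)  # 0.97087
#' @export
discount_factor <- function(quarter_index, r_annual) {
  stopifnot(all(quarter_index >= 0))
  (1 + r_annual)^(-quarter_index / 4)
}

#' Absolute likelihood of employment by age
#'
#' Piecewise-linear schedule: constant at `baseline` until
#' `decline_start_age`, declining linearly to `floor_value` at `floor_age`,
#' constant thereafter.
#'
#' @param age Age in years (vectorised).
#' @param ps An `mt_params` object (uses its `employment` block).
#' @return Probability of employment.
#' @export
employment_probability <- function(age, ps) {
  e <- ps$employment
  frac <- pmin(1, pmax(0, (age - e$decline_start_age) /
                          (e$floor_age - e$decline_start_age)))
  e$baseline - (e$baseline - e$floor_value) * frac
}

# Relative employment adjustment, normalised to 1 at cohort entry: the
# published hours already average employed and unemployed subjects at entry,
# so only the *decline* in employment with age rescales later-phase losses.
employment_relative <- function(age, entry_age, ps) {
  employment_probability(age, ps) / employment_probability(entry_age, ps)
}

#' Productivity (time) cost of one quarter
#'
#' Hours lost by phase and context/pain state, valued at the mean hourly
#' wage and weighted by an employment probability. The packaged hours are
#' already employment-weighted at cohort entry, so engine accrual passes the
#' *relative* employment adjustment here.
#'
#' @param phase `"treatment_q1"` (months 0-3), `"q2"` (months 3-6) or
#'   `"later"`.
#' @param context Treatment context `"APM"` or `"PT"` (phase
#'   `"treatment_q1"` only).
#' @param pain `"low"` or `"moderate"` (phases `"q2"` and `"later"`).
#' @param employment_prob Employment weight in `[0, 1]`.
#' @param ps An `mt_params` object.
#' @return USD for the quarter.
#' @examples
#' ps <- default_parameters()
#' time_cost_quarter("treatment_q1", context = "APM", employment_prob = 1, ps = ps)
#' @export
time_cost_quarter <- function(phase, context = NULL, pain = NULL,
                              employment_prob, ps) {
  phase <- match.arg(phase, c("treatment_q1", "q2", "later"))
  stopifnot(employment_prob >= 0, employment_prob <= 1)
  tc <- ps$time_costs
  hours <- if (phase == "treatment_q1") {
    context <- match.arg(context, c("APM", "PT"))
    if (context == "APM") tc$hours_q1_apm$mean else tc$hours_q1_pt$mean
  } else {
    pain <- match.arg(pain, c("low", "moderate"))
    key <- paste0("hours_", if (phase == "q2") "q2" else "later", "_", pain)
    tc[[key]]$mean
  }
  hours * tc$wage * employment_prob
}

# ---- engine parameter vector -----------------------------------------------

# Quantities that vary across PSA draws, flattened to a named vector so the
# cohort engine can run all draws simultaneously.
.engine_par_names <- c(
  "pfail_APM_kl02", "pfail_APM_kl34",
  "pfail_XO_kl02", "pfail_XO_kl34",
  "pfail_PT_kl02", "pfail_PT_kl34",
  "inc_APM_kl02", "inc_APM_kl34", "inc_PT_kl02", "inc_PT_kl34",
  "res_APM_kl02", "res_APM_kl34", "res_PT_kl02", "res_PT_kl34",
  "c_apm_health", "c_apm_rehab", "c_pt_health", "c_pt_rehab",
  "c_pm_mod", "c_pm_low",
  "h_q1_apm", "h_q1_pt", "h_q2_mod", "h_q2_low", "h_late_mod", "h_late_low")

extract_engine_params <- function(ps) {
  tp <- ps$treatment_pain
  v <- c(
    tp$failed_relief$APM$kl02$mean, tp$failed_relief$APM$kl34$mean,
    tp$failed_relief$APM_after_PT$kl02$mean, tp$failed_relief$APM_after_PT$kl34$mean,
    tp$failed_relief$PT$kl02$mean, tp$failed_relief$PT$kl34$mean,
    tp$incidence_q2$APM$kl02$mean, tp$incidence_q2$APM$kl34$mean,
    tp$incidence_q2$PT$kl02$mean, tp$incidence_q2$PT$kl34$mean,
    tp$resolution_q2$APM$kl02$mean, tp$resolution_q2$APM$kl34$mean,
    tp$resolution_q2$PT$kl02$mean, tp$resolution_q2$PT$kl34$mean,
    ps$costs$apm_healthcare$mean, ps$costs$apm_rehab$mean,
    ps$costs$pt_healthcare$mean, ps$costs$pt_rehab$mean,
    ps$costs$pain_mgmt_moderate$mean, ps$costs$pain_mgmt_low$mean,
    ps$time_costs$hours_q1_apm$mean, ps$time_costs$hours_q1_pt$mean,
    ps$time_costs$hours_q2_moderate$mean, ps$time_costs$hours_q2_low$mean,
    ps$time_costs$hours_later_moderate$mean, ps$time_costs$hours_later_low$mean)
  names(v) <- .engine_par_names
  v
}

# Entry age bands (5-year) with truncated-normal weights
age_bands <- function(ps) {
  co <- ps$cohort
  lo <- seq(co$age_min, co$age_max - 5, by = 5)
  hi <- lo + 5
  z <- function(a) stats::pnorm((a - co$age_mean) / co$age_sd)
  w <- z(hi) - z(lo)
  w <- w / sum(w)
  data.frame(mid = (lo + hi) / 2, weight = w)
}

engine_options <- function(ps, ...) {
  opts <- list(horizon_years = ps$horizon_years, include_time_costs = FALSE,
               delayed_efficacy = "crossover", apm_progression_multiplier = 1,
               mode = "cohort", n_subjects = NULL, seed = NULL,
               life_table = NULL)
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1L]]) && is.null(names(dots)))
    dots <- dots[[1L]]
  unknown <- setdiff(names(dots), names(opts))
  if (length(unknown))
    stop(sprintf("unknown engine option(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  opts[names(dots)] <- dots
  opts$delayed_efficacy <- match.arg(opts$delayed_efficacy,
                                     c("crossover", "same_as_immediate"))
  if (is.null(opts$life_table)) opts$life_table <- load_life_table()
  stopifnot(opts$horizon_years >= 0, opts$apm_progression_multiplier >= 0)
  opts
}

# ---- cohort engine ---------------------------------------------------------

# Runs one strategy for every row of the engine-parameter matrix `P`
# simultaneously (base case: one row of point estimates; PSA: one row per
# draw). Unsampled dynamics (OA pain, progression, mortality, TKA) are
# shared across rows, so quarters beyond the treatment window reduce to
# occupancy-matrix products with cached transition matrices.
cohort_run_multi <- function(strategy, ps, P, opts,
                             keep_trajectory = nrow(P) == 1L) {
  strategy <- match.arg(strategy, strategies())
  lt <- opts$life_table
  m <- opts$apm_progression_multiplier
  nq <- as.integer(round(opts$horizon_years * 4))
  nd <- nrow(P)
  n <- .ss$n; dead <- .ss$dead
  r <- ps$discount_rate_annual
  u_low <- ps$utilities$low_pain
  u_mod <- ps$utilities$moderate_pain

  pharm_q <- to_quarterly(ps$adverse_events$pharm$prob_annual)
  pharm_mort <- pharm_q * ps$adverse_events$pharm$mortality
  pharm_cost <- pharm_q * ps$adverse_events$pharm$cost
  apm_ae_mort <- ps$adverse_events$APM$prob * ps$adverse_events$APM$mortality
  apm_ae_cost <- ps$adverse_events$APM$prob * ps$adverse_events$APM$cost
  tka_event_cost <- ps$costs$tka_procedure$mean +
    ps$adverse_events$TKA$prob * ps$adverse_events$TKA$cost
  wage <- ps$time_costs$wage

  apm_bundle <- ps$costs$apm_procedure$mean + P[, "c_apm_health"] +
    P[, "c_apm_rehab"] + apm_ae_cost
  pt_bundle <- P[, "c_pt_health"] + P[, "c_pt_rehab"]

  a0 <- as.integer(strategy == "immediate_apm")
  xo_cols <- if (opts$delayed_efficacy == "same_as_immediate")
    c("pfail_APM_kl02", "pfail_APM_kl34") else c("pfail_XO_kl02", "pfail_XO_kl34")

  cache <- new.env(parent = emptyenv())
  get_M <- function(age) {
    key <- sprintf("%d", as.integer(floor(age)))
    if (is.null(cache[[key]]))
      cache[[key]] <- build_quarter_matrix(ps, age, lt, m)
    cache[[key]]
  }

  bands <- age_bands(ps)
  qalys <- dcost <- tcost <- numeric(nd)
  traj_mod_num <- traj_alive <- traj_tka <- if (keep_trajectory)
    matrix(0, nd, max(nq, 1L)) else NULL
  occ_err <- 0

  for (b in seq_len(nrow(bands))) {
    age0 <- bands$mid[b]
    wgt <- bands$weight[b]
    if (wgt <= 0) next

    occ <- matrix(0, nd, n)
    for (kl in 1:4) {
      s <- ps$cohort$kl_shares[kl]
      if (s > 0) occ[, sidx(kl, 1L, 0L, 0L, a0)] <- s
    }
    cum_tka <- numeric(nd)

    for (t in seq_len(nq)) {
      age_t <- age0 + (t - 1) / 4
      disc <- discount_factor(t - 1, r)
      p_alive <- 1 - occ[, dead]
      p_mod <- drop(occ %*% .ss$ind_mod)
      p_low <- p_alive - p_mod

      qalys <- qalys + wgt * disc * 0.25 * (u_low * p_low + u_mod * p_mod)
      dc <- p_mod * (P[, "c_pm_mod"] + pharm_cost) + p_low * P[, "c_pm_low"]
      if (t == 1L)
        dc <- dc + if (a0 == 1L) apm_bundle else pt_bundle
      if (t == 2L && strategy == "delayed_apm")
        dc <- dc + p_mod * apm_bundle
      dcost <- dcost + wgt * disc * dc

      emp <- employment_relative(age_t, age0, ps)
      # hour phases are anchored to each subject's index treatment: for
      # delayed-strategy crossovers (operated at month 3) quarter 2 is their
      # months 0-3 and quarter 3 their months 3-6
      th <- if (t == 1L) {
        p_alive * P[, if (a0 == 1L) "h_q1_apm" else "h_q1_pt"]
      } else if (t == 2L) {
        if (strategy == "delayed_apm")
          p_mod * P[, "h_q1_apm"] + p_low * P[, "h_q2_low"]
        else
          p_mod * P[, "h_q2_mod"] + p_low * P[, "h_q2_low"]
      } else if (t == 3L && strategy == "delayed_apm") {
        is_mod <- .ss$ind_mod == 1
        is_xo <- c(.ss$states$apm == 1L, FALSE)
        pm_x <- drop(occ %*% (is_mod & is_xo))
        pl_x <- drop(occ %*% (!is_mod & is_xo & .ss$ind_alive == 1))
        pm_n <- p_mod - pm_x
        pl_n <- p_low - pl_x
        pm_x * P[, "h_q2_mod"] + pl_x * P[, "h_q2_low"] +
          pm_n * P[, "h_late_mod"] + pl_n * P[, "h_late_low"]
      } else {
        p_mod * P[, "h_late_mod"] + p_low * P[, "h_late_low"]
      }
      tcost <- tcost + wgt * disc * wage * emp * th

      occ <- if (t == 1L) {
        transition_q1(occ, strategy, ps, P, age0, lt, m, a0)
      } else if (t == 2L) {
        transition_q2(occ, strategy, ps, P, age0 + 0.25, lt, m, a0, xo_cols)
      } else {
        occ %*% get_M(age_t)
      }
      occ_err <- max(occ_err, max(abs(rowSums(occ) - 1)))

      inflow <- drop(occ %*% .ss$ind_tka1)
      dcost <- dcost + wgt * disc * inflow * tka_event_cost
      cum_tka <- cum_tka + inflow

      if (keep_trajectory) {
        traj_mod_num[, t] <- traj_mod_num[, t] + wgt * drop(occ %*% .ss$ind_mod)
        traj_alive[, t] <- traj_alive[, t] + wgt * (1 - occ[, dead])
        traj_tka[, t] <- traj_tka[, t] + wgt * cum_tka
      }
    }
  }

  out <- list(qalys = qalys, direct_cost = dcost, time_cost = tcost,
              occupancy_error = occ_err)
  if (keep_trajectory && nq > 0) {
    out$trajectory <- data.frame(
      quarter = seq_len(nq),
      frac_moderate_pain = as.numeric(traj_mod_num[1L, ] / traj_alive[1L, ]),
      cum_tka = as.numeric(traj_tka[1L, ]))
  }
  out
}

# Quarter 1: everyone enters in moderate pain; the index treatment (APM for
# the immediate strategy, PT otherwise) determines the probability of failed
# pain relief, stratified by (post-progression) KL band.
transition_q1 <- function(occ, strategy, ps, P, age0, lt, m, a0) {
  nd <- nrow(occ)
  new <- matrix(0, nd, .ss$n)
  pf02 <- P[, if (a0 == 1L) "pfail_APM_kl02" else "pfail_PT_kl02"]
  pf34 <- P[, if (a0 == 1L) "pfail_APM_kl34" else "pfail_PT_kl34"]
  apm_ae_mort <- ps$adverse_events$APM$prob * ps$adverse_events$APM$mortality
  pharm_mort <- to_quarterly(ps$adverse_events$pharm$prob_annual) *
    ps$adverse_events$pharm$mortality
  p_die <- min(1, mortality_quarterly(age0, lt) + pharm_mort +
                  a0 * apm_ae_mort)

  for (kl in 1:4) {
    j0 <- sidx(kl, 1L, 0L, 0L, a0)
    w <- occ[, j0]
    if (all(w == 0)) next
    p_up <- kl_step_quarterly(kl, age0, ps, m, had_apm = a0 == 1L)
    for (step in 0:1) {
      w_kl <- if (step == 0L) 1 - p_up else p_up
      if (w_kl == 0) next
      kl2 <- min(kl + step, 4L)
      pf <- if (kl2 <= 2L) pf02 else pf34
      ww <- w * (1 - p_die) * w_kl
      jm <- sidx(kl2, 1L, 0L, 1L, a0)
      jl <- sidx(kl2, 0L, 0L, 0L, a0)
      new[, jm] <- new[, jm] + ww * pf
      new[, jl] <- new[, jl] + ww * (1 - pf)
    }
    new[, .ss$dead] <- new[, .ss$dead] + w * p_die
  }
  new[, .ss$dead] <- new[, .ss$dead] + occ[, .ss$dead]
  new
}

# Quarter 2 (months 3-6): subjects relieved at three months face the
# months-3-6 pain-incidence draw of their index treatment; unrelieved
# subjects face one minus pain resolution. In the delayed strategy every
# subject still in moderate pain crosses over to APM (probability 1) and
# instead faces the APM-after-PT failed-relief draw.
transition_q2 <- function(occ, strategy, ps, P, age, lt, m, a0, xo_cols) {
  nd <- nrow(occ)
  new <- matrix(0, nd, .ss$n)
  apm_ae_mort <- ps$adverse_events$APM$prob * ps$adverse_events$APM$mortality
  pharm_mort <- to_quarterly(ps$adverse_events$pharm$prob_annual) *
    ps$adverse_events$pharm$mortality
  q_bg <- mortality_quarterly(age, lt)
  arm <- if (a0 == 1L) "APM" else "PT"

  for (kl in 1:4) {
    for (pain in 0:1) {
      j0 <- sidx(kl, pain, 0L, pain, a0)   # consec tracks pain after q1
      w <- occ[, j0]
      if (all(w == 0)) next
      crossover <- strategy == "delayed_apm" && pain == 1L
      p_die <- min(1, q_bg + pain * pharm_mort +
                      (if (crossover) apm_ae_mort else 0))
      had_apm <- a0 == 1L || crossover
      p_up <- kl_step_quarterly(kl, age, ps, m, had_apm = had_apm)
      apm_new <- if (had_apm) 1L else 0L
      for (step in 0:1) {
        w_kl <- if (step == 0L) 1 - p_up else p_up
        if (w_kl == 0) next
        kl2 <- min(kl + step, 4L)
        band <- if (kl2 <= 2L) "kl02" else "kl34"
        p_mod <- if (crossover) {
          P[, xo_cols[if (band == "kl02") 1L else 2L]]
        } else if (pain == 0L) {
          P[, paste0("inc_", arm, "_", band)]
        } else {
          1 - P[, paste0("res_", arm, "_", band)]
        }
        ww <- w * (1 - p_die) * w_kl
        jm <- sidx(kl2, 1L, 0L, min(pain + 1L, 2L), apm_new)
        jl <- sidx(kl2, 0L, 0L, 0L, apm_new)
        new[, jm] <- new[, jm] + ww * p_mod
        new[, jl] <- new[, jl] + ww * (1 - p_mod)
      }
      new[, .ss$dead] <- new[, .ss$dead] + w * p_die
    }
  }
  new[, .ss$dead] <- new[, .ss$dead] + occ[, .ss$dead]
  new
}
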