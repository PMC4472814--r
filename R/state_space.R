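# Enumerated health-state space for the cohort engine.
#
# An alive state is (kl, pain, tka, consec, apm):
#   kl     1..4  : KL 0-1, KL 2, KL 3, KL 4
#   pain   0/1   : low / moderate (KOOS > 25)
#   tka    0..5  : 0 = native knee; k >= 1 = quarters since TKA (capped at 5,
#                  so 1-4 distinguishes the first post-operative year)
#   consec 0..2  : consecutive moderate-pain quarters counted after the
#                  initial treatment period (capped at the TKA gate of 2);
#                  forced to 0 once tka > 0
#   apm    0/1   : has undergone APM (drives the progression multiplier)
# plus one absorbing dead state.

make_state_space <- function() {
  g <- expand.grid(kl = 1:4, pain = 0:1, tka = 0:5, consec = 0:2, apm = 0:1)
  g <- g[!(g$tka > 0L & g$consec > 0L), , drop = FALSE]
  g <- g[order(g$apm, g$tka, g$consec, g$pain, g$kl), , drop = FALSE]
  rownames(g) <- NULL
  n_alive <- nrow(g)
  idx <- array(NA_integer_, dim = c(4L, 2L, 6L, 3L, 2L))
  idx[cbind(g$kl, g$pain + 1L, g$tka + 1L, g$consec + 1L, g$apm + 1L)] <-
    seq_len(n_alive)
  n <- n_alive + 1L
  list(states = g, idx = idx, n_alive = n_alive, dead = n, n = n,
       ind_mod = c(as.numeric(g$pain == 1L), 0),
       ind_alive = c(rep(1, n_alive), 0),
       ind_tka1 = c(as.numeric(g$tka == 1L), 0),
       ind_tka_any = c(as.numeric(g$tka > 0L), 0))
}

.ss <- make_state_space()

sidx <- function(kl, pain, tka, consec, apm) {
  .ss$idx[cbind(kl, pain + 1L, tka + 1L, consec + 1L, apm + 1L)]
}

# Quarterly transition matrix for the OA-driven ("late", beyond month 6)
# phase at a given age. Rows and columns are the full state space including
# dead; every row sums to one. All entries come from fixed (unsampled)
# parameters, so the matrix is shared across PSA iterations.
build_quarter_matrix <- function(ps, age, life_table,
                                 apm_progression_multiplier = 1) {
  st <- .ss$states
  n <- .ss$n
  dead <- .ss$dead

  pharm_q <- to_quarterly(ps$adverse_events$pharm$prob_annual)
  pharm_mort <- pharm_q * ps$adverse_events$pharm$mortality
  tka_ae_mort <- ps$adverse_events$TKA$prob * ps$adverse_events$TKA$mortality
  e_first <- ps$tka_efficacy$first_year
  e_later <- ps$tka_efficacy$subsequent

  p_die <- pmin(1, mortality_quarterly(age, life_table) +
                   st$pain * pharm_mort)
  surv <- 1 - p_die

  ii <- list(); jj <- list(); xx <- list()
  emit <- function(i, j, x) {
    keep <- x > 0
    if (any(keep)) {
      k <- length(ii) + 1L
      ii[[k]] <<- i[keep]; jj[[k]] <<- j[keep]; xx[[k]] <<- x[keep]
    }
  }

  rows <- seq_len(.ss$n_alive)
  emit(rows, rep(dead, length(rows)), p_die)

  # post-TKA: KL frozen, pain governed by prosthesis-year efficacy
  pt <- which(st$tka > 0L)
  if (length(pt)) {
    tka_new <- pmin(st$tka[pt] + 1L, 5L)
    eff <- tka_outcome(st$tka[pt] + 1L, ps)
    j_low <- sidx(st$kl[pt], 0L, tka_new, 0L, st$apm[pt])
    j_mod <- sidx(st$kl[pt], 1L, tka_new, 0L, st$apm[pt])
    emit(pt, j_low, surv[pt] * eff)
    emit(pt, j_mod, surv[pt] * (1 - eff))
  }

  # native knee: KL step, then TKA election, then pain update
  nt <- which(st$tka == 0L)
  p_up <- vapply(nt, function(r)
    kl_step_quarterly(st$kl[r], age, ps, apm_progression_multiplier,
                      had_apm = st$apm[r] == 1L), numeric(1L))
  uptake_q <- to_quarterly(band_lookup(ps$tka_uptake_by_age, age))
  inc_q <- to_quarterly(unlist(ps$oa_pain$incidence))
  res_q <- to_quarterly(unlist(ps$oa_pain$resolution))

  for (step in 0:1) {
    w_kl <- if (step == 0L) 1 - p_up else p_up
    kl_new <- pmin(st$kl[nt] + step, 4L)
    active <- which(w_kl > 0)
    if (!length(active)) next
    r <- nt[active]; w <- surv[r] * w_kl[active]; kl2 <- kl_new[active]

    elig <- kl2 >= 3L & st$consec[r] >= 2L
    p_tka <- ifelse(elig, uptake_q, 0)

    # election branch: peri-operative death, then first-year pain relief
    w_e <- w * p_tka
    emit(r, rep(dead, length(r)), w_e * tka_ae_mort)
    emit(r, sidx(kl2, 0L, 1L, 0L, st$apm[r]), w_e * (1 - tka_ae_mort) * e_first)
    emit(r, sidx(kl2, 1L, 1L, 0L, st$apm[r]), w_e * (1 - tka_ae_mort) * (1 - e_first))

    # no election: OA-driven pain dynamics
    w_s <- w * (1 - p_tka)
    p_mod <- ifelse(st$pain[r] == 0L, inc_q[kl2], 1 - res_q[kl2])
    consec_mod <- pmin(st$consec[r] + 1L, 2L)
    emit(r, sidx(kl2, 1L, 0L, consec_mod, st$apm[r]), w_s * p_mod)
    emit(r, sidx(kl2, 0L, 0L, 0L, st$apm[r]), w_s * (1 - p_mod))
  }

  M <- as.matrix(Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(n, n)))
  M[dead, dead] <- 1
  M
}
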