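#' Convert an annual probability to a quarterly probability
#'
#' Assumes a constant hazard within the year: `1 - (1 - p)^(1/4)`.
#' Maps 0 to 0 and 1 to 1 and is monotone in between.
#'
#' @param p_annual Annual probability (vectorised), in `[0, 1]`.
#' @return Quarterly probability of the same event.
#' @examples
#' to_quarterly(0.0735)  # 0.01889
#' @export
to_quarterly <- function(p_annual) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1))
    stop("annual probability must lie in [0, 1]", call. = FALSE)
  1 - (1 - p_annual)^0.25
}

band_lookup <- function(table, age) {
  idx <- findInterval(age, table$breaks)
  if (any(idx < 1L))
    stop("age below the first band of the schedule", call. = FALSE)
  table$values[idx]
}

#' Load an all-cause life table
#'
#' Reads a CSV with columns `age, annual_death_prob`. The packaged default is
#' a synthetic Gompertz approximation calibrated to published 2009 US
#' all-cause anchor points (it is *not* the official table); any table
#' covering the modelled ages can be substituted.
#'
#' @param path CSV path; defaults to the packaged synthetic table (ages
#'   40-110).
#' @return A data.frame of class `mt_life_table`.
#' @export
load_life_table <- function(path = system.file("extdata",
                                               "life_table_synthetic_us2009.csv",
                                               package = "mtcea",
                                               mustWork = TRUE)) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "annual_death_prob") %in% names(lt)))
    stop("life table must have columns 'age' and 'annual_death_prob'",
         call. = FALSE)
  if (is.unsorted(lt$age, strictly = TRUE) ||
      any(diff(lt$age) != 1L))
    stop("life table ages must be consecutive integers", call. = FALSE)
  if (any(lt$annual_death_prob < 0 | lt$annual_death_prob > 1))
    stop("life table probabilities must lie in [0, 1]", call. = FALSE)
  class(lt) <- c("mt_life_table", "data.frame")
  lt
}

annual_mortality <- function(life_table, age) {
  a <- floor(age)
  a <- pmin(a, max(life_table$age))       # beyond-table ages use the cap row
  idx <- a - life_table$age[1L] + 1L
  if (any(idx < 1L))
    stop(sprintf("age %s below life-table range starting at %d",
                 paste(unique(a[idx < 1L]), collapse = ","),
                 life_table$age[1L]), call. = FALSE)
  life_table$annual_death_prob[idx]
}

#' Quarterly background mortality
#'
#' @param age Current age in years (vectorised).
#' @param life_table An `mt_life_table` from [load_life_table()].
#' @return Quarterly probability of death from the annual probability at
#'   `floor(age)`; ages at or beyond the table cap use the final row.
#' @export
mortality_quarterly <- function(age, life_table) {
  to_quarterly(annual_mortality(life_table, age))
}

#' Quarterly pain-transition probability during the treatment window
#'
#' Months 0-3 (`phase = "quarter1"`) return the probability of failed pain
#' relief under the given treatment context; months 3-6 (`"quarter2"`) return
#' the probability of being in moderate pain next quarter: pain incidence for
#' subjects currently in low pain, one minus pain resolution for subjects in
#' moderate pain. The APM-after-PT context has no months-3-6 window (its
#' incidence/resolution entries are zero): its whole effect is the single
#' failed-relief draw in the quarter after surgery.
#'
#' @param context `"APM"`, `"APM_after_PT"` or `"PT"`.
#' @param kl_band `"kl02"` (KL 0-2) or `"kl34"` (KL 3-4).
#' @param phase `"quarter1"` or `"quarter2"`.
#' @param pain Current pain level, `"low"` or `"moderate"` (only used in
#'   quarter 2).
#' @param ps An `mt_params` object.
#' @return Probability of moderate pain next quarter.
#' @export
pain_transition_treatment <- function(context, kl_band, phase, pain = NULL,
                                      ps) {
  context <- match.arg(context, c("APM", "APM_after_PT", "PT"))
  kl_band <- match.arg(kl_band, c("kl02", "kl34"))
  phase <- match.arg(phase, c("quarter1", "quarter2"))
  if (phase == "quarter1")
    return(ps$treatment_pain$failed_relief[[context]][[kl_band]]$mean)
  if (context == "APM_after_PT")
    stop("APM_after_PT has no months-3-6 treatment window", call. = FALSE)
  pain <- match.arg(pain, c("low", "moderate"))
  if (pain == "low")
    ps$treatment_pain$incidence_q2[[context]][[kl_band]]$mean
  else
    1 - ps$treatment_pain$resolution_q2[[context]][[kl_band]]$mean
}

#' Quarterly OA-driven pain-transition probability (beyond month 6)
#'
#' After the six-month treatment-attribution window, pain dynamics depend
#' only on the underlying OA: annual incidence/resolution by KL grade,
#' converted to quarterly.
#'
#' @param kl KL grade group, 1 = KL 0-1, 2 = KL 2, 3 = KL 3, 4 = KL 4.
#' @param pain `"low"` or `"moderate"`.
#' @param ps An `mt_params` object.
#' @return Probability of moderate pain next quarter.
#' @export
pain_transition_oa <- function(kl, pain, ps) {
  pain <- match.arg(pain, c("low", "moderate"))
  if (pain == "low")
    to_quarterly(ps$oa_pain$incidence[[kl]])
  else
    1 - to_quarterly(ps$oa_pain$resolution[[kl]])
}

kl_step_quarterly <- function(kl, age, ps, multiplier = 1, had_apm = FALSE) {
  m <- if (had_apm) multiplier else 1
  p_annual <- switch(kl,
    band_lookup(ps$oa_incidence_by_age, age),   # KL 0-1 -> KL 2 (OA incidence)
    ps$kl_progression$kl2_to_kl3 * m,
    ps$kl_progression$kl3_to_kl4 * m,
    0)                                          # KL 4 absorbing
  if (p_annual > 1) {
    warning("KL progression probability exceeded 1 after multiplier; clamped",
            call. = FALSE)
    p_annual <- 1
  }
  to_quarterly(p_annual)
}

#' Quarterly KL-grade transition distribution
#'
#' At most one grade step per quarter: KL 0-1 progresses to KL 2 with the
#' age-specific quarterly OA incidence, KL 2 to KL 3 and KL 3 to KL 4 with
#' the quarterly equivalents of the annual progression probabilities
#' (optionally inflated by a multiplier for subjects with prior APM, used in
#' the progression sensitivity analysis), and KL 4 is absorbing.
#'
#' @param kl Current grade group (1-4 as in [pain_transition_oa()]).
#' @param age Current age.
#' @param ps An `mt_params` object.
#' @param apm_progression_multiplier Multiplier (>= 1) applied to structural
#'   progression when `had_apm`.
#' @param had_apm Whether the subject has undergone APM.
#' @return Named numeric vector of probabilities over grade groups 1-4.
#' @export
kl_transition <- function(kl, age, ps, apm_progression_multiplier = 1,
                          had_apm = FALSE) {
  stopifnot(kl %in% 1:4)
  p_up <- kl_step_quarterly(kl, age, ps, apm_progression_multiplier, had_apm)
  out <- numeric(4L)
  out[kl] <- 1 - p_up
  if (kl < 4L) out[kl + 1L] <- p_up else out[4L] <- 1
  names(out) <- c("kl01", "kl2", "kl3", "kl4")
  out
}

#' Quarterly probability of electing total knee arthroplasty
#'
#' TKA is available to subjects with advanced radiographic OA (KL 3 or 4) who
#' have been in moderate pain for at least six consecutive months after the
#' initial three-month treatment period (two counted quarters); the
#' age-specific annual uptake rate is converted to a quarterly probability.
#'
#' @param kl Grade group 1-4.
#' @param consecutive_moderate_quarters Counted consecutive moderate-pain
#'   quarters (post-treatment-period).
#' @param age Current age.
#' @param ps An `mt_params` object.
#' @return Quarterly election probability (0 when the gate is closed).
#' @export
tka_gate <- function(kl, consecutive_moderate_quarters, age, ps) {
  if (kl < 3L || consecutive_moderate_quarters < 2L) return(0)
  to_quarterly(band_lookup(ps$tka_uptake_by_age, age))
}

#' Probability of low pain after TKA
#'
#' @param quarters_since_tka Quarters elapsed since the replacement
#'   (1-4 = first year).
#' @param ps An `mt_params` object.
#' @return Probability of occupying the low-pain state this quarter.
#' @export
tka_outcome <- function(quarters_since_tka, ps) {
  stopifnot(quarters_since_tka >= 1)
  ifelse(quarters_since_tka <= 4, ps$tka_efficacy$first_year,
         ps$tka_efficacy$subsequent)
}

#' Adverse-event burden of a treatment exposure
#'
#' APM and TKA events are per procedure; pharmacologic pain-management events
#' are per year of moderate-pain pharmacologic exposure (converted to a
#' quarterly probability by the caller via [to_quarterly()]).
#'
#' @param event_source `"APM"`, `"TKA"` or `"pharm"`.
#' @param ps An `mt_params` object.
#' @return List with `prob` (per procedure, or annual for `"pharm"`),
#'   `cost` (USD per event) and `mortality` (probability of death given an
#'   event).
#' @export
adverse_event_burden <- function(event_source, ps) {
  event_source <- match.arg(event_source, c("APM", "TKA", "pharm"))
  ae <- ps$adverse_events[[event_source]]
  list(prob = if (event_source == "pharm") ae$prob_annual else ae$prob,
       cost = ae$cost, mortality = ae$mortality)
}
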