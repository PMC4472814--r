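# Default model parameters: US adults with symptomatic meniscal tear and
# knee osteoarthritis, 2013 USD. Probabilities carrying a beta spec and
# costs/hours carrying a gamma spec are sampled in probabilistic sensitivity
# analysis; everything else is fixed. Pain-transition probabilities are
# quarterly; OA pain, KL progression, OA incidence, TKA uptake and the
# pharmacologic adverse-event rate are annual.
cohort:
  age_mean: 58
  age_sd: 7
  age_min: 45
  age_max: 75
  kl_shares: [0.448, 0.264, 0.288, 0.0]   # KL 0-1, KL 2, KL 3, KL 4
kl_progression:           # annual probability of one-grade step
  kl2_to_kl3: 0.0735
  kl3_to_kl4: 0.0267
oa_incidence_by_age:      # annual probability KL 0-1 -> KL 2
  breaks: [45, 55, 65, 75, 85]
  values: [0.00379, 0.00668, 0.00375, 0.00306, 0.00310]
tka_uptake_by_age:        # annual probability of electing TKA when eligible
  breaks: [45, 65, 85]
  values: [0.064, 0.119, 0.030]
utilities:
  low_pain: 0.869
  moderate_pain: 0.771
  dead: 0.0
treatment_pain:           # quarterly, by strategy context and KL band
  failed_relief:          # months 0-3 after treatment start
    APM:
      kl02: {dist: beta, alpha: 29, beta: 61}
      kl34: {dist: beta, alpha: 21, beta: 22}
    APM_after_PT:
      kl02: {dist: beta, alpha: 6, beta: 9}
      kl34: {dist: beta, alpha: 6, beta: 3}
    PT:
      kl02: {dist: beta, alpha: 58, beta: 44}
      kl34: {dist: beta, alpha: 26, beta: 11}
  incidence_q2:           # months 3-6, among those relieved at 3 months
    APM:
      kl02: {dist: beta, alpha: 14, beta: 47}
      kl34: {dist: beta, alpha: 8, beta: 14}
    APM_after_PT:
      kl02: 0.0
      kl34: 0.0
    PT:
      kl02: {dist: beta, alpha: 10, beta: 34}
      kl34: {dist: beta, alpha: 2, beta: 9}
  resolution_q2:          # months 3-6, among those not relieved at 3 months
    APM:
      kl02: {dist: beta, alpha: 14, beta: 15}
      kl34: {dist: beta, alpha: 7, beta: 14}
    APM_after_PT:
      kl02: 0.0
      kl34: 0.0
    PT:
      kl02: {dist: beta, alpha: 9, beta: 49}
      kl34: {dist: beta, alpha: 3, beta: 23}
oa_pain:                  # annual, OA-driven, beyond month 6
  incidence:  {kl01: 0.075, kl2: 0.085, kl3: 0.212, kl4: 0.190}
  resolution: {kl01: 0.085, kl2: 0.037, kl3: 0.040, kl4: 0.005}
tka_efficacy:             # annual probability of low pain after TKA
  first_year: 0.862
  subsequent: 0.960
adverse_events:
  APM:   {prob: 0.015, mortality: 0.011, cost: 11589}
  TKA:   {prob: 0.036, mortality: 0.006, cost: 15149}
  pharm: {prob_annual: 0.111, mortality: 0.005, cost: 1816}
costs:                    # 2013 USD; treatment bundles quarterly at use
  apm_procedure: 2867.0
  apm_healthcare: {dist: gamma, alpha: 703, lambda: 1.5, mean: 454}
  apm_rehab:      {dist: gamma, alpha: 351, lambda: 0.8, mean: 439}
  pt_healthcare:  {dist: gamma, alpha: 117, lambda: 0.6, mean: 209}
  pt_rehab:       {dist: gamma, alpha: 352, lambda: 0.6, mean: 568}
  pain_mgmt_moderate: {dist: gamma, alpha: 129, lambda: 0.5, mean: 276}
  pain_mgmt_low:      {dist: gamma, alpha: 160, lambda: 1.6, mean: 99}
  tka_procedure: 20282.0
time_costs:               # hours lost per quarter, already employment-weighted
  hours_q1_apm:        {dist: gamma, alpha: 79, lambda: 0.7, mean: 109}
  hours_q1_pt:         {dist: gamma, alpha: 22, lambda: 0.3, mean: 79}
  hours_q2_moderate:   {dist: gamma, alpha: 32, lambda: 0.4, mean: 87}
  hours_q2_low:        {dist: gamma, alpha: 68, lambda: 1.6, mean: 42}
  hours_later_moderate: {dist: gamma, alpha: 94, lambda: 1.4, mean: 70}
  hours_later_low:      {dist: gamma, alpha: 89, lambda: 3.0, mean: 30}
  wage: 22.33
employment:               # relative likelihood-of-employment schedule
  baseline: 0.60
  floor_value: 0.10
  decline_start_age: 58
  floor_age: 70
discount_rate_annual: 0.03
horizon_years: 10
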