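# NSTEMI / unstable angina subgroup, <=150 mg aspirin.
# Subgroup-specific cost data exist for the acute MI hospitalisation only
# (3793 EUR); c_mi_y1 substitutes it into the overall first-year total
# (9558 - 4226 + 3793 = 9125).  All other costs equal the overall cohort.
cohort:
  label: NSTEMI/UA (ASA <= 150 mg)
  start_age: 62
  male_fraction: 0.72
  max_age: 110
  cohort_scale: 1
arms:
  ticagrelor:
    p_mi: 0.052
    p_stroke: 0.008
    p_death: 0.038
    u_no_event: 0.864
    u_mi: 0.794
    u_stroke: 0.736
    u_death: 0.275
  clopidogrel:
    p_mi: 0.058
    p_stroke: 0.009
    p_death: 0.050
    u_no_event: 0.863
    u_mi: 0.777
    u_stroke: 0.677
    u_death: 0.235
longterm:
  q_mi: 0.024
  q_stroke: 0.004
  q_cv_fatal: 0.023
  u_age_60_69: 0.864
  u_age_70_79: 0.826
  u_age_80plus: 0.762
  du_stroke_y1: 0.157
  du_stroke_y2plus: 0.157
  du_mi_y1: 0.078
  du_mi_y2plus: 0.078
hazard_ratios:
  hr_no_event: 1
  hr_mi_y1: 1.6
  hr_mi_y2plus: 1.4
  hr_stroke_y1: 3.23
  hr_stroke_y2plus: 1.5
costs:
  c_mi_y1: 9125
  c_stroke_y1: 14925
  c_mi_y2plus: 3421
  c_stroke_y2plus: 4336
  c_death: 8650
  c_no_event_annual: 0
  indirect_mi_y1: 2744
  indirect_stroke_y1: 4417
  indirect_stroke_y2plus: 4336
  dtc_ticagrelor: 2.90
  dtc_clopidogrel: 0.72
  drug_days: 365
  drug_death_fraction: 0.5
discount:
  rate_costs: 0.03
  rate_effects: 0.03
life_table: german_2009_synthetic
seed: 1
psa:
  n_iterations: 10000
  hr_log_sd: 0.2069
  utility_se: 0.02
  prob_n_effective: 5000
  weibull_draw: probability_beta
  threshold_from: 0
  threshold_to: 50000
  threshold_by: 1000
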