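# STEMI subgroup, <=150 mg aspirin.
# c_mi_y1 substitutes the STEMI acute hospitalisation cost (5648 EUR) into
# the overall first-year total (9558 - 4226 + 5648 = 10980).
cohort:
  label: STEMI (ASA <= 150 mg)
  start_age: 62
  male_fraction: 0.72
  max_age: 110
  cohort_scale: 1
arms:
  ticagrelor:
    p_mi: 0.026
    p_stroke: 0.008
    p_death: 0.032
    u_no_event: 0.891
    u_mi: 0.879
    u_stroke: 0.763
    u_death: 0.228
  clopidogrel:
    p_mi: 0.038
    p_stroke: 0.007
    p_death: 0.046
    u_no_event: 0.899
    u_mi: 0.855
    u_stroke: 0.833
    u_death: 0.281
longterm:
  q_mi: 0.016
  q_stroke: 0.003
  q_cv_fatal: 0.015
  u_age_60_69: 0.895
  u_age_70_79: 0.856
  u_age_80plus: 0.789
  du_stroke_y1: 0.097
  du_stroke_y2plus: 0.097
  du_mi_y1: 0.028
  du_mi_y2plus: 0.028
hazard_ratios:
  hr_no_event: 1
  hr_mi_y1: 1.6
  hr_mi_y2plus: 1.4
  hr_stroke_y1: 3.23
  hr_stroke_y2plus: 1.5
costs:
  c_mi_y1: 10980
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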