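# Overall ACS cohort, patients on <=150 mg aspirin maintenance dose.
# First-year probabilities/utilities are trial-observed; long-term annual
# probabilities are Weibull extrapolations held constant beyond year 2.
cohort:
  label: overall ACS (ASA <= 150 mg)
  start_age: 62
  male_fraction: 0.72
  max_age: 110
  cohort_scale: 1
arms:
  ticagrelor:
    p_mi: 0.041
    p_stroke: 0.008
    p_death: 0.036
    u_no_event: 0.875
    u_mi: 0.817
    u_stroke: 0.748
    u_death: 0.259
  clopidogrel:
    p_mi: 0.049
    p_stroke: 0.008
    p_death: 0.050
    u_no_event: 0.878
    u_mi: 0.801
    u_stroke: 0.720
    u_death: 0.249
longterm:
  q_mi: 0.021
  q_stroke: 0.004
  q_cv_fatal: 0.019
  u_age_60_69: 0.877
  u_age_70_79: 0.838
  u_age_80plus: 0.773
  du_stroke_y1: 0.143
  du_stroke_y2plus: 0.143
  du_mi_y1: 0.068
  du_mi_y2plus: 0.068
hazard_ratios:
  hr_no_event: 1
  hr_mi_y1: 1.6
  hr_mi_y2plus: 1.4
  hr_stroke_y1: 3.23
  hr_stroke_y2plus: 1.5
costs:
  c_mi_y1: 9558          # acute hosp. 4226 + further hosp. 2601 + rehab 1757 + visits 975
  c_stroke_y1: 14925     # 9791 + 1063 + 1610 + 2462 (printed first-year total)
  c_mi_y2plus: 3421      # 2008 + 439 + 974
  c_stroke_y2plus: 4336
  c_death: 8650
  c_no_event_annual: 0
  indirect_mi_y1: 2744
  indirect_stroke_y1: 4417
  indirect_stroke_y2plus: 4336
  dtc_ticagrelor: 2.90
  dtc_clopidogrel: 0.72  # average generic price; 0.35 lowest generic, 2.38 branded
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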