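# Shared fixtures: a small configurable model and flat life tables, built
# in code so every downstream stage is testable without external data.

flat_life_table <- function(qx = 0.02, ages = 0:110) {
  one <- function(sex) {
    q <- rep(qx, length(ages))
    q[length(q)] <- 1
    data.frame(age = ages, sex = sex, qx = q)
  }
  validate_life_table(rbind(one("male"), one("female")))
}

toy_arm <- function(label = "ticagrelor", p_mi = 0.041, p_stroke = 0.008,
                    p_death = 0.036, u_no_event = 0.875, u_mi = 0.817,
                    u_stroke = 0.748, u_death = 0.259) {
  arm_inputs(label, p_mi, p_stroke, p_death,
             u_no_event, u_mi, u_stroke, u_death)
}

toy_config <- function(start_age = 62, max_age = 110, male_fraction = 0.72,
                       q_mi = 0.021, q_stroke = 0.004, q_cv_fatal = 0.019,
                       hrs = hazard_ratio_set(),
                       discount = discount_spec(),
                       cohort_scale = 1,
                       arm_t = toy_arm("ticagrelor"),
                       arm_c = toy_arm("clopidogrel", 0.049, 0.008, 0.050,
                                       0.878, 0.801, 0.720, 0.249),
                       costs = cost_inputs(
                         c_mi_y1 = 9558, c_stroke_y1 = 14925,
                         c_mi_y2plus = 3421, c_stroke_y2plus = 4336,
                         c_death = 8650, dtc_ticagrelor = 2.90,
                         dtc_clopidogrel = 0.72)) {
  model_config(
    cohort = cohort_spec("toy", start_age = start_age, max_age = max_age,
                         male_fraction = male_fraction,
                         cohort_scale = cohort_scale),
    arm_ticagrelor = arm_t, arm_clopidogrel = arm_c,
    longterm = longterm_inputs(
      q_mi = q_mi, q_stroke = q_stroke, q_cv_fatal = q_cv_fatal,
      u_age_60_69 = 0.877, u_age_70_79 = 0.838, u_age_80plus = 0.773,
      du_stroke_y1 = 0.143, du_stroke_y2plus = 0.143,
      du_mi_y1 = 0.068, du_mi_y2plus = 0.068),
    hazard_ratios = hrs, costs = costs, discount = discount)
}

start_no_event <- function() {
  stats::setNames(c(1, 0, 0, 0, 0, 0),
                  c("no_event", "mi_y1", "mi_post", "stroke_y1",
                    "stroke_post", "dead"))
}
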