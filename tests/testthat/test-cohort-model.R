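# Decision tree and Markov cohort engine.

test_that("hazard-ratio inflation works on the rate scale", {
  expect_equal(apply_hazard_ratio(0.02, 1), 0.02)
  expect_equal(apply_hazard_ratio(0.02, 1.6), 1 - 0.98^1.6)
  expect_equal(apply_hazard_ratio(1, 7.43), 1)
  expect_equal(apply_hazard_ratio(0, 2), 0)
  expect_error(apply_hazard_ratio(1.2, 1), "p")
  expect_error(apply_hazard_ratio(0.5, 0), "hr")
})

test_that("state- and age-specific death probabilities combine hazards", {
  co <- cohort_spec("t", male_fraction = 1)
  lt <- flat_life_table(0.010)
  mklt <- function(q_cv) longterm_inputs(0, 0, q_cv, 0.877, 0.838, 0.773,
                                         0.1, 0.1, 0.1, 0.1)
  # neutral hazard ratios and no CV mortality: the life-table qx exactly
  ones <- hazard_ratio_set(1, 1, 1, 1, 1)
  expect_equal(annual_death_prob(70, co, lt, mklt(0), ones, "no_event"), 0.010)
  # hazard additivity: qx 0.010 + q_cv 0.019 -> 1 - 0.990 * 0.981
  expect_equal(annual_death_prob(70, co, lt, mklt(0.019), ones, "mi_post"),
               1 - 0.990 * 0.981)
  # base-case set routes the year-1 vs later stroke hazard ratios
  hrs <- hazard_ratio_set()
  h <- -log(0.990) - log(0.981)
  expect_equal(annual_death_prob(70, co, lt, mklt(0.019), hrs, "stroke_y1"),
               1 - exp(-h * 3.23))
  expect_equal(annual_death_prob(70, co, lt, mklt(0.019), hrs, "stroke_post"),
               1 - exp(-h * 1.5))
  # sex weighting on the probability mix
  co2 <- cohort_spec("t", male_fraction = 0.5)
  lt2 <- rbind(flat_life_table(0.02)[flat_life_table(0.02)$sex == "male", ],
               flat_life_table(0.04)[flat_life_table(0.04)$sex == "female", ])
  lt2 <- validate_life_table(lt2)
  expect_equal(annual_death_prob(70, co2, lt2, mklt(0), ones, "no_event"),
               0.03)
  expect_error(annual_death_prob(150, co, lt, mklt(0), ones), "life table")
})

test_that("the decision tree splits, values and costs the first year", {
  cfg <- toy_config()
  y1 <- run_year_one(cfg$arm_ticagrelor, cfg$costs, 2.90)
  d <- y1$end_distribution
  expect_equal(sum(d), 1)
  expect_equal(unname(d["no_event"]), 1 - 0.041 - 0.008 - 0.036)
  expect_equal(unname(d[c("mi_y1", "stroke_y1", "dead")]),
               c(0.041, 0.008, 0.036))
  expect_equal(unname(d[c("mi_post", "stroke_post")]), c(0, 0))
  expect_equal(y1$life_years, 1 - 0.5 * 0.036)
  expect_equal(y1$qalys,
               0.915 * 0.875 + 0.041 * 0.817 + 0.008 * 0.748 + 0.036 * 0.259)
  expect_equal(y1$cost,
               0.041 * 9558 + 0.008 * 14925 + 0.036 * 8650 +
                 365 * 2.90 * (1 - 0.036 * 0.5))
  expect_lte(y1$qalys, y1$life_years)

  # clopidogrel event and death cost excluding the drug component
  y1c <- run_year_one(cfg$arm_clopidogrel, cfg$costs, 0)
  expect_equal(y1c$cost, 0.049 * 9558 + 0.008 * 14925 + 0.050 * 8650,
               tolerance = 1e-12)
  expect_equal(y1c$cost, 1020.2, tolerance = 1e-4)
})

test_that("Markov traces conserve probability and absorb into death", {
  cfg <- toy_config()
  lt <- bundled_life_table("german_2009_synthetic")
  y1 <- run_year_one(cfg$arm_ticagrelor, cfg$costs, 2.90)
  tr <- run_markov(y1$end_distribution, cfg, lt)
  occ <- as.matrix(tr[, acs_states])
  expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
  expect_true(all(occ >= 0))
  expect_true(all(diff(tr$dead) >= 0))
  expect_equal(tr$age, cfg$cohort$start_age + tr$cycle)
  # tunnel correctness: next-cycle tunnel occupancy is exactly the newly
  # eventing survivors of the event-free state
  dp <- acsCEA:::death_prob_matrix(cfg, lt)
  for (t in 1:(nrow(tr) - 1)) {
    d <- dp$d[t + 1, ]
    expect_equal(tr$mi_y1[t + 1],
                 tr$no_event[t] * (1 - d[["no_event"]]) * cfg$longterm$q_mi,
                 tolerance = 1e-14)
    # tunnel occupants all leave: to post state or death
    expect_equal(tr$mi_post[t + 1],
                 tr$mi_y1[t] * (1 - d[["mi_y1"]]) +
                   tr$mi_post[t] * (1 - d[["mi_post"]]),
                 tolerance = 1e-14)
  }
  expect_error(run_markov(start_no_event() * 2, cfg, lt), "sum to 1")
})

test_that("degenerate Markov inputs reproduce closed-form survival", {
  # no transitions at all: the cohort stays event-free
  qz <- flat_life_table(0)
  cfg <- toy_config(start_age = 62, max_age = 72, q_mi = 0, q_stroke = 0,
                    q_cv_fatal = 0)
  tr <- run_markov(start_no_event(), cfg, qz)
  expect_equal(tr$no_event, rep(1, nrow(tr)))

  # constant death probability 0.05: geometric survival, cumulative
  # undiscounted life-years over 40 cycles equals the geometric sum
  lt5 <- flat_life_table(0.05)
  cfg2 <- toy_config(start_age = 20, max_age = 60, q_mi = 0, q_stroke = 0,
                     q_cv_fatal = 0)
  tr2 <- run_markov(start_no_event(), cfg2, lt5)
  expect_equal(nrow(tr2), 40)
  expect_equal(sum(1 - tr2$dead), sum(0.95^(1:40)), tolerance = 1e-10)

  # neutral hazard ratios reproduce life-table survival exactly
  cfg3 <- toy_config(q_mi = 0, q_stroke = 0, q_cv_fatal = 0,
                     hrs = hazard_ratio_set(1, 1, 1, 1, 1),
                     male_fraction = 1)
  de <- bundled_life_table("german_2009_synthetic")
  tr3 <- run_markov(start_no_event(), cfg3, de)
  qx <- de$qx[de$sex == "male" & de$age %in% tr3$age]
  expect_equal(tr3$no_event, cumprod(1 - qx), tolerance = 1e-12)
})

test_that("traces export as the documented CSV layout", {
  cfg <- toy_config(max_age = 70)
  tr <- run_markov(start_no_event(), cfg, flat_life_table(0.02))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("cycle", "age", "no_event", "mi_y1", "mi_post",
                     "stroke_y1", "stroke_post", "dead"))
  expect_equal(back$no_event, tr$no_event, tolerance = 1e-12)
})
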