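# Discounting, utilities, accumulation and incremental comparison.

test_that("discount factors follow the annual convention", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(2, 0.03), 1 / 1.03^2)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_error(discount_factor(-1, 0.03), "year_index")
})

test_that("state utilities use age bands and event decrements", {
  lt <- default_config("overall")$longterm
  expect_equal(state_utility("no_event", 65, lt), 0.877)
  expect_equal(state_utility("no_event", 45, lt), 0.877) # <60 uses 60-69 band
  expect_equal(state_utility("no_event", 70, lt), 0.838)
  expect_equal(state_utility("no_event", 83, lt), 0.773)
  expect_equal(state_utility("stroke_y1", 72, lt), 0.838 - 0.143)
  expect_equal(state_utility("mi_post", 65, lt), 0.877 - 0.068)
  expect_equal(state_utility("dead", 90, lt), 0)
})

test_that("accumulation matches a hand-computed three-cycle trace", {
  cfg <- toy_config(start_age = 62)
  sched <- state_value_schedule(cfg)
  y1 <- run_year_one(cfg$arm_ticagrelor, cfg$costs, 2.90)
  # hand-built occupancy trace (cycle, age, six states)
  tr <- data.frame(
    cycle = 1:3, age = 63:65,
    no_event = c(0.90, 0.85, 0.80), mi_y1 = c(0.02, 0.015, 0.012),
    mi_post = c(0, 0.03, 0.04), stroke_y1 = c(0.005, 0.004, 0.003),
    stroke_post = c(0, 0.006, 0.01), dead = c(0.075, 0.095, 0.135))
  class(tr) <- c("markov_trace", "data.frame")
  res <- accumulate(y1, tr, sched, discount_spec(0.03, 0.03))
  # spreadsheet-style expectations, computed term by term
  df <- 1.03^-(1:3)
  exp_cost <- y1$cost +
    sum(df * (tr$mi_y1 * 9558 + tr$mi_post * 3421 +
                tr$stroke_y1 * 14925 + tr$stroke_post * 4336))
  exp_ly <- y1$life_years + sum(df * (1 - tr$dead))
  u <- 0.877
  exp_qaly <- y1$qalys + sum(df * (tr$no_event * u +
    tr$mi_y1 * (u - 0.068) + tr$mi_post * (u - 0.068) +
    tr$stroke_y1 * (u - 0.143) + tr$stroke_post * (u - 0.143)))
  expect_equal(res$cost, exp_cost, tolerance = 1e-10)
  expect_equal(res$life_years, exp_ly, tolerance = 1e-10)
  expect_equal(res$qalys, exp_qaly, tolerance = 1e-10)

  # an empty trace returns the first-year values unchanged
  res0 <- accumulate(y1, tr[0, ], sched, discount_spec())
  expect_equal(res0$cost, y1$cost)
  expect_equal(res0$life_years, y1$life_years)

  # zero-rate discounting equals plain cumulative sums
  resz <- accumulate(y1, tr, sched, discount_spec(0, 0))
  expect_equal(resz$life_years, y1$life_years + sum(1 - tr$dead))
})

test_that("full utilities make QALYs equal life-years exactly", {
  # living utilities 1, no decrements, and decedents' within-year accrual
  # at half a healthy year mirror the life-year convention
  arm1 <- arm_inputs("t", 0.04, 0.01, 0.05, 1, 1, 1, 0.5)
  arm2 <- arm_inputs("c", 0.05, 0.01, 0.06, 1, 1, 1, 0.5)
  cfg <- toy_config(arm_t = arm1, arm_c = arm2)
  cfg$longterm <- longterm_inputs(0.021, 0.004, 0.019, 1, 1, 1, 0, 0, 0, 0)
  lt <- flat_life_table(0.02)
  res <- run_cea(cfg, lt)
  expect_equal(res$ticagrelor$qalys, res$ticagrelor$life_years,
               tolerance = 1e-12)
  expect_equal(res$clopidogrel$qalys, res$clopidogrel$life_years,
               tolerance = 1e-12)
})

test_that("comparison computes increments, ICERs and dominance", {
  mk <- function(cost, ly, q, lab = "x")
    structure(list(arm_label = lab, cost = cost, life_years = ly, qalys = q),
              class = "arm_result")
  r <- compare(mk(11815, 12.1471, 10.1349), mk(11387, 11.9674, 9.9779))
  expect_equal(r$delta_cost, 428)
  expect_equal(r$icer_ly, 428 / 0.1797, tolerance = 1e-3)
  expect_equal(round(560 / 0.1796), 3118) # printed-arithmetic consistency
  expect_identical(r$dominance, "none")

  dom <- compare(mk(100, 10.1, 9.1), mk(110, 10.0, 9.0))
  expect_identical(dom$dominance, "ticagrelor_dominant")
  expect_true(is.na(dom$icer_ly) && is.na(dom$icer_qaly))

  tie <- compare(mk(120, 10, 9), mk(100, 10, 9))
  expect_true(is.na(tie$icer_ly)) # zero effect difference: undefined
})

test_that("qalys never exceed life-years for the bundled cohorts", {
  for (co in c("overall", "nstemi_ua", "stemi")) {
    res <- run_cea(default_config(co))
    expect_lte(res$ticagrelor$qalys, res$ticagrelor$life_years)
    expect_lte(res$clopidogrel$qalys, res$clopidogrel$life_years)
    expect_gte(res$delta_ly, 0)
  }
})

test_that("ICERs are invariant to cohort scaling", {
  cfg1 <- toy_config(cohort_scale = 1)
  cfg2 <- toy_config(cohort_scale = 1000)
  lt <- flat_life_table(0.02)
  r1 <- run_cea(cfg1, lt)
  r2 <- run_cea(cfg2, lt)
  expect_equal(r2$ticagrelor$cost, 1000 * r1$ticagrelor$cost)
  expect_equal(r2$icer_ly, r1$icer_ly, tolerance = 1e-12)
  expect_equal(r2$icer_qaly, r1$icer_qaly, tolerance = 1e-12)
})

test_that("raising the clopidogrel price lowers incremental cost to dominance", {
  cfg <- default_config("overall")
  lt <- bundled_life_table(cfg$life_table_ref)
  prices <- c(0.35, 0.72, 1.5, 2.38)
  dcs <- vapply(prices, function(p) {
    sc <- scenario_spec("p", list(dtc_clopidogrel = p))
    run_cea(apply_scenario(cfg, sc), lt, keep_traces = FALSE)$delta_cost
  }, numeric(1))
  expect_true(all(diff(dcs) < 0))
  res_branded <- run_cea(apply_scenario(
    cfg, scenario_spec("b", list(dtc_clopidogrel = 2.38))), lt)
  expect_identical(res_branded$dominance, "ticagrelor_dominant")
  expect_lt(res_branded$delta_cost, 0)
})
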