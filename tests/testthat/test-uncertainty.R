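# PSA draws, acceptability curves, scenarios and the tornado ordering.

test_that("zero-variance draws return the base configuration exactly", {
  cfg <- default_config("overall")
  spec <- psa_spec(hr_log_sd = 0, utility_se = 0, prob_n_effective = Inf,
                   seed = 5L)
  drawn <- draw_parameters(spec, cfg, 17)
  expect_equal(serialize_config(drawn), serialize_config(cfg))
})

test_that("draws are deterministic in (seed, index) and vary across indices", {
  cfg <- default_config("overall")
  spec <- psa_spec(seed = 9L)
  a <- draw_parameters(spec, cfg, 3)
  b <- draw_parameters(spec, cfg, 3)
  expect_identical(serialize_config(a), serialize_config(b))
  c2 <- draw_parameters(spec, cfg, 4)
  expect_false(identical(serialize_config(a), serialize_config(c2)))
})

test_that("log-normal hazard-ratio draws have the base value as median", {
  cfg <- default_config("overall")
  spec <- psa_spec(seed = 21L, utility_se = 0, prob_n_effective = Inf,
                   hr_log_sd = 0.2)
  hrs <- vapply(1:5000, function(i)
    draw_parameters(spec, cfg, i)$hazard_ratios$hr_mi_y1, numeric(1))
  expect_lt(abs(stats::median(hrs) - 1.6) / 1.6, 0.02)
  expect_true(all(hrs > 0))
})

test_that("PSA collapses to the deterministic result at zero variance", {
  cfg <- default_config("overall")
  lt <- bundled_life_table(cfg$life_table_ref)
  det <- run_cea(cfg, lt)
  spec0 <- psa_spec(hr_log_sd = 0, utility_se = 0, prob_n_effective = Inf,
                    seed = 1L)
  d0 <- run_psa(spec0, cfg, lt, n = 25)
  expect_equal(nrow(d0), 25)
  expect_equal(d0$delta_cost, rep(det$delta_cost, 25), tolerance = 1e-10)
  expect_equal(d0$delta_qaly, rep(det$delta_qaly, 25), tolerance = 1e-10)
  expect_equal(attr(d0, "n_failed"), 0L)
})

test_that("mean-centred PSA draws are unbiased for the deterministic deltas", {
  # hazard ratios held fixed (their log-normal draws are median-centred);
  # probability and utility draws are mean-centred betas
  cfg <- default_config("overall")
  lt <- bundled_life_table(cfg$life_table_ref)
  det <- run_cea(cfg, lt)
  spec <- psa_spec(hr_log_sd = 0, seed = 33L)
  d <- run_psa(spec, cfg, lt, n = 2000)
  for (f in c("delta_qaly", "delta_ly", "delta_cost")) {
    mc_se <- stats::sd(d[[f]]) / sqrt(nrow(d))
    expect_lt(abs(mean(d[[f]]) - det[[f]]), 3 * mc_se + 1e-12)
  }
})

test_that("acceptability curves follow their definition and monotonicity", {
  d <- data.frame(delta_cost = c(428, -50, 300), delta_qaly = c(0.157, 0.1, -0.05))
  cc <- ceac(d, thresholds = c(0, 2000, 3000, 1e7))
  # lambda = 0: fraction of cost-saving draws
  expect_equal(cc$prob_cost_effective[1], mean(d$delta_cost < 0))
  # lambda -> infinity tends to the fraction with positive effect
  expect_equal(cc$prob_cost_effective[4], mean(d$delta_qaly > 0))

  single <- data.frame(delta_cost = 428, delta_qaly = 0.157)
  cs <- ceac(single, thresholds = c(2000, 3000))
  expect_equal(cs$prob_cost_effective, c(0, 1)) # NMB flips at 428/0.157
  expect_error(ceac(single[0, ]), "draws")

  # all-positive-effect draws give a non-decreasing curve
  cfg <- default_config("overall")
  lt <- bundled_life_table(cfg$life_table_ref)
  dd <- run_psa(psa_spec(seed = 2L), cfg, lt, n = 200)
  curve <- ceac(dd, seq(0, 50000, by = 1000))
  if (all(dd$delta_qaly > 0))
    expect_true(all(diff(curve$prob_cost_effective) >= 0))
  expect_true(all(curve$prob_cost_effective >= 0 &
                    curve$prob_cost_effective <= 1))
})

test_that("scenario overrides apply and unknown keys are rejected", {
  cfg <- default_config("overall")
  lt <- bundled_life_table(cfg$life_table_ref)
  base <- run_cea(cfg, lt)

  ident <- run_cea(apply_scenario(cfg, scenario_spec("id", list())), lt)
  expect_equal(ident$delta_cost, base$delta_cost, tolerance = 1e-12)
  expect_equal(ident$icer_ly, base$icer_ly, tolerance = 1e-12)

  glob <- apply_scenario(cfg, scenario_spec("g", list(hazard_ratios = "global")))
  expect_equal(glob$hazard_ratios$hr_stroke_y1, 7.43)

  d0 <- run_cea(apply_scenario(cfg, scenario_spec("d0", list(discount_rate = 0))), lt)
  expect_gt(d0$delta_ly, base$delta_ly)

  expect_error(scenario_spec("bad", list(dtc_aspirin = 1)), "unknown override")
  expect_error(apply_scenario(cfg, scenario_spec("h", list(hazard_ratios = "wild"))),
               "hazard_ratios")
})

test_that("the bundled univariate set reproduces the published scenario grid", {
  scens <- scenario_set("paper_univariate")
  labels <- vapply(scens, `[[`, "", "label")
  expect_true(any(grepl("0.35", labels)) && any(grepl("2.38", labels)))
  cfg <- default_config("overall")
  lt <- bundled_life_table(cfg$life_table_ref)
  tab <- run_scenarios(cfg, scens, lt)
  expect_equal(nrow(tab), length(scens))
  branded <- tab[grepl("2.38", tab$label), ]
  expect_identical(branded$dominance, "ticagrelor_dominant")
  expect_true(is.na(branded$icer_ly))
  expect_error(scenario_set("nope"), "paper_univariate")
})

test_that("tornado ordering ranks the drug price widest and handles edge cases", {
  cfg <- default_config("overall")
  lt <- bundled_life_table(cfg$life_table_ref)
  tor <- tornado(cfg, life_table = lt)
  expect_identical(tor$group[1], "clopidogrel price")
  expect_true(all(diff(tor$width) <= 0))
  expect_true(tor$dominant_low[1]) # branded price scenario dominates

  empty <- tornado(cfg, scenarios = list(), life_table = lt)
  expect_equal(nrow(empty), 0)

  # a no-op perturbation produces a zero-width bar
  noop <- tornado(cfg, list(scenario_spec("same", list(), group = "noop")),
                  life_table = lt)
  expect_equal(noop$width, 0, tolerance = 1e-9)
})

test_that("the covariance-based Weibull draw produces valid correlated draws", {
  cfg <- default_config("overall")
  lt <- bundled_life_table(cfg$life_table_ref)
  fits <- psa_weibull_fits(cfg, n = 5000)
  expect_s3_class(fits$c$mi, "weibull_fit")
  spec <- psa_spec(weibull_draw = "covariance_mvn", seed = 4L,
                   utility_se = 0, prob_n_effective = Inf)
  drawn <- vapply(1:200, function(i) {
    cf <- draw_parameters(spec, cfg, i, weibull_fits = fits)
    c(cf$arm_ticagrelor$p_mi, cf$arm_clopidogrel$p_mi)
  }, numeric(2))
  expect_true(all(drawn > 0 & drawn < 1))
  # shared endpoint quantiles induce positive between-arm correlation
  expect_gt(stats::cor(drawn[1, ], drawn[2, ]), 0.5)
  expect_lt(abs(stats::median(drawn[2, ]) - 0.049), 0.01)
})
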