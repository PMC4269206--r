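# Probabilistic sensitivity analysis, acceptability curves, deterministic
# scenarios and the tornado ordering.

#' Probabilistic sensitivity analysis specification
#'
#' The published analysis reports 10,000 iterations with log-normal hazard
#' ratios and Weibull-summarised first-year effects, but prints no
#' uncertainty magnitudes; the defaults below are therefore synthetic:
#' `hr_log_sd` makes the 95% interval span `[HR/1.5, 1.5*HR]`,
#' `utility_se` is 0.02, and first-year/annual probabilities are drawn
#' from beta distributions with effective sample size `prob_n_effective`
#' per arm (`weibull_draw = "probability_beta"`), or from a multivariate
#' normal on the log-parameters of Weibull fits to synthetic patient-level
#' data (`"covariance_mvn"`).  Costs are treated as known with certainty.
#'
#' @param n_iterations Number of draws (default 10,000).
#' @param seed Optional integer seed; `NULL` inherits the config seed.
#' @param hr_log_sd Log-scale standard deviation of every hazard ratio.
#' @param utility_se Standard error of utilities and decrements.
#' @param prob_n_effective Effective sample size of the beta draws.
#' @param weibull_draw `"probability_beta"` or `"covariance_mvn"`.
#' @param threshold_from,threshold_to,threshold_by Willingness-to-pay grid
#'   (EUR per QALY) for the acceptability curve.
#' @param max_redraws Cap on redraws of an invalid parameter set.
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(n_iterations = 10000L, seed = NULL,
                     hr_log_sd = log(1.5) / stats::qnorm(0.975),
                     utility_se = 0.02, prob_n_effective = 5000,
                     weibull_draw = c("probability_beta", "covariance_mvn"),
                     threshold_from = 0, threshold_to = 50000,
                     threshold_by = 1000, max_redraws = 100L) {
  if (n_iterations < 1) vfail("psa.n_iterations", "must be >= 1")
  chk_nonneg(hr_log_sd, "psa.hr_log_sd")
  chk_nonneg(utility_se, "psa.utility_se")
  # Inf collapses the probability draws to their means (zero variance)
  if (!is.numeric(prob_n_effective) || length(prob_n_effective) != 1L ||
      is.na(prob_n_effective) || prob_n_effective <= 0)
    vfail("psa.prob_n_effective", "must be > 0 (Inf for no uncertainty)")
  weibull_draw <- match.arg(weibull_draw)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 hr_log_sd = hr_log_sd, utility_se = utility_se,
                 prob_n_effective = prob_n_effective,
                 weibull_draw = weibull_draw,
                 threshold_from = threshold_from,
                 threshold_to = threshold_to, threshold_by = threshold_by,
                 max_redraws = as.integer(max_redraws)),
            class = "psa_spec")
}

psa_thresholds <- function(spec) {
  seq(spec$threshold_from, spec$threshold_to, by = spec$threshold_by)
}

# deterministic per-draw seed below 2^31
draw_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
}

# beta draw matched to mean/se through a shared standard-normal quantile
# (shared quantiles induce the between-arm correlation of a common
# baseline); se = 0 collapses to the mean
beta_q <- function(z, mean, se) {
  if (se == 0 || mean <= 0 || mean >= 1) return(mean)
  nu <- mean * (1 - mean) / se^2 - 1
  if (nu <= 0) return(mean)
  stats::qbeta(stats::pnorm(z), mean * nu, (1 - mean) * nu)
}

# binomial-style beta draw with effective sample size n
beta_q_n <- function(z, mean, n) {
  if (mean <= 0 || mean >= 1 || !is.finite(n)) return(mean)
  stats::qbeta(stats::pnorm(z), mean * n, (1 - mean) * n)
}

#' Draw one probabilistic parameter set
#'
#' Hazard ratios are drawn log-normally around their base values;
#' first-year endpoint probabilities and the shared long-term annual
#' probabilities are drawn per the `weibull_draw` flag (beta with
#' effective sample size, or multivariate-normal Weibull log-parameters
#' from `weibull_fits`); utilities and decrements are drawn from beta
#' distributions matched to mean and standard error.  Costs and discount
#' rates are never drawn.  Deterministic given `(seed, index)`; a
#' parameter set violating a probability-sum invariant is redrawn up to
#' `max_redraws` times.
#'
#' @param spec A [psa_spec()].
#' @param base A [model_config()].
#' @param index Draw index (1-based).
#' @param weibull_fits Optional per-arm, per-endpoint `weibull_fit` list
#'   (required for `weibull_draw = "covariance_mvn"`), as built by
#'   [psa_weibull_fits()].
#' @return A [model_config()] with sampled parameters.
#' @export
draw_parameters <- function(spec, base, index, weibull_fits = NULL) {
  stopifnot(inherits(spec, "psa_spec"), inherits(base, "model_config"))
  seed0 <- if (is.null(spec$seed)) base$seed else spec$seed
  set.seed(draw_seed(seed0, index))

  for (attempt in seq_len(spec$max_redraws + 1L)) {
    cfg <- base
    # hazard ratios: independent log-normal, median at the base value
    hr <- base$hazard_ratios
    if (spec$hr_log_sd > 0) {
      z <- stats::rnorm(5L)
      hr <- hazard_ratio_set(
        hr_no_event = hr$hr_no_event * exp(spec$hr_log_sd * z[1L]),
        hr_mi_y1 = hr$hr_mi_y1 * exp(spec$hr_log_sd * z[2L]),
        hr_mi_y2plus = hr$hr_mi_y2plus * exp(spec$hr_log_sd * z[3L]),
        hr_stroke_y1 = hr$hr_stroke_y1 * exp(spec$hr_log_sd * z[4L]),
        hr_stroke_y2plus = hr$hr_stroke_y2plus * exp(spec$hr_log_sd * z[5L]))
    }
    cfg$hazard_ratios <- hr

    # first-year probabilities: one shared quantile vector per endpoint
    # across arms (common-baseline correlation), arm-specific distributions
    if (spec$weibull_draw == "covariance_mvn" && !is.null(weibull_fits)) {
      ze <- lapply(ipd_endpoints, function(e) stats::rnorm(2L))
      names(ze) <- ipd_endpoints
      probs <- lapply(weibull_fits, function(arm_fits)
        vapply(ipd_endpoints, function(e) {
          fit <- arm_fits[[e]]
          if (is.null(fit)) return(0)
          L <- tryCatch(chol(fit$vcov_log),
                        error = function(err) matrix(0, 2, 2))
          th <- log(c(fit$shape, fit$scale)) + drop(t(L) %*% ze[[e]])
          k <- exp(th[1L]); lam <- exp(th[2L])
          1 - exp(-(1 / lam)^k)        # 1 - S(1) under the drawn parameters
        }, numeric(1L)))
      names(probs) <- c("t", "c")[seq_along(probs)]
    } else {
      ze <- stats::rnorm(3L)
      probs <- lapply(list(t = base$arm_ticagrelor, c = base$arm_clopidogrel),
                      function(a) c(
                        mi = beta_q_n(ze[1L], a$p_mi, spec$prob_n_effective),
                        stroke = beta_q_n(ze[2L], a$p_stroke, spec$prob_n_effective),
                        death = beta_q_n(ze[3L], a$p_death, spec$prob_n_effective)))
    }

    # utilities: beta around mean with utility_se; arm-specific year-1
    # utilities drawn independently, shared long-term bands/decrements once
    du <- function(m) beta_q(stats::rnorm(1L), m, spec$utility_se)
    mk_arm <- function(a, p) {
      tryCatch(arm_inputs(a$arm_label, p[["mi"]], p[["stroke"]], p[["death"]],
                          du(a$u_no_event), du(a$u_mi), du(a$u_stroke),
                          du(a$u_death)),
               acs_validation_error = function(e) NULL)
    }
    arm_t <- mk_arm(base$arm_ticagrelor, probs[[1L]])
    arm_c <- mk_arm(base$arm_clopidogrel, probs[[2L]])

    lt0 <- base$longterm
    zq <- stats::rnorm(3L)
    bands <- c(du(lt0$u_age_60_69), du(lt0$u_age_70_79), du(lt0$u_age_80plus))
    decs <- c(du(lt0$du_stroke_y1), du(lt0$du_stroke_y2plus),
              du(lt0$du_mi_y1), du(lt0$du_mi_y2plus))
    decs <- pmin(decs, min(bands))  # keep decrements within the band floor
    longterm <- tryCatch(longterm_inputs(
      q_mi = beta_q_n(zq[1L], lt0$q_mi, spec$prob_n_effective),
      q_stroke = beta_q_n(zq[2L], lt0$q_stroke, spec$prob_n_effective),
      q_cv_fatal = beta_q_n(zq[3L], lt0$q_cv_fatal, spec$prob_n_effective),
      u_age_60_69 = bands[1L], u_age_70_79 = bands[2L],
      u_age_80plus = bands[3L],
      du_stroke_y1 = decs[1L], du_stroke_y2plus = decs[2L],
      du_mi_y1 = decs[3L], du_mi_y2plus = decs[4L]),
      acs_validation_error = function(e) NULL)

    if (!is.null(arm_t) && !is.null(arm_c) && !is.null(longterm)) {
      cfg$arm_ticagrelor <- arm_t
      cfg$arm_clopidogrel <- arm_c
      cfg$longterm <- longterm
      return(cfg)
    }
  }
  stop(sprintf("draw %d: no valid parameter set after %d redraws",
               index, spec$max_redraws), call. = FALSE)
}

#' Weibull fits backing the covariance-based PSA draw
#'
#' Generates synthetic patient-level data for each arm from the base
#' configuration and fits each endpoint marginally, providing the
#' log-parameter covariance used by `weibull_draw = "covariance_mvn"`.
#'
#' @param base A [model_config()].
#' @param n Patients per arm (default 20,000).
#' @return A list `list(t = <fits>, c = <fits>)` of per-endpoint fits
#'   (`NULL` for endpoints with zero base probability).
#' @export
psa_weibull_fits <- function(base, n = 20000L) {
  one_arm <- function(arm, seed_off) {
    ipd <- generate_ipd(arm, n, seed = base$seed + seed_off,
                        longterm = base$longterm)
    fits <- lapply(ipd_endpoints, function(e)
      if (sum(ipd$event == e) >= 2L) fit_weibull_mle(ipd, e) else NULL)
    names(fits) <- ipd_endpoints
    fits
  }
  list(t = one_arm(base$arm_ticagrelor, 101L),
       c = one_arm(base$arm_clopidogrel, 202L))
}

#' Run the probabilistic sensitivity analysis
#'
#' Runs the full model (decision tree, Markov model, discounted
#' accumulation) once per draw and collects incremental cost, life-years
#' and QALYs.  Per-draw failures are recorded and counted, not fatal.
#'
#' @param spec A [psa_spec()].
#' @param base A [model_config()].
#' @param life_table Optional pre-resolved life table.
#' @param n Optional override of `spec$n_iterations`.
#' @return A `psa_result` data.frame (`draw`, `delta_cost`, `delta_ly`,
#'   `delta_qaly`) with attributes `n_failed` and `thresholds`.
#' @export
run_psa <- function(spec, base, life_table = NULL, n = NULL) {
  stopifnot(inherits(spec, "psa_spec"), inherits(base, "model_config"))
  if (is.null(life_table)) life_table <- resolve_life_table(base)
  n <- if (is.null(n)) spec$n_iterations else as.integer(n)
  if (n < 1) vfail("psa.n_iterations", "must be >= 1")
  fits <- if (spec$weibull_draw == "covariance_mvn")
    psa_weibull_fits(base) else NULL
  dc <- dly <- dq <- rep(NA_real_, n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      cfg <- draw_parameters(spec, base, i, weibull_fits = fits)
      run_cea(cfg, life_table, keep_traces = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    dc[i] <- res$delta_cost; dly[i] <- res$delta_ly; dq[i] <- res$delta_qaly
  }
  ok <- !is.na(dc)
  out <- data.frame(draw = seq_len(n)[ok], delta_cost = dc[ok],
                    delta_ly = dly[ok], delta_qaly = dq[ok])
  class(out) <- c("psa_result", "data.frame")
  attr(out, "n_failed") <- n_failed
  attr(out, "thresholds") <- psa_thresholds(spec)
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold `lambda`, the fraction of draws
#' with positive incremental net monetary benefit
#' `lambda * delta_qaly - delta_cost > 0`.
#'
#' @param draws A `psa_result` (or any data.frame with `delta_cost` and
#'   `delta_qaly`).
#' @param thresholds EUR-per-QALY values (defaults to the grid attached to
#'   the draws).
#' @return A `ceac_curve` data.frame (`threshold`, `prob_cost_effective`).
#' @export
ceac <- function(draws, thresholds = attr(draws, "thresholds")) {
  if (is.null(thresholds)) thresholds <- seq(0, 50000, by = 1000)
  if (NROW(draws) < 1L) stop("no PSA draws supplied", call. = FALSE)
  prob <- vapply(thresholds, function(l)
    mean(l * draws$delta_qaly - draws$delta_cost > 0), numeric(1L))
  out <- data.frame(threshold = thresholds, prob_cost_effective = prob)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

# ---- deterministic scenarios --------------------------------------------

scenario_override_keys <- c(
  "dtc_clopidogrel", "dtc_ticagrelor", "hazard_ratios", "discount_rate",
  "rate_costs", "rate_effects", "include_indirect", "c_no_event_annual",
  "c_mi_y1", "c_stroke_y1", "c_mi_y2plus", "c_stroke_y2plus", "c_death",
  "drug_death_fraction")

#' Deterministic scenario specification
#'
#' @param label Scenario name.
#' @param overrides Named list of parameter overrides; allowed keys are
#'   the drug prices, event/death/no-event costs, `hazard_ratios`
#'   (`"base"`, `"global"`, or a [hazard_ratio_set()]), `discount_rate`
#'   (sets both rates), `rate_costs`/`rate_effects`, `include_indirect`
#'   and `drug_death_fraction`.
#' @param group Parameter group used to pair scenarios in the tornado
#'   ordering (defaults to the label).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, overrides = list(), group = label) {
  bad <- setdiff(names(overrides), scenario_override_keys)
  if (length(bad))
    stop(sprintf("unknown override key(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(scenario_override_keys, collapse = ", ")),
         call. = FALSE)
  structure(list(label = label, overrides = overrides, group = group),
            class = "scenario_spec")
}

#' Apply scenario overrides to a configuration
#'
#' @param base A [model_config()].
#' @param scenario A [scenario_spec()].
#' @return The modified, re-validated [model_config()].
#' @export
apply_scenario <- function(base, scenario) {
  stopifnot(inherits(base, "model_config"), inherits(scenario, "scenario_spec"))
  cfg <- base
  ov <- scenario$overrides
  cost_fields <- intersect(names(ov), c(
    "dtc_clopidogrel", "dtc_ticagrelor", "c_no_event_annual", "c_mi_y1",
    "c_stroke_y1", "c_mi_y2plus", "c_stroke_y2plus", "c_death",
    "include_indirect", "drug_death_fraction"))
  if (length(cost_fields)) {
    cs <- unclass(cfg$costs)
    for (f in cost_fields) cs[[f]] <- ov[[f]]
    cfg$costs <- do.call(cost_inputs, cs)
  }
  if (!is.null(ov$hazard_ratios)) {
    cfg$hazard_ratios <- if (inherits(ov$hazard_ratios, "hazard_ratio_set"))
      ov$hazard_ratios
    else switch(ov$hazard_ratios,
                base = hazard_ratio_set(), global = global_hazard_ratios(),
                stop("hazard_ratios override must be 'base', 'global' or a hazard_ratio_set",
                     call. = FALSE))
  }
  rc <- ov$rate_costs %||% ov$discount_rate %||% cfg$discount$rate_costs
  re <- ov$rate_effects %||% ov$discount_rate %||% cfg$discount$rate_effects
  cfg$discount <- discount_spec(rc, re)
  cfg
}

#' Bundled scenario sets
#'
#' `"paper_univariate"` covers the published one-way analyses: clopidogrel
#' price at the lowest generic (0.35), average generic (0.72, base) and
#' branded (2.38) daily cost, the alternative "global model" hazard-ratio
#' set, 0%/5% discounting, indirect costs on, and an annual cost for the
#' event-free state (EUR 974/year, the outpatient follow-up figure).
#'
#' @param name Scenario set name.
#' @return A list of [scenario_spec()]s.
#' @export
scenario_set <- function(name = "paper_univariate") {
  sets <- list(paper_univariate = list(
    scenario_spec("base case", list(), group = "base"),
    scenario_spec("clopidogrel DTC 0.35 (lowest generic)",
                  list(dtc_clopidogrel = 0.35), group = "clopidogrel price"),
    scenario_spec("clopidogrel DTC 2.38 (branded)",
                  list(dtc_clopidogrel = 2.38), group = "clopidogrel price"),
    scenario_spec("global-model hazard ratios",
                  list(hazard_ratios = "global"), group = "post-event mortality HRs"),
    scenario_spec("discount 0%", list(discount_rate = 0),
                  group = "discount rate"),
    scenario_spec("discount 5%", list(discount_rate = 0.05),
                  group = "discount rate"),
    scenario_spec("indirect costs included",
                  list(include_indirect = TRUE), group = "indirect costs"),
    scenario_spec("no-event annual cost 974",
                  list(c_no_event_annual = 974), group = "no-event costs")))
  if (!name %in% names(sets))
    stop(sprintf("unknown scenario set '%s'; available: %s", name,
                 paste(names(sets), collapse = ", ")), call. = FALSE)
  sets[[name]]
}

#' Run deterministic scenarios
#'
#' One full deterministic model run per scenario.
#'
#' @param base A [model_config()].
#' @param scenarios A list of [scenario_spec()]s.
#' @param life_table Optional pre-resolved life table (only valid when no
#'   scenario changes the life table).
#' @return A data.frame with one row per scenario (per-arm results,
#'   increments, ICERs, dominance).
#' @export
run_scenarios <- function(base, scenarios, life_table = NULL) {
  if (is.null(life_table)) life_table <- resolve_life_table(base)
  rows <- lapply(scenarios, function(sc) {
    res <- run_cea(apply_scenario(base, sc), life_table, keep_traces = FALSE)
    out <- cea_row(res, label = sc$label)
    out$group <- sc$group
    out
  })
  do.call(rbind, rows)
}

#' Tornado ordering of one-way scenarios
#'
#' Runs the scenarios, pools them with the base case by parameter group
#' and reports each group's ICER range (EUR per life-year), widest first.
#' A dominant scenario is reported as a flagged bound (`dominant_low` /
#' `dominant_high`), not as a negative ICER; for ordering, dominance is
#' treated as an ICER bound at 0.
#'
#' @param base A [model_config()].
#' @param scenarios A list of [scenario_spec()]s (defaults to the bundled
#'   `"paper_univariate"` set without its base-case entry).
#' @param life_table Optional pre-resolved life table.
#' @return A data.frame (`group`, `icer_low`, `icer_high`,
#'   `dominant_low`, `dominant_high`, `width`) ordered by `width`
#'   descending.
#' @export
tornado <- function(base, scenarios = NULL, life_table = NULL) {
  if (is.null(scenarios))
    scenarios <- Filter(function(s) s$group != "base",
                        scenario_set("paper_univariate"))
  if (!length(scenarios))
    return(data.frame(group = character(), icer_low = numeric(),
                      icer_high = numeric(), dominant_low = logical(),
                      dominant_high = logical(), width = numeric()))
  if (is.null(life_table)) life_table <- resolve_life_table(base)
  tab <- run_scenarios(base, scenarios, life_table)
  base_res <- run_cea(base, life_table, keep_traces = FALSE)
  base_icer <- base_res$icer_ly
  rows <- lapply(split(tab, tab$group), function(g) {
    icers <- c(g$icer_ly, base_icer)
    dom <- c(g$dominance, base_res$dominance) == "ticagrelor_dominant"
    vals <- ifelse(dom, 0, icers)  # dominance ordered as an ICER bound at 0
    lo <- which.min(vals); hi <- which.max(vals)
    data.frame(group = g$group[1L], icer_low = icers[lo],
               icer_high = icers[hi], dominant_low = dom[lo],
               dominant_high = dom[hi], width = vals[hi] - vals[lo],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  out
}
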