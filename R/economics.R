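# Discounted valuation of the decision tree + Markov trace, incremental
# comparison, ICERs and dominance.

#' Discount factor
#'
#' `(1 + rate)^(-year_index)`.  The decision-tree year carries index 0
#' (undiscounted); Markov cycle `t` carries index `t`.
#'
#' @param year_index Integer year index `>= 0` (vectorised).
#' @param rate Non-negative annual rate.
#' @return Discount factors.
#' @export
discount_factor <- function(year_index, rate) {
  if (any(year_index < 0)) vfail("year_index", "must be >= 0")
  chk_nonneg(rate, "rate")
  (1 + rate)^(-year_index)
}

#' Health-state utility by age
#'
#' Event-free utility of the cohort's age band (60-69 below age 70 —
#' also used below 60 — 70-79, 80+), minus the MI or stroke decrement for
#' post-event states (first post-event year versus later years); 0 when
#' dead.
#'
#' @param state One of the model states.
#' @param age Age in years.
#' @param longterm A [longterm_inputs()].
#' @return A utility weight.
#' @export
state_utility <- function(state, age, longterm) {
  state <- match.arg(state, acs_states)
  if (state == "dead") return(0)
  band <- if (age < 70) longterm$u_age_60_69 else
    if (age < 80) longterm$u_age_70_79 else longterm$u_age_80plus
  dec <- switch(state, no_event = 0,
                mi_y1 = longterm$du_mi_y1, mi_post = longterm$du_mi_y2plus,
                stroke_y1 = longterm$du_stroke_y1,
                stroke_post = longterm$du_stroke_y2plus)
  max(band - dec, 0)
}

#' Per-state annual values used by the accumulator
#'
#' Bundles, per living state, the annual cost (with the indirect-cost
#' components folded in when the scenario toggle is on) and the utility
#' rule.  The one-off death cost is not part of the schedule: it belongs
#' to the trial-observed decision-tree year (see [run_year_one()]); later
#' deaths, predominantly from background causes beyond the trial horizon,
#' accrue no event cost.
#'
#' @param config A [model_config()].
#' @return An object of class `state_value_schedule`.
#' @export
state_value_schedule <- function(config) {
  cs <- config$costs
  ind <- cs$include_indirect
  cost <- c(no_event = cs$c_no_event_annual,
            mi_y1 = cs$c_mi_y1 + if (ind) cs$indirect_mi_y1 else 0,
            mi_post = cs$c_mi_y2plus,
            stroke_y1 = cs$c_stroke_y1 + if (ind) cs$indirect_stroke_y1 else 0,
            stroke_post = cs$c_stroke_y2plus +
              if (ind) cs$indirect_stroke_y2plus else 0,
            dead = 0)
  structure(list(cost = cost, longterm = config$longterm),
            class = "state_value_schedule")
}

# utility matrix (cycles x states) for a trace
trace_utilities <- function(trace, longterm) {
  band <- ifelse(trace$age < 70, longterm$u_age_60_69,
                 ifelse(trace$age < 80, longterm$u_age_70_79,
                        longterm$u_age_80plus))
  cbind(no_event = band,
        mi_y1 = pmax(band - longterm$du_mi_y1, 0),
        mi_post = pmax(band - longterm$du_mi_y2plus, 0),
        stroke_y1 = pmax(band - longterm$du_stroke_y1, 0),
        stroke_post = pmax(band - longterm$du_stroke_y2plus, 0),
        dead = 0)
}

#' Accumulate discounted lifetime results for one arm
#'
#' Adds the discounted per-cycle values of a Markov trace to the
#' (undiscounted) first-year results: state occupancy times annual state
#' cost, living occupancy for life-years, and occupancy times age-band
#' utility for QALYs.  Cycle `t` is discounted by `(1 + r)^-t`.  The
#' one-off death cost is charged in the decision-tree year only.
#'
#' @param year_one A `year_one_result` from [run_year_one()].
#' @param trace A `markov_trace` from [run_markov()] (may have zero rows).
#' @param schedule A [state_value_schedule()].
#' @param discount A [discount_spec()].
#' @param cohort_scale Normalisation constant (default 1).
#' @return An `arm_result` with discounted `cost`, `life_years`, `qalys`.
#' @export
accumulate <- function(year_one, trace, schedule, discount,
                       cohort_scale = 1) {
  stopifnot(inherits(year_one, "year_one_result"),
            inherits(schedule, "state_value_schedule"),
            inherits(discount, "discount_spec"))
  cost <- year_one$cost
  ly <- year_one$life_years
  qaly <- year_one$qalys
  if (nrow(trace) > 0L) {
    occ <- as.matrix(trace[, acs_states, drop = FALSE])
    dfc <- discount_factor(trace$cycle, discount$rate_costs)
    dfe <- discount_factor(trace$cycle, discount$rate_effects)
    cost <- cost + sum(dfc * (occ %*% schedule$cost[acs_states]))
    living <- 1 - occ[, "dead"]
    ly <- ly + sum(dfe * living)
    u <- trace_utilities(trace, schedule$longterm)
    qaly <- qaly + sum(dfe * rowSums(occ * u))
  }
  structure(list(arm_label = year_one$arm_label,
                 cost = cost * cohort_scale,
                 life_years = ly * cohort_scale,
                 qalys = qaly * cohort_scale),
            class = "arm_result")
}

#' Incremental comparison of the two strategies
#'
#' Computes increments (ticagrelor minus clopidogrel), ICERs per life-year
#' and per QALY, and the dominance status.  Under dominance (one strategy
#' cheaper *and* more effective) no ICER is reported; a zero effect
#' difference with a non-zero cost difference leaves the ICER undefined
#' (`NA`).
#'
#' @param ticagrelor,clopidogrel `arm_result` objects.
#' @return A `cea_result`.
#' @export
compare <- function(ticagrelor, clopidogrel) {
  stopifnot(inherits(ticagrelor, "arm_result"),
            inherits(clopidogrel, "arm_result"))
  dc <- ticagrelor$cost - clopidogrel$cost
  dly <- ticagrelor$life_years - clopidogrel$life_years
  dq <- ticagrelor$qalys - clopidogrel$qalys
  dominance <- if (dc < 0 && (dly > 0 || dq > 0)) "ticagrelor_dominant"
  else if (dc > 0 && dly < 0 && dq < 0) "clopidogrel_dominant"
  else "none"
  icer <- function(de) {
    if (dominance != "none" || de == 0) NA_real_ else dc / de
  }
  structure(list(ticagrelor = ticagrelor, clopidogrel = clopidogrel,
                 delta_cost = dc, delta_ly = dly, delta_qaly = dq,
                 icer_ly = icer(dly), icer_qaly = icer(dq),
                 dominance = dominance),
            class = "cea_result")
}

#' Run the full model for one configuration
#'
#' Decision tree, Markov model and discounted accumulation for both arms,
#' followed by the incremental comparison.
#'
#' @param config A [model_config()].
#' @param life_table Optional pre-resolved life table (resolved from the
#'   config otherwise).
#' @param keep_traces Attach the per-arm Markov traces as attribute
#'   `traces` (default `TRUE`).
#' @return A `cea_result`.
#' @export
run_cea <- function(config, life_table = NULL, keep_traces = TRUE) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(life_table)) life_table <- resolve_life_table(config)
  sched <- state_value_schedule(config)
  one_arm <- function(arm, dtc) {
    y1 <- run_year_one(arm, config$costs, dtc)
    tr <- run_markov(y1$end_distribution, config, life_table)
    list(res = accumulate(y1, tr, sched, config$discount,
                          config$cohort$cohort_scale),
         trace = tr)
  }
  ti <- one_arm(config$arm_ticagrelor, config$costs$dtc_ticagrelor)
  cl <- one_arm(config$arm_clopidogrel, config$costs$dtc_clopidogrel)
  out <- compare(ti$res, cl$res)
  out$cohort_label <- config$cohort$label
  if (keep_traces)
    attr(out, "traces") <- list(ticagrelor = ti$trace, clopidogrel = cl$trace)
  out
}

fmt_icer <- function(x, dominance) {
  if (dominance == "ticagrelor_dominant") "dominant"
  else if (dominance == "clopidogrel_dominant") "dominated"
  else if (is.na(x)) "undefined" else sprintf("%.0f", x)
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>", if (!is.null(x$cohort_label)) x$cohort_label else "",
      "\n")
  row <- function(lab, f, digits) {
    cat(sprintf("  %-11s %12s %12s %12s\n", lab,
                formatC(f(x$ticagrelor), format = "f", digits = digits),
                formatC(f(x$clopidogrel), format = "f", digits = digits),
                formatC(f(x$ticagrelor) - f(x$clopidogrel), format = "f",
                        digits = max(digits, 4L))))
  }
  cat(sprintf("  %-11s %12s %12s %12s\n", "", "ticagrelor", "clopidogrel",
              "incremental"))
  row("costs (EUR)", function(a) a$cost, 0L)
  row("life-years", function(a) a$life_years, 4L)
  row("QALYs", function(a) a$qalys, 4L)
  cat(sprintf("  ICER: %s EUR/LY, %s EUR/QALY%s\n",
              fmt_icer(x$icer_ly, x$dominance),
              fmt_icer(x$icer_qaly, x$dominance),
              if (x$dominance != "none") paste0(" (", x$dominance, ")") else ""))
  invisible(x)
}

# flat one-row summary used by scenario tables and reports
cea_row <- function(res, label = res$cohort_label) {
  data.frame(label = label %||% "",
             cost_ticagrelor = res$ticagrelor$cost,
             cost_clopidogrel = res$clopidogrel$cost,
             ly_ticagrelor = res$ticagrelor$life_years,
             ly_clopidogrel = res$clopidogrel$life_years,
             qaly_ticagrelor = res$ticagrelor$qalys,
             qaly_clopidogrel = res$clopidogrel$qalys,
             delta_cost = res$delta_cost, delta_ly = res$delta_ly,
             delta_qaly = res$delta_qaly, icer_ly = res$icer_ly,
             icer_qaly = res$icer_qaly, dominance = res$dominance,
             stringsAsFactors = FALSE)
}
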