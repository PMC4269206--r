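# First-year decision tree and lifetime Markov cohort model.
#
# States: no_event, mi_y1, mi_post, stroke_y1, stroke_post, dead.
# mi_y1/stroke_y1 are tunnel states: the single cycle following a
# non-fatal event, carrying first-year costs, utilities and mortality
# hazard ratios; survivors move to the corresponding *_post state and stay
# there (no further non-fatal events) until death.

#' Model state identifiers, in trace column order
#' @export
acs_states <- c("no_event", "mi_y1", "mi_post", "stroke_y1", "stroke_post",
                "dead")

#' Inflate an annual probability by a hazard ratio
#'
#' Multiplication on the rate scale: `1 - (1 - p)^hr`, i.e. the
#' probability is converted to a hazard, multiplied, and transformed back.
#'
#' @param p Annual probability in `[0, 1]` (vectorised).
#' @param hr Positive hazard ratio.
#' @return Inflated probabilities.
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (any(p < 0 | p > 1)) vfail("p", "probability outside [0, 1]")
  if (any(hr <= 0)) vfail("hr", "hazard ratio must be > 0")
  1 - (1 - p)^hr
}

#' Annual death probability by state and age
#'
#' Combines, on the hazard scale, the sex-weighted life-table death
#' probability at `age` with the annual fatal-cardiovascular-event
#' probability, then applies the state-specific hazard ratio:
#' `1 - exp(-(h_lifetable + h_cv) * hr)`.
#'
#' @param age Integer age in years (must lie within the life table).
#' @param cohort A [cohort_spec()] (supplies the sex mix).
#' @param life_table A `life_table`.
#' @param longterm A [longterm_inputs()] (supplies `q_cv_fatal`).
#' @param hrs A [hazard_ratio_set()].
#' @param state One of the living model states.
#' @return A probability.
#' @export
annual_death_prob <- function(age, cohort, life_table, longterm, hrs,
                              state = "no_event") {
  state <- match.arg(state, acs_states[-6L])
  qmix <- mixed_qx(life_table, cohort$male_fraction, age)
  hr <- switch(state,
               no_event = hrs$hr_no_event,
               mi_y1 = hrs$hr_mi_y1, mi_post = hrs$hr_mi_y2plus,
               stroke_y1 = hrs$hr_stroke_y1, stroke_post = hrs$hr_stroke_y2plus)
  h <- -log1p(-qmix) - log1p(-longterm$q_cv_fatal)
  1 - exp(-h * hr)
}

# precomputed death-probability matrix (cycles x living states) for the
# run_markov hot loop; ages = start_age + 1, ..., max_age
death_prob_matrix <- function(config, life_table) {
  co <- config$cohort; hrs <- config$hazard_ratios
  ages <- (co$start_age + 1):co$max_age
  qmix <- mixed_qx(life_table, co$male_fraction, ages)
  h <- -log1p(-qmix) - log1p(-config$longterm$q_cv_fatal)
  out <- sapply(c(hrs$hr_no_event, hrs$hr_mi_y1, hrs$hr_mi_y2plus,
                  hrs$hr_stroke_y1, hrs$hr_stroke_y2plus),
                function(hr) 1 - exp(-h * hr))
  out <- matrix(out, ncol = 5L,
                dimnames = list(NULL, acs_states[1:5]))
  list(ages = ages, d = out)
}

#' Run the first-year decision tree for one arm
#'
#' Splits the cohort over the four first-year outcomes and values the
#' year: survivors of a non-fatal event end the year in the corresponding
#' tunnel state; decedents are credited half a life-year and their
#' within-year utility accrual `u_death`; costs comprise the first-year
#' event costs, the one-off death cost and the drug cost
#' `drug_days * dtc * (1 - p_death * (1 - drug_death_fraction))`.
#'
#' @param arm An [arm_inputs()].
#' @param costs A [cost_inputs()].
#' @param dtc Daily therapy cost of this arm's drug, EUR/day.
#' @return A `year_one_result`: end-of-year state distribution plus
#'   undiscounted `life_years`, `qalys` and `cost`.
#' @export
run_year_one <- function(arm, costs, dtc) {
  stopifnot(inherits(arm, "arm_inputs"), inherits(costs, "cost_inputs"))
  chk_nonneg(dtc, "dtc")
  p_no <- 1 - arm$p_mi - arm$p_stroke - arm$p_death
  dist <- stats::setNames(c(p_no, arm$p_mi, 0, arm$p_stroke, 0, arm$p_death),
                          acs_states)
  c_mi <- costs$c_mi_y1 + if (costs$include_indirect) costs$indirect_mi_y1 else 0
  c_st <- costs$c_stroke_y1 +
    if (costs$include_indirect) costs$indirect_stroke_y1 else 0
  drug <- costs$drug_days * dtc *
    (1 - arm$p_death * (1 - costs$drug_death_fraction))
  cost <- arm$p_mi * c_mi + arm$p_stroke * c_st + arm$p_death * costs$c_death +
    p_no * costs$c_no_event_annual + drug
  structure(list(
    arm_label = arm$arm_label,
    end_distribution = dist,
    life_years = 1 - 0.5 * arm$p_death,
    qalys = p_no * arm$u_no_event + arm$p_mi * arm$u_mi +
      arm$p_stroke * arm$u_stroke + arm$p_death * arm$u_death,
    cost = cost), class = "year_one_result")
}

#' Run the lifetime Markov cohort model
#'
#' Advances the end-of-year-1 state distribution one annual cycle at a
#' time until `max_age` or extinction of the living cohort (< 1e-9).
#' Within a cycle, death (state- and age-specific, see
#' [annual_death_prob()]) is applied first; surviving occupants of the
#' event-free state then split over non-fatal MI (`q_mi`), non-fatal
#' stroke (`q_stroke`) and remaining event-free; tunnel survivors move to
#' their post-event state; post-event survivors stay.  Age advances one
#' year per cycle starting at `start_age + 1` for cycle 1.
#'
#' @param start Named state distribution summing to 1 (e.g. the
#'   `end_distribution` of [run_year_one()]).
#' @param config A [model_config()].
#' @param life_table Optional resolved life table (defaults to the
#'   config's `life_table_ref`).
#' @return A `markov_trace` data.frame: `cycle`, `age`, one column per
#'   state.  Rows sum to 1; `dead` is non-decreasing.
#' @export
run_markov <- function(start, config, life_table = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(life_table)) life_table <- resolve_life_table(config)
  if (length(start) != 6L || is.null(names(start)) ||
      !all(acs_states %in% names(start)))
    vfail("start", "must be a named distribution over the six model states")
  start <- start[acs_states]
  if (abs(sum(start) - 1) > 1e-8) vfail("start", "must sum to 1")
  if (any(start < 0)) vfail("start", "occupancies must be non-negative")

  dp <- death_prob_matrix(config, life_table)
  q_mi <- config$longterm$q_mi
  q_stroke <- config$longterm$q_stroke
  n_max <- length(dp$ages)
  out <- matrix(NA_real_, nrow = n_max, ncol = 6L,
                dimnames = list(NULL, acs_states))
  occ <- as.numeric(start)
  t_used <- 0L
  for (t in seq_len(n_max)) {
    d <- dp$d[t, ]
    live <- occ[1:5]
    surv <- live * (1 - d)
    newly_dead <- sum(live * d)
    occ <- c(surv[1L] * (1 - q_mi - q_stroke),       # stays event-free
             surv[1L] * q_mi,                        # new MI -> tunnel
             surv[2L] + surv[3L],                    # tunnel + post MI
             surv[1L] * q_stroke,                    # new stroke -> tunnel
             surv[4L] + surv[5L],                    # tunnel + post stroke
             occ[6L] + newly_dead)
    out[t, ] <- occ
    t_used <- t
    if (1 - occ[6L] < 1e-9) break
  }
  trace <- data.frame(cycle = seq_len(t_used), age = dp$ages[seq_len(t_used)],
                      out[seq_len(t_used), , drop = FALSE])
  class(trace) <- c("markov_trace", "data.frame")
  attr(trace, "start") <- start
  trace
}

#' Export a Markov trace as CSV
#'
#' Columns `cycle,age,no_event,mi_y1,mi_post,stroke_y1,stroke_post,dead`.
#'
#' @param trace A `markov_trace`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
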