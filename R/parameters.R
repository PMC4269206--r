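#' @keywords internal
"_PACKAGE"

# ---- validation helpers ------------------------------------------------

vfail <- function(field, msg) {
  stop(structure(
    class = c("acs_validation_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = NULL)
  ))
}

chk_num1 <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    vfail(field, "must be a single finite number")
  invisible(x)
}

chk_prob <- function(x, field) {
  chk_num1(x, field)
  if (x < 0 || x > 1) vfail(field, sprintf("probability %g outside [0, 1]", x))
  invisible(x)
}

chk_pos <- function(x, field) {
  chk_num1(x, field)
  if (x <= 0) vfail(field, sprintf("must be > 0, got %g", x))
  invisible(x)
}

chk_nonneg <- function(x, field) {
  chk_num1(x, field)
  if (x < 0) vfail(field, sprintf("must be >= 0, got %g", x))
  invisible(x)
}

chk_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    vfail(field, "must be TRUE or FALSE")
  invisible(x)
}

# pull a required key out of a config section, failing with the dotted path
need <- function(lst, key, section) {
  if (is.null(lst[[key]]))
    vfail(paste0(section, ".", key), "required field is missing")
  lst[[key]]
}

# ---- cohort ------------------------------------------------------------

#' Cohort specification
#'
#' Describes the modelled cohort: a closed group of patients entering the
#' model at the index acute coronary syndrome, followed until `max_age`.
#' The start age and sex mix determine background mortality and the
#' age-band utilities of the long-term model; `cohort_scale` is a pure
#' normalisation (results are reported per `cohort_scale` patients) and
#' never changes incremental cost-effectiveness ratios.
#'
#' @param label Cohort name.
#' @param start_age Age (years) at model entry; default 62.
#' @param male_fraction Proportion male in `[0, 1]`; default 0.72.
#' @param max_age Horizon cap in years (at most 110).
#' @param cohort_scale Positive normalisation constant, default 1.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(label, start_age = 62, male_fraction = 0.72,
                        max_age = 110, cohort_scale = 1) {
  chk_num1(start_age, "cohort.start_age")
  chk_num1(max_age, "cohort.max_age")
  chk_prob(male_fraction, "cohort.male_fraction")
  chk_pos(cohort_scale, "cohort.cohort_scale")
  if (start_age <= 0) vfail("cohort.start_age", "must be > 0")
  if (max_age > 110) vfail("cohort.max_age", "must be <= 110")
  if (start_age >= max_age)
    vfail("cohort.start_age", "must be below `max_age`")
  structure(list(label = as.character(label)[1L], start_age = start_age,
                 male_fraction = male_fraction, max_age = max_age,
                 cohort_scale = cohort_scale),
            class = "cohort_spec")
}

# ---- first-year (decision-tree) arm inputs ------------------------------

#' First-year inputs for one treatment arm
#'
#' Trial-observed first-year probabilities of the three model endpoints
#' (non-fatal myocardial infarction, non-fatal stroke, death from any
#' cause) and the corresponding within-year utility weights.  The death
#' utility is the average within-year quality-of-life accrual of patients
#' who die during the year, not the utility of being dead.
#'
#' @param arm_label Arm name ("ticagrelor" or "clopidogrel" in the
#'   bundled configurations).
#' @param p_mi,p_stroke,p_death First-year endpoint probabilities; their
#'   sum may not exceed 1.
#' @param u_no_event,u_mi,u_stroke,u_death Utility weights in `[0, 1]`.
#' @return An object of class `arm_inputs`.
#' @export
arm_inputs <- function(arm_label, p_mi, p_stroke, p_death,
                       u_no_event, u_mi, u_stroke, u_death) {
  pre <- function(f) paste0("arm.", arm_label, ".", f)
  chk_prob(p_mi, pre("p_mi")); chk_prob(p_stroke, pre("p_stroke"))
  chk_prob(p_death, pre("p_death"))
  if (p_mi + p_stroke + p_death > 1)
    vfail(pre("p_mi"), sprintf(
      "first-year probabilities sum to %g > 1", p_mi + p_stroke + p_death))
  for (u in c("u_no_event", "u_mi", "u_stroke", "u_death"))
    chk_prob(get(u), pre(u))
  structure(list(arm_label = as.character(arm_label)[1L],
                 p_mi = p_mi, p_stroke = p_stroke, p_death = p_death,
                 u_no_event = u_no_event, u_mi = u_mi,
                 u_stroke = u_stroke, u_death = u_death),
            class = "arm_inputs")
}

# ---- long-term (Markov) inputs ------------------------------------------

#' Long-term annual inputs shared by both arms
#'
#' Annual probabilities of the endpoints from the event-free state
#' (extrapolated from Weibull regressions, held constant beyond year 2),
#' age-band utilities of event-free survivors, and the additive utility
#' decrements applied after a non-fatal event (first post-event year
#' versus subsequent years).
#'
#' @param q_mi,q_stroke Annual probabilities of a non-fatal event from the
#'   event-free state.
#' @param q_cv_fatal Annual probability of a fatal cardiovascular event.
#' @param u_age_60_69,u_age_70_79,u_age_80plus Event-free utilities by age
#'   band; ages below 60 use the 60-69 band.
#' @param du_stroke_y1,du_stroke_y2plus,du_mi_y1,du_mi_y2plus Utility
#'   decrements; each must not exceed the smallest band utility.
#' @return An object of class `longterm_inputs`.
#' @export
longterm_inputs <- function(q_mi, q_stroke, q_cv_fatal,
                            u_age_60_69, u_age_70_79, u_age_80plus,
                            du_stroke_y1, du_stroke_y2plus,
                            du_mi_y1, du_mi_y2plus) {
  chk_prob(q_mi, "longterm.q_mi")
  chk_prob(q_stroke, "longterm.q_stroke")
  chk_prob(q_cv_fatal, "longterm.q_cv_fatal")
  if (q_mi + q_stroke + q_cv_fatal > 1)
    vfail("longterm.q_mi", "annual event probabilities sum to > 1")
  chk_prob(u_age_60_69, "longterm.u_age_60_69")
  chk_prob(u_age_70_79, "longterm.u_age_70_79")
  chk_prob(u_age_80plus, "longterm.u_age_80plus")
  umin <- min(u_age_60_69, u_age_70_79, u_age_80plus)
  for (d in c("du_stroke_y1", "du_stroke_y2plus", "du_mi_y1", "du_mi_y2plus")) {
    chk_nonneg(get(d), paste0("longterm.", d))
    if (get(d) > umin)
      vfail(paste0("longterm.", d),
            sprintf("decrement %g exceeds smallest band utility %g", get(d), umin))
  }
  structure(list(q_mi = q_mi, q_stroke = q_stroke, q_cv_fatal = q_cv_fatal,
                 u_age_60_69 = u_age_60_69, u_age_70_79 = u_age_70_79,
                 u_age_80plus = u_age_80plus,
                 du_stroke_y1 = du_stroke_y1, du_stroke_y2plus = du_stroke_y2plus,
                 du_mi_y1 = du_mi_y1, du_mi_y2plus = du_mi_y2plus),
            class = "longterm_inputs")
}

# ---- hazard ratios -------------------------------------------------------

#' Post-event mortality hazard ratios
#'
#' Multiplicative factors on the combined background (life-table plus fatal
#' cardiovascular) death hazard by health state.  The base case uses
#' 1 / 1.6 / 1.4 / 3.23 / 1.5 for no-event / MI year 1 / MI year 2+ /
#' stroke year 1 / stroke year 2+; the "global model" alternative set is
#' available via [global_hazard_ratios()].
#'
#' @param hr_no_event,hr_mi_y1,hr_mi_y2plus,hr_stroke_y1,hr_stroke_y2plus
#'   Positive hazard ratios.
#' @return An object of class `hazard_ratio_set`.
#' @export
hazard_ratio_set <- function(hr_no_event = 1, hr_mi_y1 = 1.6,
                             hr_mi_y2plus = 1.4, hr_stroke_y1 = 3.23,
                             hr_stroke_y2plus = 1.5) {
  for (f in c("hr_no_event", "hr_mi_y1", "hr_mi_y2plus",
              "hr_stroke_y1", "hr_stroke_y2plus"))
    chk_pos(get(f), paste0("hazard_ratios.", f))
  structure(list(hr_no_event = hr_no_event, hr_mi_y1 = hr_mi_y1,
                 hr_mi_y2plus = hr_mi_y2plus, hr_stroke_y1 = hr_stroke_y1,
                 hr_stroke_y2plus = hr_stroke_y2plus),
            class = "hazard_ratio_set")
}

#' @rdname hazard_ratio_set
#' @export
global_hazard_ratios <- function() {
  hazard_ratio_set(hr_no_event = 2, hr_mi_y1 = 6, hr_mi_y2plus = 3,
                   hr_stroke_y1 = 7.43, hr_stroke_y2plus = 3)
}

# ---- costs ---------------------------------------------------------------

#' Cost inputs (EUR, price year 2009)
#'
#' Event costs follow the macro-costing convention: a total for the first
#' post-event year and an annual total for each subsequent year, a one-off
#' cost of death, daily therapy costs per arm, and optional indirect-cost
#' and no-event annual-cost components used only in scenario analyses.
#'
#' `drug_death_fraction` is the fraction of the annual drug cost accrued by
#' patients who die during the treatment year (default 0.5, i.e. decedents
#' are exposed for half a year on average).
#'
#' @param c_mi_y1,c_stroke_y1 Total cost of the first year after a
#'   non-fatal event.
#' @param c_mi_y2plus,c_stroke_y2plus Annual cost in each subsequent year.
#' @param c_death One-off cost of death (EUR 8,650 in the bundled configs).
#' @param c_no_event_annual Annual non-drug cost of the event-free state
#'   (0 in the base case).
#' @param indirect_mi_y1,indirect_stroke_y1,indirect_stroke_y2plus Indirect
#'   (productivity) costs added when `include_indirect` is `TRUE`.
#' @param include_indirect Scenario toggle for indirect costs.
#' @param dtc_ticagrelor,dtc_clopidogrel Daily therapy costs, EUR/day.
#' @param drug_days Days of therapy per treatment year (default 365).
#' @param drug_death_fraction Fraction of annual drug cost accrued by
#'   first-year decedents, in `[0, 1]`.
#' @return An object of class `cost_inputs`.
#' @export
cost_inputs <- function(c_mi_y1, c_stroke_y1, c_mi_y2plus, c_stroke_y2plus,
                        c_death, dtc_ticagrelor, dtc_clopidogrel,
                        c_no_event_annual = 0,
                        indirect_mi_y1 = 0, indirect_stroke_y1 = 0,
                        indirect_stroke_y2plus = 0, include_indirect = FALSE,
                        drug_days = 365, drug_death_fraction = 0.5) {
  for (f in c("c_mi_y1", "c_stroke_y1", "c_mi_y2plus", "c_stroke_y2plus",
              "c_death", "c_no_event_annual", "indirect_mi_y1",
              "indirect_stroke_y1", "indirect_stroke_y2plus",
              "dtc_ticagrelor", "dtc_clopidogrel", "drug_days"))
    chk_nonneg(get(f), paste0("costs.", f))
  chk_prob(drug_death_fraction, "costs.drug_death_fraction")
  chk_flag(include_indirect, "costs.include_indirect")
  structure(list(c_mi_y1 = c_mi_y1, c_stroke_y1 = c_stroke_y1,
                 c_mi_y2plus = c_mi_y2plus, c_stroke_y2plus = c_stroke_y2plus,
                 c_death = c_death, c_no_event_annual = c_no_event_annual,
                 indirect_mi_y1 = indirect_mi_y1,
                 indirect_stroke_y1 = indirect_stroke_y1,
                 indirect_stroke_y2plus = indirect_stroke_y2plus,
                 include_indirect = include_indirect,
                 dtc_ticagrelor = dtc_ticagrelor,
                 dtc_clopidogrel = dtc_clopidogrel,
                 drug_days = drug_days,
                 drug_death_fraction = drug_death_fraction),
            class = "cost_inputs")
}

# ---- discounting ---------------------------------------------------------

#' Discounting specification
#'
#' Annual discount rates for costs and effects (both 3% in the base case).
#' @param rate_costs,rate_effects Non-negative annual rates.
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(rate_costs = 0.03, rate_effects = 0.03) {
  chk_nonneg(rate_costs, "discount.rate_costs")
  chk_nonneg(rate_effects, "discount.rate_effects")
  structure(list(rate_costs = rate_costs, rate_effects = rate_effects),
            class = "discount_spec")
}

# ---- full model configuration -------------------------------------------

#' Assemble and validate a full model configuration
#'
#' @param cohort A [cohort_spec()].
#' @param arm_ticagrelor,arm_clopidogrel [arm_inputs()] per arm.
#' @param longterm A [longterm_inputs()].
#' @param hazard_ratios A [hazard_ratio_set()].
#' @param costs A [cost_inputs()].
#' @param discount A [discount_spec()].
#' @param life_table_ref Bundled life-table fixture name (see
#'   [bundled_life_table()]) or a path to a `age,sex,qx` delimited file.
#' @param psa A [psa_spec()].
#' @param seed Integer master seed for stochastic stages.
#' @return An object of class `model_config`.
#' @export
model_config <- function(cohort, arm_ticagrelor, arm_clopidogrel, longterm,
                         hazard_ratios = hazard_ratio_set(),
                         costs, discount = discount_spec(),
                         life_table_ref = "german_2009_synthetic",
                         psa = psa_spec(), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(arm_ticagrelor, "arm_inputs"),
            inherits(arm_clopidogrel, "arm_inputs"),
            inherits(longterm, "longterm_inputs"),
            inherits(hazard_ratios, "hazard_ratio_set"),
            inherits(costs, "cost_inputs"),
            inherits(discount, "discount_spec"),
            inherits(psa, "psa_spec"))
  chk_num1(seed, "seed")
  structure(list(cohort = cohort, arm_ticagrelor = arm_ticagrelor,
                 arm_clopidogrel = arm_clopidogrel, longterm = longterm,
                 hazard_ratios = hazard_ratios, costs = costs,
                 discount = discount,
                 life_table_ref = as.character(life_table_ref)[1L],
                 psa = psa, seed = as.integer(seed)),
            class = "model_config")
}

section_keys <- list(
  cohort = c("label", "start_age", "male_fraction", "max_age", "cohort_scale"),
  arm = c("p_mi", "p_stroke", "p_death",
          "u_no_event", "u_mi", "u_stroke", "u_death"),
  longterm = c("q_mi", "q_stroke", "q_cv_fatal", "u_age_60_69", "u_age_70_79",
               "u_age_80plus", "du_stroke_y1", "du_stroke_y2plus",
               "du_mi_y1", "du_mi_y2plus"),
  hazard_ratios = c("hr_no_event", "hr_mi_y1", "hr_mi_y2plus",
                    "hr_stroke_y1", "hr_stroke_y2plus"),
  costs = c("c_mi_y1", "c_stroke_y1", "c_mi_y2plus", "c_stroke_y2plus",
            "c_death", "dtc_ticagrelor", "dtc_clopidogrel"),
  discount = c("rate_costs", "rate_effects"))

#' Load a model configuration from YAML (or an equivalent list)
#'
#' Reads the documented key schema, applies defaults only where a default
#' is part of the model definition, and validates every invariant.  Errors
#' name the offending field with its dotted path.
#'
#' @param source Path to a YAML document, or a pre-parsed nested list.
#' @return A validated [model_config()].
#' @export
load_config <- function(source) {
  doc <- if (is.character(source)) {
    if (!file.exists(source)) vfail("config", paste("no such file:", source))
    yaml::read_yaml(source)
  } else if (is.list(source)) source else
    vfail("config", "must be a file path or a list")

  grab <- function(section, keys, required = keys) {
    x <- doc[[section]]
    if (is.null(x)) vfail(section, "required section is missing")
    for (k in required) if (is.null(x[[k]]))
      vfail(paste0(section, ".", k), "required field is missing")
    x
  }
  co <- grab("cohort", required = c("label"))
  arms <- doc[["arms"]]
  if (is.null(arms)) vfail("arms", "required section is missing")
  mk_arm <- function(name) {
    a <- arms[[name]]
    if (is.null(a)) vfail(paste0("arms.", name), "required section is missing")
    for (k in section_keys$arm) if (is.null(a[[k]]))
      vfail(paste0("arms.", name, ".", k), "required field is missing")
    arm_inputs(name, a$p_mi, a$p_stroke, a$p_death,
               a$u_no_event, a$u_mi, a$u_stroke, a$u_death)
  }
  lt <- grab("longterm", required = section_keys$longterm)
  hr <- doc[["hazard_ratios"]]
  cs <- grab("costs", required = section_keys$costs)
  di <- doc[["discount"]]
  ps <- doc[["psa"]]

  cohort <- cohort_spec(
    label = co$label,
    start_age = co$start_age %||% 62,
    male_fraction = co$male_fraction %||% 0.72,
    max_age = co$max_age %||% 110,
    cohort_scale = co$cohort_scale %||% 1)
  longterm <- do.call(longterm_inputs, lt[section_keys$longterm])
  hrs <- if (is.null(hr)) hazard_ratio_set() else
    do.call(hazard_ratio_set, hr[intersect(names(hr), section_keys$hazard_ratios)])
  costs <- do.call(cost_inputs, cs[intersect(
    names(cs), names(formals(cost_inputs)))])
  disc <- if (is.null(di)) discount_spec() else
    discount_spec(di$rate_costs %||% 0.03, di$rate_effects %||% 0.03)
  psa <- if (is.null(ps)) psa_spec() else do.call(psa_spec, ps[intersect(
    names(ps), names(formals(psa_spec)))])

  model_config(cohort = cohort,
               arm_ticagrelor = mk_arm("ticagrelor"),
               arm_clopidogrel = mk_arm("clopidogrel"),
               longterm = longterm, hazard_ratios = hrs, costs = costs,
               discount = disc,
               life_table_ref = doc$life_table %||% "german_2009_synthetic",
               psa = psa, seed = doc$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a model configuration back to the YAML key schema
#'
#' `serialize_config()` returns the nested list; `write_config()` writes it
#' as YAML.  `load_config(write_config(x))` reproduces every numeric field
#' exactly.
#'
#' @param config A [model_config()].
#' @param path Output file path.
#' @return The nested list (invisibly for `write_config`).
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "model_config"))
  strip <- function(x) unclass(x)
  arm_out <- function(a) { a <- unclass(a); a$arm_label <- NULL; a }
  list(cohort = strip(config$cohort),
       arms = list(ticagrelor = arm_out(config$arm_ticagrelor),
                   clopidogrel = arm_out(config$arm_clopidogrel)),
       longterm = strip(config$longterm),
       hazard_ratios = strip(config$hazard_ratios),
       costs = strip(config$costs),
       discount = strip(config$discount),
       life_table = config$life_table_ref,
       psa = strip(config$psa),
       seed = config$seed)
}

#' @rdname serialize_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(serialize_config(config), path, precision = 15L)
  invisible(path)
}

#' Bundled cohort configurations
#'
#' The three shipped analysis cohorts (patients on low-dose aspirin):
#' `"overall"` (all acute coronary syndrome patients), `"nstemi_ua"`
#' (non-ST-elevation MI / unstable angina) and `"stemi"`.  Every numeric
#' field carries the published model input value; the subgroup first-year
#' MI cost substitutes the subgroup acute-hospitalisation component into
#' the overall first-year total.
#'
#' @param cohort One of `"overall"`, `"nstemi_ua"`, `"stemi"`.
#' @return `default_config()`: one [model_config()]; `default_configs()`:
#'   a named list of all three.
#' @export
default_config <- function(cohort = c("overall", "nstemi_ua", "stemi")) {
  cohort <- match.arg(cohort)
  path <- system.file("configs", paste0(cohort, ".yaml"), package = "acsCEA",
                      mustWork = TRUE)
  load_config(path)
}

#' @rdname default_config
#' @export
default_configs <- function() {
  cohorts <- c("overall", "nstemi_ua", "stemi")
  stats::setNames(lapply(cohorts, default_config), cohorts)
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>", x$cohort$label, "\n")
  cat(sprintf("  cohort: start age %g, %.0f%% male, horizon %g\n",
              x$cohort$start_age, 100 * x$cohort$male_fraction,
              x$cohort$max_age))
  cat(sprintf("  year-1 p(mi/stroke/death): ticagrelor %g/%g/%g, clopidogrel %g/%g/%g\n",
              x$arm_ticagrelor$p_mi, x$arm_ticagrelor$p_stroke,
              x$arm_ticagrelor$p_death, x$arm_clopidogrel$p_mi,
              x$arm_clopidogrel$p_stroke, x$arm_clopidogrel$p_death))
  cat(sprintf("  DTC: ticagrelor %.2f, clopidogrel %.2f EUR/day; discount %g%%/%g%%\n",
              x$costs$dtc_ticagrelor, x$costs$dtc_clopidogrel,
              100 * x$discount$rate_costs, 100 * x$discount$rate_effects))
  cat("  life table:", x$life_table_ref, "\n")
  invisible(x)
}
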