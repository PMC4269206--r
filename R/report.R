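# Report generation: base-case tables, PSA exports, scenario tables, and a
# run manifest sufficient to reproduce every output.

# djb2-style rolling hash (mod 2^31 - 1) of a character scalar; a plain-R
# checksum good enough to detect config drift between runs
text_checksum <- function(txt) {
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

config_checksum <- function(config) {
  text_checksum(paste(utils::capture.output(
    utils::str(serialize_config(config), digits.d = 15)), collapse = "\n"))
}

write_manifest <- function(out_dir, config, seed, extra = character()) {
  lines <- c(
    sprintf("package: acsCEA %s",
            as.character(utils::packageVersion("acsCEA"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("config_checksum: %s", config_checksum(config)),
    sprintf("cohort: %s", config$cohort$label),
    sprintf("life_table: %s", config$life_table_ref),
    sprintf("seed: %d", as.integer(seed)),
    extra)
  writeLines(lines, file.path(out_dir, "manifest.txt"))
}

resolve_cmd_config <- function(config, cohort) {
  if (inherits(config, "model_config")) config
  else if (is.character(config)) load_config(config)
  else if (is.null(config)) default_config(cohort)
  else stop("`config` must be a model_config, a YAML path, or NULL",
            call. = FALSE)
}

# Table-6-style long table: one row per outcome measure
cea_table <- function(res) {
  val <- function(f) c(f(res$ticagrelor), f(res$clopidogrel),
                       f(res$ticagrelor) - f(res$clopidogrel))
  data.frame(
    measure = c("costs_eur", "life_years", "qalys"),
    ticagrelor = c(res$ticagrelor$cost, res$ticagrelor$life_years,
                   res$ticagrelor$qalys),
    clopidogrel = c(res$clopidogrel$cost, res$clopidogrel$life_years,
                    res$clopidogrel$qalys),
    incremental = c(res$delta_cost, res$delta_ly, res$delta_qaly),
    icer = c(NA, res$icer_ly, res$icer_qaly),
    dominance = res$dominance)
}

#' Run the deterministic base case and write its outputs
#'
#' Writes, per cohort: the cost / life-year / QALY table with increments
#' and ICERs (`cea_table.csv` and `cea_result.json`), the per-arm Markov
#' traces, and a manifest.
#'
#' @param config A [model_config()], a YAML path, or `NULL` (bundled
#'   config for `cohort`).
#' @param cohort Bundled cohort name used when `config` is `NULL`.
#' @param life_table Optional life-table fixture name or path overriding
#'   the config's reference.
#' @param out_dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest (the base case itself is
#'   deterministic).
#' @return The `cea_result`, invisibly.
#' @export
cmd_base_case <- function(config = NULL, cohort = "overall",
                          life_table = NULL, out_dir, seed = 1L) {
  cfg <- resolve_cmd_config(config, cohort)
  if (!is.null(life_table)) cfg$life_table_ref <- life_table
  lt <- resolve_life_table(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_cea(cfg, lt)
  utils::write.csv(cea_table(res), file.path(out_dir, "cea_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cea_row(res), file.path(out_dir, "cea_result.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  traces <- attr(res, "traces")
  write_trace(traces$ticagrelor, file.path(out_dir, "trace_ticagrelor.csv"))
  write_trace(traces$clopidogrel, file.path(out_dir, "trace_clopidogrel.csv"))
  write_manifest(out_dir, cfg, seed, "command: base_case")
  invisible(res)
}

#' Run the probabilistic sensitivity analysis and write its outputs
#'
#' Writes the cost-effectiveness-plane points (`ce_plane.csv`), the
#' acceptability curve (`ceac.csv`), a run log with the failed-draw count,
#' and a manifest.
#'
#' @inheritParams cmd_base_case
#' @param n Number of draws (defaults to the config's PSA spec).
#' @param seed Master seed for the draws.
#' @param thresholds Optional willingness-to-pay grid.
#' @return The `psa_result`, invisibly.
#' @export
cmd_psa <- function(config = NULL, cohort = "overall", life_table = NULL,
                    out_dir, n = NULL, seed = 1L, thresholds = NULL) {
  cfg <- resolve_cmd_config(config, cohort)
  if (!is.null(life_table)) cfg$life_table_ref <- life_table
  if (!is.null(n) && n < 1) stop("`n` must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cfg$psa
  spec$seed <- as.integer(seed)
  draws <- run_psa(spec, cfg, n = n)
  curve <- ceac(draws, thresholds %||% psa_thresholds(spec))
  utils::write.csv(as.data.frame(draws), file.path(out_dir, "ce_plane.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(curve), file.path(out_dir, "ceac.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("draws_requested: %d", NROW(draws) +
                         attr(draws, "n_failed")),
               sprintf("draws_failed: %d", attr(draws, "n_failed"))),
             file.path(out_dir, "psa_log.txt"))
  write_manifest(out_dir, cfg, seed,
                 c("command: psa", sprintf("iterations: %d", NROW(draws))))
  invisible(draws)
}

#' Run a deterministic scenario set and write its outputs
#'
#' Writes one result row per scenario (`scenarios.csv`), the tornado
#' ordering (`tornado.csv`), and a manifest.
#'
#' @inheritParams cmd_base_case
#' @param scenario_set_name Bundled scenario set name, or a list of
#'   [scenario_spec()]s.
#' @return The scenario table, invisibly.
#' @export
cmd_scenarios <- function(config = NULL, cohort = "overall",
                          life_table = NULL, out_dir,
                          scenario_set_name = "paper_univariate",
                          seed = 1L) {
  cfg <- resolve_cmd_config(config, cohort)
  if (!is.null(life_table)) cfg$life_table_ref <- life_table
  scenarios <- if (is.character(scenario_set_name))
    scenario_set(scenario_set_name) else scenario_set_name
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lt <- resolve_life_table(cfg)
  tab <- if (length(scenarios)) run_scenarios(cfg, scenarios, lt) else {
    empty <- cea_row(run_cea(cfg, lt, keep_traces = FALSE))[0, ]
    empty$group <- character(0)
    empty
  }
  utils::write.csv(tab, file.path(out_dir, "scenarios.csv"),
                   row.names = FALSE)
  tor <- tornado(cfg, Filter(function(s) s$group != "base", scenarios), lt)
  utils::write.csv(tor, file.path(out_dir, "tornado.csv"), row.names = FALSE)
  write_manifest(out_dir, cfg, seed,
                 c("command: scenarios",
                   sprintf("scenarios: %s",
                           paste(vapply(scenarios, `[[`, "", "label"),
                                 collapse = "; "))))
  invisible(tab)
}
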