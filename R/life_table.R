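# Life tables: generation (Gompertz-Makeham), bundled fixtures, file I/O.
#
# A life table is a data.frame with columns age (integer years, contiguous),
# sex ("male"/"female") and qx (annual probability of death), with qx = 1 at
# the terminal age of each sex.

#' Gompertz-Makeham hazard parameters
#'
#' Annual mortality hazard `h(age) = a + b * exp(c * age)`: an
#' age-independent background component `a` plus an exponentially ageing
#' senescent component.
#'
#' @param a Background hazard per year (>= 0).
#' @param b Baseline senescent hazard per year (> 0).
#' @param c Ageing rate per year (> 0).
#' @return An object of class `gm_params`.
#' @export
gm_params <- function(a = 5e-5, b = 3.5e-5, c = 0.095) {
  chk_nonneg(a, "gm.a"); chk_pos(b, "gm.b"); chk_pos(c, "gm.c")
  structure(list(a = a, b = b, c = c), class = "gm_params")
}

# one-year death probability from the GM hazard integrated over [age, age+1]
gm_qx <- function(age, p) {
  cum <- p$a + p$b / p$c * exp(p$c * age) * (exp(p$c) - 1)
  1 - exp(-cum)
}

#' Generate a synthetic life table from a Gompertz-Makeham hazard
#'
#' `qx(age) = 1 - exp(-H(age))` with `H` the hazard integrated over one
#' year of age; `qx` is forced to 1 at the terminal age so the table closes
#' the cohort.  Both sexes receive the same parameters unless
#' `params_female` is given.
#'
#' @param params A [gm_params()] (used for males, and for females when
#'   `params_female` is `NULL`).
#' @param ages Contiguous integer age range, e.g. `0:110`.
#' @param params_female Optional separate female parameters.
#' @return A life-table data.frame (`age`, `sex`, `qx`).
#' @export
generate_life_table <- function(params = gm_params(), ages = 0:110,
                                params_female = NULL) {
  if (length(ages) == 0L) vfail("life_table.ages", "empty age range")
  ages <- sort(as.integer(ages))
  if (!all(diff(ages) == 1L)) vfail("life_table.ages", "ages must be contiguous")
  if (is.null(params_female)) params_female <- params
  stopifnot(inherits(params, "gm_params"), inherits(params_female, "gm_params"))
  one <- function(p, sex) {
    qx <- gm_qx(ages, p)
    qx[length(qx)] <- 1
    data.frame(age = ages, sex = sex, qx = pmin(qx, 1))
  }
  lt <- rbind(one(params, "male"), one(params_female, "female"))
  validate_life_table(lt)
}

#' Validate a life table
#'
#' Checks column names, probability range, per-sex age contiguity and the
#' terminal closure `qx = 1`.
#'
#' @param lt A data.frame with columns `age`, `sex`, `qx`.
#' @return The validated life table (invisibly classed `life_table`).
#' @export
validate_life_table <- function(lt) {
  if (!is.data.frame(lt) || !all(c("age", "sex", "qx") %in% names(lt)))
    vfail("life_table", "needs columns age, sex, qx")
  if (any(!lt$sex %in% c("male", "female")))
    vfail("life_table.sex", "values must be 'male' or 'female'")
  if (any(lt$qx < 0 | lt$qx > 1) || any(!is.finite(lt$qx)))
    vfail("life_table.qx", "probabilities must lie in [0, 1]")
  for (s in unique(lt$sex)) {
    sub <- lt[lt$sex == s, ]
    sub <- sub[order(sub$age), ]
    if (any(diff(sub$age) != 1L))
      vfail("life_table.age", paste("ages not contiguous for sex", s))
    if (sub$qx[nrow(sub)] != 1)
      vfail("life_table.qx", paste("terminal qx must be 1 for sex", s))
  }
  class(lt) <- c("life_table", "data.frame")
  lt
}

# per-sex GM parameters of the bundled fixtures; the german_2009 set is a
# synthetic reconstruction calibrated to published summary levels of the
# official German 2009/11 period table (see the methods vignette)
acs_life_table_fixtures <- function() {
  list(
    synthetic_default = list(male = gm_params(), female = gm_params()),
    german_2009_synthetic = list(
      male = gm_params(a = 5e-4, b = 2.75e-5, c = 0.0958),
      female = gm_params(a = 3e-4, b = 7.2e-6, c = 0.108)))
}

#' Bundled life-table fixtures
#'
#' Two fixtures ship with the package: `"synthetic_default"` (a single
#' Gompertz-Makeham schedule for both sexes) and `"german_2009_synthetic"`
#' (a per-sex Gompertz-Makeham reconstruction of German period mortality
#' around 2009; synthetic, calibrated to published summary levels, not a
#' transcription).  `"german_2009"` is accepted as an alias of the latter.
#'
#' @param name Fixture name.
#' @return A `life_table` data.frame spanning ages 0-110.
#' @export
bundled_life_table <- function(name) {
  fixtures <- acs_life_table_fixtures()
  if (identical(name, "german_2009")) name <- "german_2009_synthetic"
  if (!name %in% names(fixtures))
    stop(sprintf("unknown life table fixture '%s'; available: %s", name,
                 paste(names(fixtures), collapse = ", ")), call. = FALSE)
  p <- fixtures[[name]]
  generate_life_table(p$male, ages = 0:110, params_female = p$female)
}

#' Read / write a life table as delimited text
#'
#' Comma- or tab-separated with header `age,sex,qx`.
#'
#' @param path File path.
#' @param lt A life table.
#' @return `read_life_table()`: a validated `life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) vfail("life_table", paste("no such file:", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  lt <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_life_table(lt)
}

#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# resolve a config's life_table_ref: fixture name or file path
resolve_life_table <- function(ref) {
  if (inherits(ref, "life_table")) return(ref)
  if (inherits(ref, "model_config")) ref <- ref$life_table_ref
  fixtures <- names(acs_life_table_fixtures())
  if (ref %in% c(fixtures, "german_2009")) bundled_life_table(ref)
  else if (file.exists(ref)) read_life_table(ref)
  else bundled_life_table(ref) # informative unknown-fixture error
}

# sex-mixed annual death probability lookup vector indexed by age
mixed_qx <- function(lt, male_fraction, ages) {
  m <- lt[lt$sex == "male", ]
  f <- lt[lt$sex == "female", ]
  qm <- m$qx[match(ages, m$age)]
  qf <- f$qx[match(ages, f$age)]
  if (anyNA(qm) || anyNA(qf))
    vfail("cohort.max_age", "model ages extend beyond the life table")
  male_fraction * qm + (1 - male_fraction) * qf
}
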