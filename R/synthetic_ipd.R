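# Synthetic individual patient data: latent Weibull event times per
# endpoint (competing risks, earliest wins) with administrative censoring
# at the 6-, 9- or 12-month visit, calibrated so the marginal 12-month
# cumulative incidence of each endpoint matches the configured first-year
# probability.

ipd_endpoints <- c("mi", "stroke", "death")

# marginal 12-month cumulative incidence of endpoint e under competing
# latent Weibull times: integral of f_e(t) * prod_{j != e} S_j(t) over (0,1]
competing_incidence <- function(shapes, scales, e) {
  f <- function(t) {
    h <- shapes[e] / scales[e] * (t / scales[e])^(shapes[e] - 1)
    stot <- rep(1, length(t))
    for (j in seq_along(shapes))
      stot <- stot * exp(-(t / scales[j])^shapes[j])
    h * stot
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10, subdivisions = 400L)$value
}

#' Generate PLATO-like synthetic individual patient data
#'
#' One latent Weibull time is drawn per endpoint (non-fatal MI, non-fatal
#' stroke, death) and the earliest determines the record; administrative
#' censoring occurs at the 6-, 9- or 12-month visit with probabilities
#' `censor_mix`.  Latent scales are recalibrated by a fixed-point loop
#' (at most 5 rounds) so the *marginal* 12-month cumulative incidence of
#' each endpoint — i.e. the competing-risks cumulative incidence — matches
#' the arm's configured first-year probability to within 1e-3 absolute.
#' Event times are recorded in years at day (1/365) resolution.
#'
#' @param arm An [arm_inputs()] holding the target first-year
#'   probabilities.
#' @param n Number of patients.
#' @param censor_mix Probabilities of leaving at the 6-, 9- and 12-month
#'   visit; must sum to 1 (default `c(0.2, 0.2, 0.6)`).
#' @param seed Integer seed; identical seeds give identical output.
#' @param longterm Optional [longterm_inputs()]; when supplied, latent
#'   shapes come from [calibrate_from_probs()] against the conditional
#'   year-2 probabilities, otherwise latent times are exponential (k = 1).
#' @return A data.frame (`patient_id`, `arm`, `time`, `event`) with
#'   `event` one of `"mi"`, `"stroke"`, `"death"`, `"censored"`.
#' @export
generate_ipd <- function(arm, n, censor_mix = c(0.2, 0.2, 0.6), seed = 1L,
                         longterm = NULL) {
  stopifnot(inherits(arm, "arm_inputs"))
  if (n < 1) vfail("n", "need at least one patient")
  if (length(censor_mix) != 3L || any(censor_mix < 0) ||
      abs(sum(censor_mix) - 1) > 1e-8)
    vfail("censor_mix", "must be three non-negative proportions summing to 1")

  p1 <- c(mi = arm$p_mi, stroke = arm$p_stroke, death = arm$p_death)
  p2c <- if (is.null(longterm)) p1 else
    c(mi = longterm$q_mi, stroke = longterm$q_stroke,
      death = longterm$q_cv_fatal)
  active <- p1 > 0

  shapes <- scales <- stats::setNames(rep(NA_real_, 3L), ipd_endpoints)
  if (any(active)) {
    for (e in ipd_endpoints[active]) {
      fit <- calibrate_from_probs(p1[[e]], max(p2c[[e]], 1e-6))
      shapes[e] <- fit$shape; scales[e] <- fit$scale
    }
    # fixed-point recalibration of the marginal targets against the
    # competing-risks distortion (shape held fixed, scale re-solved)
    target <- p1[active]
    ptilde <- target
    for (round in 1:5) {
      ach <- vapply(names(target), function(e)
        competing_incidence(shapes[active], scales[active],
                            match(e, names(target))), numeric(1L))
      err <- target - ach
      if (max(abs(err)) < 1e-3 && round > 1) break
      ptilde <- pmin(pmax(ptilde + err, 1e-8), 1 - 1e-8)
      for (e in names(target))
        scales[e] <- (-log1p(-ptilde[[e]]))^(-1 / shapes[e]) # H(1) inversion
    }
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  lat <- matrix(Inf, nrow = n, ncol = 3L,
                dimnames = list(NULL, ipd_endpoints))
  for (e in ipd_endpoints[active]) {
    u <- stats::runif(n)
    lat[, e] <- scales[e] * (-log(u))^(1 / shapes[e])
  }
  cens <- sample(c(0.5, 0.75, 1.0), n, replace = TRUE, prob = censor_mix)
  tmin <- do.call(pmin, as.data.frame(lat))
  which_e <- ipd_endpoints[max.col(-lat, ties.method = "first")]
  is_event <- tmin < cens
  # day resolution, at least one day, never beyond the censoring visit
  t_evt <- pmin(pmax(round(tmin * 365), 1) / 365, cens)
  data.frame(
    patient_id = seq_len(n),
    arm = arm$arm_label,
    time = ifelse(is_event, t_evt, cens),
    event = ifelse(is_event, which_e, "censored"),
    stringsAsFactors = FALSE)
}

#' Read / write individual patient data as CSV
#'
#' Header `patient_id,arm,time,event`.
#'
#' @param ipd An IPD data.frame as from [generate_ipd()].
#' @param path File path.
#' @return `read_ipd()`: the IPD data.frame.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(ipd, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  if (!file.exists(path)) vfail("ipd", paste("no such file:", path))
  ipd <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "arm", "time", "event") %in% names(ipd)))
    vfail("ipd", "needs columns patient_id, arm, time, event")
  ipd
}
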