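# Weibull event-time models: maximum likelihood under right censoring,
# survival/conditional-probability conversions, and the closed-form
# calibration that inverts a (year-1, conditional year-2) probability pair
# back to shape/scale.  S(t) = exp(-(t/lambda)^k).

new_weibull_fit <- function(shape, scale, vcov_log = matrix(0, 2, 2),
                            n_events = NA_integer_, n_censored = NA_integer_,
                            loglik = NA_real_) {
  dimnames(vcov_log) <- list(c("log_shape", "log_scale"),
                             c("log_shape", "log_scale"))
  structure(list(shape = shape, scale = scale, vcov_log = vcov_log,
                 n_events = n_events, n_censored = n_censored,
                 loglik = loglik),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> shape %.4f, scale %.4f (%d events, %d censored)\n",
              x$shape, x$scale,
              if (is.na(x$n_events)) 0L else x$n_events,
              if (is.na(x$n_censored)) 0L else x$n_censored))
  invisible(x)
}

# negative log-likelihood and gradient on theta = (log k, log lambda);
# delta = 1 for events of the fitted endpoint, 0 for censored
weib_negll <- function(theta, t, delta) {
  k <- exp(theta[1L]); lam <- exp(theta[2L])
  w <- (t / lam)^k
  -(sum(delta * (log(k) - k * log(lam) + (k - 1) * log(t))) - sum(w))
}

weib_negll_grad <- function(theta, t, delta) {
  k <- exp(theta[1L]); lam <- exp(theta[2L])
  lt <- log(t) - log(lam)
  w <- exp(k * lt)
  dk <- sum(delta * (1 / k + lt)) - sum(w * lt)   # d loglik / d k
  dv <- k * (sum(w) - sum(delta))                 # d loglik / d log lambda
  c(-dk * k, -dv)
}

#' Fit a Weibull event-time model by maximum likelihood
#'
#' Fits one endpoint of an individual-patient-data set under right
#' censoring: records of other endpoints and administratively censored
#' records are both treated as censored at their recorded time.
#' Optimisation runs on log-parameters (positivity for free) with an
#' analytic gradient; the covariance of the log-parameters comes from the
#' observed information at the optimum.
#'
#' @param ipd Data frame with columns `time` (> 0, years) and `event`
#'   (`"mi"`, `"stroke"`, `"death"` or `"censored"`), as produced by
#'   [generate_ipd()].
#' @param endpoint Which event kind to fit.
#' @param max_iter Iteration cap (default 500).
#' @param grad_tol Convergence tolerance on the gradient norm (default 1e-8,
#'   relative to the number of observations).
#' @return A `weibull_fit` with shape, scale, log-parameter covariance and
#'   event/censoring counts.
#' @export
fit_weibull_mle <- function(ipd, endpoint = c("mi", "stroke", "death"),
                            max_iter = 500L, grad_tol = 1e-8) {
  endpoint <- match.arg(endpoint)
  if (!all(c("time", "event") %in% names(ipd)))
    vfail("ipd", "needs columns time and event")
  t <- as.numeric(ipd$time)
  if (any(t <= 0)) vfail("ipd.time", "all times must be > 0")
  delta <- as.numeric(ipd$event == endpoint)
  d <- sum(delta)
  if (d < 2)
    stop(sprintf("cannot fit endpoint '%s': %d event(s), need at least 2",
                 endpoint, d), call. = FALSE)
  # exponential start: k = 1, lambda = total exposure / events
  theta0 <- c(0, log(sum(t) / d))
  opt <- stats::optim(theta0, weib_negll, weib_negll_grad, t = t,
                      delta = delta, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  # Newton polish: BFGS stops on function change, which for large samples
  # leaves a per-observation gradient above the documented tolerance
  theta <- opt$par
  H <- stats::optimHess(theta, weib_negll, weib_negll_grad,
                        t = t, delta = delta)
  for (it in 1:25) {
    g <- weib_negll_grad(theta, t, delta)
    if (sqrt(sum(g^2)) / length(t) <= grad_tol) break
    step <- tryCatch(solve(H, g), error = function(e) g * 0)
    cand <- theta - step
    if (!all(is.finite(cand)) ||
        weib_negll(cand, t, delta) > weib_negll(theta, t, delta) + 1e-9) break
    theta <- cand
    H <- stats::optimHess(theta, weib_negll, weib_negll_grad,
                          t = t, delta = delta)
  }
  g <- weib_negll_grad(theta, t, delta)
  if (sqrt(sum(g^2)) / length(t) > grad_tol)
    stop(sprintf(paste0("Weibull fit for '%s' did not converge: gradient norm ",
                        "%.3e after %d evaluations (code %d)"),
                 endpoint, sqrt(sum(g^2)), opt$counts[1L], opt$convergence),
         call. = FALSE)
  opt$par <- theta
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  vc <- (vc + t(vc)) / 2
  new_weibull_fit(shape = exp(opt$par[1L]), scale = exp(opt$par[2L]),
                  vcov_log = vc, n_events = as.integer(d),
                  n_censored = as.integer(length(t) - d),
                  loglik = -opt$value)
}

#' Weibull survival function
#'
#' `S(t) = exp(-(t/lambda)^k)`.
#'
#' @param fit A `weibull_fit` (from [fit_weibull_mle()] or
#'   [calibrate_from_probs()]).
#' @param t Time in years, `>= 0` (vectorised).
#' @return Survival probabilities.
#' @export
survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (any(t < 0)) vfail("t", "time must be >= 0")
  exp(-(t / fit$scale)^fit$shape)
}

#' Conditional annual event probability
#'
#' Probability of the event during `year`, conditional on being event-free
#' at its start: `(S(year-1) - S(year)) / S(year-1)`.  The lifetime model
#' uses the year-2 value and holds it constant in later cycles.
#'
#' @param fit A `weibull_fit`.
#' @param year Integer year index `>= 1`.
#' @return A probability.
#' @export
conditional_annual_prob <- function(fit, year) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (any(year < 1) || any(year != floor(year)))
    vfail("year", "must be an integer >= 1")
  s0 <- survival_at(fit, year - 1)
  if (any(s0 == 0)) stop("conditional probability undefined: S(year-1) = 0",
                         call. = FALSE)
  (s0 - survival_at(fit, year)) / s0
}

#' Calibrate a Weibull distribution to two printed probabilities
#'
#' Inverts the pair (first-year cumulative probability `p_year1`,
#' conditional second-year probability `p_year2_conditional`) to the unique
#' Weibull shape/scale, via `2^k - 1 = log(1 - p2c) / log(1 - p1)`:
#' with `H(t) = (t/lambda)^k`, `H(1) = -log(1 - p1)` and
#' `H(2) - H(1) = -log(1 - p2c)`.  Equal probabilities give `k = 1`
#' (memoryless, exponential).  This replaces the unavailable patient-level
#' regression stage when only the published probabilities are known.
#'
#' @param p_year1 First-year cumulative event probability, in (0, 1).
#' @param p_year2_conditional Conditional year-2 probability, in (0, 1).
#' @return A `weibull_fit` with zero covariance.
#' @export
calibrate_from_probs <- function(p_year1, p_year2_conditional) {
  chk_num1(p_year1, "p_year1"); chk_num1(p_year2_conditional, "p_year2_conditional")
  if (p_year1 <= 0 || p_year1 >= 1)
    vfail("p_year1", "must lie strictly inside (0, 1)")
  if (p_year2_conditional <= 0 || p_year2_conditional >= 1)
    vfail("p_year2_conditional", "must lie strictly inside (0, 1)")
  h1 <- -log1p(-p_year1)              # cumulative hazard over year 1
  h2 <- -log1p(-p_year2_conditional)  # added cumulative hazard over year 2
  k <- log2(1 + h2 / h1)
  if (!is.finite(k) || k <= 0)
    stop(sprintf("infeasible probability pair (%g, %g)", p_year1,
                 p_year2_conditional), call. = FALSE)
  new_weibull_fit(shape = k, scale = h1^(-1 / k),
                  n_events = 0L, n_censored = 0L)
}
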