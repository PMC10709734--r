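#' Parametric survival models
#'
#' A `survival_model` bundles a parametric family with its parameters and
#' provides the survival function used everywhere else in the package:
#' extrapolation beyond trial follow-up, time-dependent Markov transition
#' probabilities, and event-time simulation.
#'
#' All families use the (lambda, gamma) convention of published
#' health-economic survival tables: `lambda` plays the scale role and
#' `gamma` the shape role.  The concrete parameterizations are:
#'
#' \describe{
#'   \item{exponential}{S(t) = exp(-lambda t); `gamma` unused.}
#'   \item{weibull}{proportional-hazards form, S(t) = exp(-lambda t^gamma).}
#'   \item{gompertz}{hazard h(t) = lambda exp(gamma t), so
#'     S(t) = exp(-(lambda/gamma)(exp(gamma t) - 1)); gamma = 0 reduces to
#'     the exponential.}
#'   \item{log_logistic}{S(t) = 1 / (1 + (t/lambda)^gamma) with `lambda` the
#'     scale (median) and `gamma` the shape.}
#'   \item{log_normal}{S(t) = 1 - Phi((log t - mu)/sigma) with mu = lambda
#'     (meanlog) and sigma = gamma (sdlog).  Published parameter tables
#'     occasionally carry a negative shape for the log-normal, which is
#'     inadmissible as a log-scale standard deviation; when
#'     `allow_abs_gamma = TRUE` (the default) the absolute value is used and
#'     a warning is emitted, so the table stays usable while the
#'     inconsistency is surfaced.}
#'   \item{generalized_gamma}{the stable (mu, sigma, Q) parameterization of
#'     Prentice, as used by Stata's streg and \pkg{flexsurv}; mu = lambda,
#'     sigma = gamma, and `extra` carries Q.}
#' }
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"log_logistic"`, `"log_normal"`, `"generalized_gamma"`.
#' @param lambda Scale-role parameter (meanlog for the log-normal, mu for
#'   the generalized gamma).
#' @param gamma Shape-role parameter; omit for the exponential.
#' @param extra Second shape parameter Q, generalized gamma only.
#' @param allow_abs_gamma Log-normal only: replace a negative `gamma` by its
#'   absolute value (with a warning) instead of failing.
#'
#' @return An object of class `"survival_model"`.
#' @examples
#' m <- survival_model("weibull", lambda = 0.015, gamma = 1.16)
#' survival_fn(m, c(0, 1, 5, 10))
#' cycle_transition_prob(m, t = 5, u = 1)
#' @export
survival_model <- function(family, lambda, gamma = NULL, extra = NULL,
                           allow_abs_gamma = TRUE) {
  family <- match.arg(family, surv_families())
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda)) {
    stop("`lambda` must be a single finite number", call. = FALSE)
  }
  if (family == "exponential") {
    if (!is.null(gamma)) {
      stop("the exponential family has no shape parameter `gamma`",
           call. = FALSE)
    }
  } else {
    if (is.null(gamma) || !is.numeric(gamma) || length(gamma) != 1L ||
        !is.finite(gamma)) {
      stop("family '", family, "' requires a single finite `gamma`",
           call. = FALSE)
    }
  }
  if (family == "log_normal" && gamma < 0) {
    if (allow_abs_gamma) {
      warning("log-normal shape gamma = ", gamma, " is negative; ",
              "using |gamma| = ", abs(gamma),
              " as the log-scale standard deviation", call. = FALSE)
      gamma <- abs(gamma)
    } else {
      stop("log-normal shape `gamma` must be positive", call. = FALSE)
    }
  }
  if (family == "generalized_gamma") {
    if (is.null(extra) || !is.numeric(extra) || length(extra) != 1L ||
        !is.finite(extra)) {
      stop("the generalized gamma requires `extra` (the Q parameter)",
           call. = FALSE)
    }
  } else if (!is.null(extra)) {
    stop("`extra` is only meaningful for the generalized gamma",
         call. = FALSE)
  }

  # family-specific admissibility
  ok <- switch(family,
    exponential       = lambda >= 0,
    weibull           = lambda >= 0 && gamma > 0,
    gompertz          = lambda >= 0,
    log_logistic      = lambda > 0 && gamma > 0,
    log_normal        = gamma > 0,
    generalized_gamma = gamma > 0
  )
  if (!ok) {
    stop("inadmissible parameters for family '", family, "': lambda = ",
         lambda, if (!is.null(gamma)) paste0(", gamma = ", gamma),
         call. = FALSE)
  }

  structure(
    list(family = family, lambda = lambda, gamma = gamma, extra = extra,
         time_unit = "years"),
    class = "survival_model"
  )
}

surv_families <- function() {
  c("exponential", "weibull", "gompertz", "log_logistic", "log_normal",
    "generalized_gamma")
}

#' @export
print.survival_model <- function(x, ...) {
  pars <- paste0("lambda = ", format(x$lambda))
  if (!is.null(x$gamma)) pars <- paste0(pars, ", gamma = ", format(x$gamma))
  if (!is.null(x$extra)) pars <- paste0(pars, ", Q = ", format(x$extra))
  cat("<survival_model> ", x$family, " (", pars, "), time in ",
      x$time_unit, "\n", sep = "")
  invisible(x)
}

#' Survival function S(t)
#'
#' @param model A [survival_model()].
#' @param t Vector of non-negative times (years).
#' @return Survival probabilities in `[0, 1]`, with `S(0) = 1`.
#' @export
survival_fn <- function(model, t) {
  stopifnot(inherits(model, "survival_model"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  la <- model$lambda
  ga <- model$gamma
  s <- switch(model$family,
    exponential = exp(-la * t),
    weibull     = exp(-la * t^ga),
    gompertz    = if (abs(ga) < 1e-12) exp(-la * t)
                  else exp(-(la / ga) * (exp(ga * t) - 1)),
    log_logistic = 1 / (1 + (t / la)^ga),
    log_normal   = stats::plnorm(t, meanlog = la, sdlog = ga,
                                 lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, mu = la, sigma = ga,
                                            Q = model$extra,
                                            lower.tail = FALSE)
  )
  # S(0) = 1 for every family (log-logistic with t = 0 gives 1 directly)
  s[t == 0] <- 1
  pmin(pmax(s, 0), 1)
}

#' Time-dependent cycle transition probability
#'
#' The probability of leaving the current state during the cycle ending at
#' time `t`, conditional on having remained until `t - u`:
#' `tp(t) = 1 - S(t) / S(t - u)`.  For the Weibull this equals the familiar
#' closed form `1 - exp(lambda (t-u)^gamma - lambda t^gamma)`.
#'
#' When `S(t - u) = 0` the cohort has already fully failed and the
#' transition probability is defined as 1.
#'
#' @param model A [survival_model()].
#' @param t Cycle-end time(s), years; must satisfy `t >= u`.
#' @param u Cycle length in years (default 1, the model's annual cycle).
#' @return Transition probabilities in `[0, 1]`.
#' @export
cycle_transition_prob <- function(model, t, u = 1) {
  stopifnot(inherits(model, "survival_model"))
  if (u <= 0) stop("cycle length `u` must be positive", call. = FALSE)
  if (any(t < u)) stop("`t` must be at least `u`", call. = FALSE)
  s_prev <- survival_fn(model, t - u)
  s_now <- survival_fn(model, t)
  tp <- ifelse(s_prev <= 0, 1, 1 - s_now / s_prev)
  pmin(pmax(tp, 0), 1)
}

#' Simulate event times from a parametric model
#'
#' Uncensored event times; censoring is layered on by [simulate_ipd()].
#'
#' @param model A [survival_model()].
#' @param n Number of draws.
#' @return Numeric vector of `n` positive event times (years).
#' @keywords internal
rsurv_times <- function(model, n) {
  stopifnot(inherits(model, "survival_model"))
  la <- model$lambda
  ga <- model$gamma
  switch(model$family,
    exponential = stats::rexp(n, rate = la),
    weibull     = flexsurv::rweibullPH(n, shape = ga, scale = la),
    gompertz    = flexsurv::rgompertz(n, shape = ga, rate = la),
    log_logistic = flexsurv::rllogis(n, shape = ga, scale = la),
    log_normal   = stats::rlnorm(n, meanlog = la, sdlog = ga),
    generalized_gamma = flexsurv::rgengamma(n, mu = la, sigma = ga,
                                            Q = model$extra)
  )
}
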