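#' Fit a parametric survival family to right-censored IPD
#'
#' Maximum-likelihood estimation is delegated to
#' [flexsurv::flexsurvreg()], whose optimizer is deterministic for a given
#' data set; the fitted natural parameters are mapped back onto the
#' package's (lambda, gamma) convention (see [survival_model()]).
#'
#' @param ipd Data frame with columns `time`, `event`; at least 2 events.
#' @param family A family name, see [survival_model()].
#' @return An object of class `"fit_result"`: list with `model` (a
#'   [survival_model()]), `loglik`, `aic`, `bic`, `n`, `k` (number of free
#'   parameters) and `converged`.
#' @examples
#' set.seed(1)
#' ipd <- data.frame(time = rexp(200, 0.3), event = 1)
#' fit_parametric(ipd, "exponential")$model$lambda  # ~ 0.3
#' @export
fit_parametric <- function(ipd, family) {
  ipd <- validate_ipd(ipd)
  family <- match.arg(family, surv_families())
  if (sum(ipd$event) < 2L) {
    stop("parametric fitting requires at least 2 events", call. = FALSE)
  }

  dist <- switch(family,
    exponential = "exp", weibull = "weibullPH", gompertz = "gompertz",
    log_logistic = "llogis", log_normal = "lnorm",
    generalized_gamma = "gengamma")

  fit <- flexsurv::flexsurvreg(
    survival::Surv(time, event) ~ 1, data = ipd, dist = dist)
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))

  model <- switch(family,
    exponential = survival_model("exponential", lambda = est[["rate"]]),
    weibull = survival_model("weibull", lambda = est[["scale"]],
                             gamma = est[["shape"]]),
    gompertz = survival_model("gompertz", lambda = est[["rate"]],
                              gamma = est[["shape"]]),
    log_logistic = survival_model("log_logistic", lambda = est[["scale"]],
                                  gamma = est[["shape"]]),
    log_normal = survival_model("log_normal", lambda = est[["meanlog"]],
                                gamma = est[["sdlog"]]),
    generalized_gamma = survival_model("generalized_gamma",
                                       lambda = est[["mu"]],
                                       gamma = est[["sigma"]],
                                       extra = est[["Q"]])
  )

  k <- fit$npars
  ll <- fit$loglik
  n <- nrow(ipd)
  converged <- is.null(fit$opt$convergence) || fit$opt$convergence == 0
  if (!converged) {
    warning("optimizer did not report convergence for family '", family,
            "'", call. = FALSE)
  }
  structure(
    list(model = model, loglik = ll, aic = 2 * k - 2 * ll,
         bic = k * log(n) - 2 * ll, n = n, k = k, converged = converged),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> family:", x$model$family,
      sprintf("| loglik %.3f AIC %.3f BIC %.3f | n = %d%s\n",
              x$loglik, x$aic, x$bic, x$n,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Select the best-fitting family by AIC or BIC
#'
#' Ties (within `1e-9`) are broken by fewer free parameters, then by
#' family name in the fixed order exponential, weibull, gompertz,
#' log_logistic, log_normal, generalized_gamma.
#'
#' @param fits A list of `"fit_result"` objects.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @return The selected `"fit_result"`.
#' @export
select_model <- function(fits, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (length(fits) < 1L) stop("`fits` is empty", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "fit_result")))
  score <- vapply(fits, function(f) {
    if (criterion == "AIC") f$aic else f$bic
  }, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  fam <- vapply(fits, function(f) match(f$model$family, surv_families()),
                numeric(1))
  ord <- order(round(score / 1e-9) * 1e-9, k, fam)
  fits[[ord[1L]]]
}

#' Fit all (or a subset of) families and select the best
#'
#' @inheritParams fit_parametric
#' @param families Character vector of families to try.
#' @param criterion Passed to [select_model()].
#' @return List with `fits` (all results) and `best` (the selection).
#' @export
fit_and_select <- function(ipd, families = surv_families(),
                           criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  fits <- lapply(families, function(f) {
    tryCatch(fit_parametric(ipd, f), error = function(e) {
      warning("family '", f, "' failed to fit: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("no family could be fitted", call. = FALSE)
  list(fits = fits, best = select_model(fits, criterion))
}
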