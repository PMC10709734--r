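#' Kaplan-Meier estimate from individual patient data
#'
#' Thin wrapper around [survival::survfit()] returning the product-limit
#' curve in the step-function form the digitization and reconstruction
#' stages work with.  The original records are kept on the object so that
#' exact numbers at risk at arbitrary boundary times can be recovered.
#'
#' @param ipd Data frame with columns `time` (> 0, years) and `event`
#'   (1 = event, 0 = right-censored).
#' @return An object of class `"km_curve"`: a list with `time`, `surv`,
#'   `n_risk`, `n_event`, `n_censor` at the distinct observed times, and
#'   the input `ipd`.
#' @examples
#' ipd <- data.frame(time = 1:4, event = 1)
#' km_estimate(ipd)$surv   # 0.75 0.50 0.25 0.00
#' @export
km_estimate <- function(ipd) {
  ipd <- validate_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event, n_censor = fit$n.censor, ipd = ipd),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", nrow(x$ipd), "records,", sum(x$n_event),
      "events,", length(x$time), "distinct times\n")
  invisible(x)
}

#' Evaluate a KM curve as a right-continuous step function
#'
#' @param km A `"km_curve"`.
#' @param t Times at which to evaluate.
#' @return Survival probabilities (1 before the first observed time).
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1L]
}

validate_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd))) {
    stop("`ipd` must be a data frame with columns `time` and `event`",
         call. = FALSE)
  }
  if (nrow(ipd) < 1L) stop("`ipd` has no records", call. = FALSE)
  if (any(!is.finite(ipd$time)) || any(ipd$time <= 0)) {
    stop("all follow-up times must be finite and > 0", call. = FALSE)
  }
  if (!all(ipd$event %in% c(0, 1))) {
    stop("`event` must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  ipd[c("time", "event")]
}
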