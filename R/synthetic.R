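#' Censoring specification for simulated trial data
#'
#' Right-censoring is the composition of (i) administrative censoring at
#' the end of follow-up, optionally staggered uniformly over
#' `[0, max_follow_up]` to emulate rolling trial entry, and (ii) random
#' dropout with an exponential hazard.
#'
#' @param max_follow_up End of follow-up in years (default 5, the typical
#'   follow-up of the adjuvant-therapy trials this model extrapolates);
#'   `Inf` disables administrative censoring.
#' @param uniform_entry If `TRUE`, administrative censoring times are
#'   uniform on `[0, max_follow_up]` instead of fixed at `max_follow_up`.
#' @param dropout_rate Exponential dropout hazard per year (0 = none).
#' @return An object of class `"censor_spec"`.
#' @export
censor_spec <- function(max_follow_up = 5, uniform_entry = FALSE,
                        dropout_rate = 0) {
  if (!is.numeric(max_follow_up) || max_follow_up <= 0) {
    stop("`max_follow_up` must be positive (possibly Inf)", call. = FALSE)
  }
  if (dropout_rate < 0) stop("`dropout_rate` must be >= 0", call. = FALSE)
  structure(list(max_follow_up = max_follow_up,
                 uniform_entry = isTRUE(uniform_entry),
                 dropout_rate = dropout_rate),
            class = "censor_spec")
}

#' Simulate right-censored individual patient data
#'
#' Event times are drawn from a parametric [survival_model()]; censoring
#' follows a [censor_spec()].  A record is an event if the latent event
#' time precedes the censoring time, otherwise it is censored at the
#' censoring time.
#'
#' @param model A [survival_model()].
#' @param n Cohort size (>= 1).
#' @param censoring A [censor_spec()]; default administrative censoring at
#'   5 years, no dropout.
#' @param seed Integer seed; identical seeds give identical data.
#' @return Data frame with columns `time`, `event`.
#' @examples
#' ipd <- simulate_ipd(survival_model("exponential", 0.2), n = 100, seed = 1)
#' @export
simulate_ipd <- function(model, n, censoring = censor_spec(), seed = NULL) {
  stopifnot(inherits(model, "survival_model"),
            inherits(censoring, "censor_spec"))
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  t_event <- rsurv_times(model, n)
  t_admin <- if (is.infinite(censoring$max_follow_up)) {
    rep(Inf, n)
  } else if (censoring$uniform_entry) {
    stats::runif(n, 0, censoring$max_follow_up)
  } else {
    rep(censoring$max_follow_up, n)
  }
  t_drop <- if (censoring$dropout_rate > 0) {
    stats::rexp(n, censoring$dropout_rate)
  } else {
    rep(Inf, n)
  }
  t_cens <- pmin(t_admin, t_drop)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  if (any(time <= 0)) {
    stop("censoring specification produced non-positive follow-up times",
         call. = FALSE)
  }
  data.frame(time = time, event = event)
}

#' Emulate graph digitization of a Kaplan-Meier curve
#'
#' Samples the KM step function on a regular time grid, optionally jitters
#' the coordinates on the probability scale (as reading points off a
#' printed figure would), re-imposes monotonicity by clipping each jittered
#' value to its predecessor, and computes the companion numbers-at-risk
#' table exactly from the underlying records.
#'
#' @param km A `"km_curve"` from [km_estimate()].
#' @param grid_step Grid spacing in years (> 0), default 0.25.
#' @param risk_interval Width of the risk-table intervals in years,
#'   default 1 (the Markov model's cycle length).
#' @param noise_sd Standard deviation of Gaussian jitter on the survival
#'   scale; 0 (default) reproduces the step function exactly.
#' @param seed Integer seed for the jitter.
#' @return An object of class `"digitized_curve"`: list with `coords`
#'   (data frame `time`, `surv`, first row (0, 1)), `risk` (data frame
#'   `start`, `end`, `n_risk`) and `total_events`.
#' @export
digitize_km <- function(km, grid_step = 0.25, risk_interval = 1,
                        noise_sd = 0, seed = NULL) {
  stopifnot(inherits(km, "km_curve"))
  if (grid_step <= 0) stop("`grid_step` must be positive", call. = FALSE)
  if (risk_interval <= 0) stop("`risk_interval` must be positive",
                               call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  t_max <- max(km$ipd$time)
  grid <- seq(0, t_max, by = grid_step)
  if (max(grid) < t_max) grid <- c(grid, t_max)
  surv <- km_survival_at(km, grid)
  if (noise_sd > 0) {
    jitter <- stats::rnorm(length(surv), 0, noise_sd)
    jitter[1L] <- 0                     # anchor (0, 1)
    surv <- pmin(pmax(surv + jitter, 0), 1)
    surv <- cummin(surv)                # clip to previous value
  }
  coords <- data.frame(time = grid, surv = surv)

  starts <- seq(0, t_max, by = risk_interval)
  ends <- pmin(starts + risk_interval, t_max)
  # number still under observation at the interval start (exact from IPD)
  n_risk <- vapply(starts, function(s) sum(km$ipd$time >= s), integer(1))
  keep <- starts < t_max
  risk <- data.frame(start = starts[keep], end = ends[keep],
                     n_risk = n_risk[keep])

  structure(
    list(coords = coords, risk = risk, total_events = sum(km$ipd$event)),
    class = "digitized_curve"
  )
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat("<digitized_curve>", nrow(x$coords), "coordinates,",
      nrow(x$risk), "risk intervals, n0 =", x$risk$n_risk[1L], "\n")
  invisible(x)
}

validate_digitized_curve <- function(curve) {
  if (!inherits(curve, "digitized_curve")) {
    stop("`curve` must be a 'digitized_curve'", call. = FALSE)
  }
  co <- curve$coords
  if (nrow(co) < 2L || co$time[1L] != 0 || co$surv[1L] != 1) {
    stop("curve coordinates must start at (0, 1)", call. = FALSE)
  }
  if (is.unsorted(co$time, strictly = TRUE)) {
    stop("curve times must be strictly increasing", call. = FALSE)
  }
  if (any(diff(co$surv) > 1e-9)) {
    stop("survival coordinates must be non-increasing", call. = FALSE)
  }
  if (any(co$surv < 0 | co$surv > 1)) {
    stop("survival coordinates must lie in [0, 1]", call. = FALSE)
  }
  rk <- curve$risk
  if (is.null(rk) || nrow(rk) < 1L) {
    stop("at least one risk interval is required", call. = FALSE)
  }
  if (any(diff(rk$n_risk) > 0)) {
    stop("numbers at risk must be non-increasing", call. = FALSE)
  }
  if (any(rk$n_risk < 0) || any(rk$n_risk != round(rk$n_risk))) {
    stop("numbers at risk must be non-negative integers", call. = FALSE)
  }
  invisible(curve)
}

#' Parametric (Gompertz-Makeham) life table
#'
#' Annual probability of death
#' `q(age) = 1 - exp(-(a + b exp(c age)))`: a constant background hazard
#' `a` plus an exponentially age-increasing (Gompertz) component.  The
#' defaults approximate mid-life female all-cause mortality of a few per
#' 1,000 per year at age 50, rising to a few per 100 by the late 70s; real
#' life tables can be supplied in the same `(age, qx)` format.
#'
#' @param makeham_a Age-independent hazard component (default 5e-4).
#' @param gompertz_b Gompertz level (default 3e-5).
#' @param gompertz_c Gompertz slope per year of age (default 0.09).
#' @param age_range Integer ages covered (default 0:110).
#' @return Data frame with columns `age`, `qx`.
#' @examples
#' lt <- synthetic_life_table()
#' lt$qx[lt$age == 50] * 1000   # ~3 per 1,000
#' @export
synthetic_life_table <- function(makeham_a = 5e-4, gompertz_b = 3e-5,
                                 gompertz_c = 0.09, age_range = 0:110) {
  if (makeham_a < 0 || gompertz_b < 0) {
    stop("hazard components must be non-negative", call. = FALSE)
  }
  age <- as.integer(age_range)
  hz <- makeham_a + gompertz_b * exp(gompertz_c * age)
  data.frame(age = age, qx = 1 - exp(-hz))
}

life_table_q <- function(life_table, age) {
  idx <- match(age, life_table$age)
  if (anyNA(idx)) {
    stop("life table does not cover age(s) ",
         paste(age[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  life_table$qx[idx]
}

#' Self-contained fixture bundle with known ground truth
#'
#' Produces everything an end-to-end run needs -- a full model
#' configuration plus simulated IPD and digitized-curve fixtures for one
#' pathway -- with the generating parameters recorded, so parameter
#' recovery through the reconstruction and fitting stages can be checked
#' against truth.
#'
#' @param seed Integer seed.
#' @param n Cohort size for the simulated trial data (default 2000).
#' @return List with `config` (see [base_case_config()]), `truth` (the
#'   generating survival model), `ipd`, `km` and `curve` (the digitized
#'   fixture).
#' @export
fixture_bundle <- function(seed = 1, n = 2000) {
  truth <- survival_model("exponential", lambda = 0.2)
  ipd <- simulate_ipd(truth, n = n, censoring = censor_spec(5), seed = seed)
  km <- km_estimate(ipd)
  curve <- digitize_km(km, grid_step = 0.25, risk_interval = 1)
  list(config = base_case_config(), truth = truth, ipd = ipd, km = km,
       curve = curve)
}

# ---- delimited-text interchange -------------------------------------------
# All files are UTF-8, comma-separated, decimal point, with a header row.

#' Read/write the package's delimited interchange formats
#'
#' IPD: columns `time,event`.  Digitized curve: `time,surv` plus a
#' companion risk-table file `start,end,n_risk`.  Life table: `age,qx`.
#'
#' @param ipd,curve,life_table Objects to write.
#' @param path,curve_path,risk_path File paths.
#' @name tilcea_io
#' @export
write_ipd <- function(ipd, path) {
  ipd <- validate_ipd(ipd)
  utils::write.csv(ipd, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tilcea_io
#' @export
read_ipd <- function(path) {
  validate_ipd(utils::read.csv(path))
}

#' @rdname tilcea_io
#' @export
write_curve <- function(curve, curve_path, risk_path) {
  validate_digitized_curve(curve)
  utils::write.csv(curve$coords, curve_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(curve$risk, risk_path, row.names = FALSE, quote = FALSE)
  invisible(curve_path)
}

#' @rdname tilcea_io
#' @param total_events Optional known total event count.
#' @export
read_curve <- function(curve_path, risk_path, total_events = NULL) {
  coords <- utils::read.csv(curve_path)
  risk <- utils::read.csv(risk_path)
  curve <- structure(list(coords = coords[c("time", "surv")],
                          risk = risk[c("start", "end", "n_risk")],
                          total_events = total_events),
                     class = "digitized_curve")
  validate_digitized_curve(curve)
}

#' @rdname tilcea_io
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(life_table[c("age", "qx")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname tilcea_io
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)[c("age", "qx")]
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop("life-table probabilities must lie in [0, 1]", call. = FALSE)
  }
  lt
}
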