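#' Sensitivity-analysis parameter specification
#'
#' Describes one tunable model input: where it lives in the configuration
#' (see [base_case_config()]), its base value and plausible range, and the
#' distribution used to sample it in probabilistic sensitivity analysis.
#' Published cost ranges come from procurement price databases; parameters
#' without a published range are varied by +/-20 percent.
#'
#' @param name Human-readable label.
#' @param path Character vector addressing the config field, e.g.
#'   `c("prices", "docetaxel")`.
#' @param base,low,high Base value and range (`low <= base <= high`).
#' @param distribution `"gamma"` (non-negative costs), `"beta"` (utilities
#'   on `[0, 1]`), `"normal"`, or `"none"` (one-way analysis only).
#' @return An object of class `"param_spec"`.
#' @export
param_spec <- function(name, path, base, low, high,
                       distribution = c("gamma", "beta", "normal",
                                        "none")) {
  distribution <- match.arg(distribution)
  if (!(low <= base && base <= high)) {
    stop("need low <= base <= high for '", name, "'", call. = FALSE)
  }
  if (distribution == "beta" && (low < 0 || high > 1)) {
    stop("beta is only admissible for [0, 1] quantities ('", name, "')",
         call. = FALSE)
  }
  if (distribution == "gamma" && low < 0) {
    stop("gamma is only admissible for non-negative quantities ('", name,
         "')", call. = FALSE)
  }
  structure(list(name = name, path = path, base = base, low = low,
                 high = high, distribution = distribution),
            class = "param_spec")
}

#' The default sensitivity-analysis parameter set
#'
#' Unit prices (gamma), adverse-event / administration / laboratory and
#' biomarker-test costs (gamma), the recurrence treatment cost (normal)
#' and the four state utilities (beta), with their published base values
#' and ranges; the discount rate (0 to 10 percent) enters the one-way
#' analysis only and carries no distribution.
#'
#' @return List of [param_spec()] objects.
#' @export
default_param_specs <- function() {
  list(
    param_spec("Docetaxel price", c("prices", "docetaxel"),
               139.28, 22.6, 980, "gamma"),
    param_spec("Epirubicin price", c("prices", "epirubicin"),
               79.15, 70.1, 170, "gamma"),
    param_spec("Cyclophosphamide price", c("prices", "cyclophosphamide"),
               23.98, 23.95, 24.51, "gamma"),
    param_spec("Palonosetron price", c("prices", "palonosetron"),
               53.8, 4.86, 220, "gamma"),
    param_spec("Aprepitant price", c("prices", "aprepitant"),
               450, 150, 574.33, "gamma"),
    param_spec("Dexamethasone price", c("prices", "dexamethasone"),
               0.58, 0.03, 39, "gamma"),
    param_spec("G-CSF price", c("prices", "gcsf"),
               58.98, 15.29, 73.93, "gamma"),
    param_spec("AE management, AC-T", c("ae_cost", "act"),
               21175, 16940, 25410, "gamma"),
    param_spec("AE management, TC", c("ae_cost", "tc"),
               9201, 7360.8, 11041.2, "gamma"),
    param_spec("Administration, AC-T", c("admin_cost", "act"),
               3200, 2560, 3840, "gamma"),
    param_spec("Administration, TC", c("admin_cost", "tc"),
               2400, 1920, 2880, "gamma"),
    param_spec("Testing, AC-T", c("lab_cost", "act"),
               1002, 801.6, 1202.4, "gamma"),
    param_spec("Testing, TC", c("lab_cost", "tc"),
               1005.04, 804.03, 1206.05, "gamma"),
    param_spec("TILs test cost", "tils_test_cost",
               3000, 2400, 3600, "gamma"),
    param_spec("Recurrence treatment cost", "recurrence_cost",
               70319.9, 20595.7, 120044.2, "normal"),
    param_spec("Utility PFS, chemotherapy",
               c("utilities", "chemo", "pfs"), 0.8, 0.73, 0.87, "beta"),
    param_spec("Utility PD, chemotherapy",
               c("utilities", "chemo", "pd"), 0.5, 0.4, 0.6, "beta"),
    param_spec("Utility PFS, spared chemotherapy",
               c("utilities", "spared", "pfs"), 0.94, 0.75, 1, "beta"),
    param_spec("Utility PD, spared chemotherapy",
               c("utilities", "spared", "pd"), 0.73, 0.66, 0.8, "beta"),
    param_spec("Discount rate", "discount_rate", 0.05, 0, 0.10, "none")
  )
}

set_config_value <- function(config, path, value) {
  config[[path]] <- value
  config
}

#' Draw one value for a parameter
#'
#' Gamma and beta use method-of-moments matching with mean equal to the
#' base value and standard deviation `(high - low) / (2 * 1.96)`, treating
#' the published range as a 95 percent interval; the normal uses the same
#' mean and SD.  Draws outside the admissible domain (negative costs) are
#' rejected and redrawn, up to 1,000 attempts.  When beta moments are
#' infeasible (SD too large for the mean) the sampler falls back to a
#' uniform draw over `[low, high]` with a warning.
#'
#' @param spec A [param_spec()].
#' @return One numeric draw (the base value for degenerate specs).
#' @export
sample_param <- function(spec) {
  stopifnot(inherits(spec, "param_spec"))
  if (spec$distribution == "none" || spec$high == spec$low) {
    return(spec$base)
  }
  s <- (spec$high - spec$low) / (2 * 1.96)
  m <- spec$base
  draw <- switch(spec$distribution,
    gamma = function() stats::rgamma(1, shape = (m / s)^2, rate = m / s^2),
    normal = function() stats::rnorm(1, mean = m, sd = s),
    beta = {
      nu <- m * (1 - m) / s^2 - 1
      if (m <= 0 || m >= 1 || nu <= 0) {
        warning("infeasible beta moments for '", spec$name,
                "'; falling back to a uniform draw over [low, high]",
                call. = FALSE)
        function() stats::runif(1, spec$low, spec$high)
      } else {
        function() stats::rbeta(1, shape1 = m * nu, shape2 = (1 - m) * nu)
      }
    }
  )
  lo_ok <- if (spec$distribution == "beta") 0 else 0   # costs must be >= 0
  for (i in seq_len(1000L)) {
    x <- draw()
    if (is.finite(x) && x >= lo_ok) return(x)
  }
  stop("failed to draw an admissible value for '", spec$name,
       "' after 1000 attempts", call. = FALSE)
}

#' One-way (tornado) sensitivity analysis
#'
#' Reruns the full deterministic model with each parameter at its low and
#' high bound in turn, all else held at base, and records the resulting
#' ICER.  Entries are returned sorted by descending swing
#' `|icer_high - icer_low|`, the order a tornado diagram plots them in.
#'
#' @param config A model configuration, see [base_case_config()].
#' @param specs List of [param_spec()]s (default [default_param_specs()]).
#' @return Data frame `parameter`, `low`, `high`, `icer_low`, `icer_high`,
#'   `swing`, plus attribute `base_icer`.
#' @export
one_way <- function(config, specs = default_param_specs()) {
  validate_config(config)
  models <- suppressWarnings(build_model_set(config))
  base_icer <- run_base_case(config, models = models)$cea$icer
  rows <- lapply(specs, function(sp) {
    icer_at <- function(v) {
      run_base_case(set_config_value(config, sp$path, v),
                    models = models)$cea$icer
    }
    lo <- icer_at(sp$low)
    hi <- icer_at(sp$high)
    data.frame(parameter = sp$name, low = sp$low, high = sp$high,
               icer_low = lo, icer_high = hi, swing = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: in each iteration every distributed parameter
#' is drawn independently from its [sample_param()] distribution, the full
#' model is rerun for both strategies, and the per-patient incremental
#' cost and effect are recorded.  Bitwise reproducible for a given seed,
#' iteration count and spec order.
#'
#' @inheritParams one_way
#' @param n_iterations Number of Monte Carlo draws (10,000 in the full
#'   analysis; smaller values are useful for interactive work).
#' @param seed Integer seed.
#' @return An object of class `"psa_result"`: list with `iterations`
#'   (data frame `iteration`, `delta_cost`, `delta_effect`, per patient),
#'   `n_iterations`, `seed` and `wtp`.
#' @export
run_psa <- function(config, specs = default_param_specs(),
                    n_iterations = 10000, seed = 1) {
  validate_config(config)
  if (n_iterations < 1) stop("`n_iterations` must be >= 1", call. = FALSE)
  specs <- Filter(function(sp) sp$distribution != "none", specs)
  models <- suppressWarnings(build_model_set(config))
  set.seed(seed)
  dc <- de <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    cfg <- config
    for (sp in specs) {
      cfg <- set_config_value(cfg, sp$path, sample_param(sp))
    }
    res <- run_base_case(cfg, models = models)
    dc[it] <- res$cea$delta_cost / res$strategy1$cohort_size
    de[it] <- res$cea$delta_effect / res$strategy1$cohort_size
  }
  structure(
    list(iterations = data.frame(iteration = seq_len(n_iterations),
                                 delta_cost = dc, delta_effect = de),
         n_iterations = n_iterations, seed = seed, wtp = config$wtp),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  p <- mean(x$wtp * x$iterations$delta_effect - x$iterations$delta_cost > 0)
  cat("<psa_result>", x$n_iterations, "iterations (seed", x$seed, ")\n")
  cat(sprintf("  mean dC %.0f yuan, mean dE %.3f QALYs per patient\n",
              mean(x$iterations$delta_cost), mean(x$iterations$delta_effect)))
  cat(sprintf("  P(cost-effective at WTP %.0f) = %.3f\n", x$wtp, p))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations with
#' positive net monetary benefit `wtp * dE - dC > 0`.
#'
#' @param psa A `"psa_result"`.
#' @param wtp_grid Vector of willingness-to-pay values (yuan/QALY).
#' @return Data frame `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 200000, by = 10000)) {
  stopifnot(inherits(psa, "psa_result"))
  if (nrow(psa$iterations) == 0L) {
    stop("PSA result has no iterations", call. = FALSE)
  }
  dc <- psa$iterations$delta_cost
  de <- psa$iterations$delta_effect
  prob <- vapply(wtp_grid, function(w) mean(w * de - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}
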