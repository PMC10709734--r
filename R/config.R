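#' Base-case model configuration
#'
#' A single nested list is the source of truth for an analysis: cohort and
#' horizon settings, the decision-tree split, unit prices and cost
#' components, utilities, the fitted survival-curve parameters for the
#' three Markov pathways, and the background-mortality life table.
#'
#' Defaults encode the base case of the TILs-guided de-escalation model:
#' 10,000 fifty-year-old women followed for 27 annual cycles (to age 77)
#' at a 5 percent discount rate; one third of the tested cohort (3,333 of
#' 10,000) has TILs >= 30 percent and is spared chemotherapy (pathway M1),
#' the rest (6,667) are treated (M2); without testing everyone is treated
#' (M3).  Survival parameters are the published best-fitting families per
#' curve; the M1 overall-survival log-normal carries a negative published
#' shape, which [survival_model()] maps to its absolute value with a
#' warning (see that help page).
#'
#' `regimen_assignment` selects which course is charged to which treated
#' arm.  `"cost_table"` (default) reproduces the published base-case cost
#' arithmetic: the tested-but-treated arm (M2) is charged the TC course
#' and the untested arm (M3) the AC-T course.  `"guideline_text"` follows
#' the treatment-guideline narrative instead (M2: AC-T, M3: TC).  The two
#' disagree in the source material; both are provided.
#'
#' @param regimen_assignment `"cost_table"` or `"guideline_text"`.
#' @return A named list; see Details.
#' @export
base_case_config <- function(regimen_assignment = c("cost_table",
                                                    "guideline_text")) {
  regimen_assignment <- match.arg(regimen_assignment)
  list(
    cohort_size = 10000,
    start_age = 50,
    horizon_years = 27,
    discount_rate = 0.05,
    wtp = 85700,
    tils_split = list(m1 = 3333, m2 = 6667),
    tils_test_cost = 3000,
    patient = list(height_cm = 158, weight_kg = 59),
    prices = default_unit_prices(),
    ae_cost = list(act = 21175, tc = 9201),
    admin_cost = list(act = 3200, tc = 2400),
    lab_cost = list(act = 1002, tc = 1005.04),
    recurrence_cost = 70319.9,
    recurrence_cost_mode = "once",
    followup_cost = c(1846, 2128, 1564),
    utilities = list(chemo = list(pfs = 0.8, pd = 0.5, death = 0),
                     spared = list(pfs = 0.94, pd = 0.73, death = 0)),
    regimen_assignment = regimen_assignment,
    survival = list(
      m1_dfs = list(family = "log_normal", lambda = 2.880, gamma = 0.061),
      m1_os  = list(family = "log_normal", lambda = 3.240, gamma = -0.120),
      m2_dfs = list(family = "weibull", lambda = 0.002, gamma = 1.040),
      m2_os  = list(family = "log_normal", lambda = 5.920, gamma = 0.360),
      m3_dfs = list(family = "exponential", lambda = 0.034),
      m3_os  = list(family = "weibull", lambda = 0.015, gamma = 1.160)
    ),
    life_table = synthetic_life_table()
  )
}

config_keys <- function() {
  c("cohort_size", "start_age", "horizon_years", "discount_rate", "wtp",
    "tils_split", "tils_test_cost", "patient", "prices", "ae_cost",
    "admin_cost", "lab_cost", "recurrence_cost", "recurrence_cost_mode",
    "followup_cost", "utilities", "regimen_assignment", "survival",
    "life_table")
}

#' Validate a model configuration
#'
#' All violations are collected and reported together.
#'
#' @param config A configuration list, see [base_case_config()].
#' @return The configuration, invisibly, if valid; otherwise an error
#'   listing every problem found.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  unknown <- setdiff(names(config), config_keys())
  if (length(unknown) > 0) {
    note("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(config_keys(), names(config))
  if (length(missing) > 0) {
    note("missing configuration keys: ", paste(missing, collapse = ", "))
  }

  num_ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!is.null(config$cohort_size) &&
      (!num_ok(config$cohort_size) || config$cohort_size < 1)) {
    note("cohort_size must be a single number >= 1")
  }
  if (!is.null(config$horizon_years) &&
      (!num_ok(config$horizon_years) || config$horizon_years < 1)) {
    note("horizon_years must be a single number >= 1")
  }
  if (!is.null(config$discount_rate) &&
      (!num_ok(config$discount_rate) || config$discount_rate < 0 ||
       config$discount_rate > 1)) {
    note("discount_rate must lie in [0, 1]")
  }
  if (!is.null(config$tils_split)) {
    spl <- unlist(config$tils_split)
    if (length(spl) != 2 || any(spl < 0)) {
      note("tils_split must give non-negative m1 and m2 counts")
    } else if (!is.null(config$cohort_size) &&
               num_ok(config$cohort_size) &&
               abs(sum(spl) - config$cohort_size) > 1e-9) {
      note("tils_split (m1 + m2) must sum to cohort_size")
    }
  }
  if (!is.null(config$utilities)) {
    u <- unlist(config$utilities)
    if (any(u < 0 | u > 1)) note("utilities must lie in [0, 1]")
    for (grp in c("chemo", "spared")) {
      d <- config$utilities[[grp]][["death"]]
      if (!is.null(d) && d != 0) note("death utility must be 0 (", grp, ")")
    }
  }
  if (!is.null(config$prices) && any(unlist(config$prices) < 0)) {
    note("unit prices must be non-negative")
  }
  if (!is.null(config$followup_cost) &&
      (length(config$followup_cost) != 3 ||
       any(config$followup_cost < 0))) {
    note("followup_cost must be 3 non-negative values")
  }
  if (is.null(config$life_table)) {
    note("a life table (data frame with columns age, qx) is required; ",
         "synthetic_life_table() supplies a parametric one")
  } else {
    lt <- config$life_table
    if (!all(c("age", "qx") %in% names(lt))) {
      note("life_table must have columns age and qx")
    } else {
      if (any(lt$qx < 0 | lt$qx > 1)) {
        note("life_table probabilities must lie in [0, 1]")
      }
      if (!is.null(config$start_age) && !is.null(config$horizon_years) &&
          num_ok(config$start_age) && num_ok(config$horizon_years)) {
        need <- config$start_age + seq_len(config$horizon_years) - 1
        if (!all(need %in% lt$age)) {
          note("life_table must cover ages ", min(need), " to ", max(need))
        }
      }
    }
  }
  if (!is.null(config$regimen_assignment) &&
      !config$regimen_assignment %in% c("cost_table", "guideline_text")) {
    note("regimen_assignment must be 'cost_table' or 'guideline_text'")
  }
  if (!is.null(config$survival)) {
    needed <- c("m1_dfs", "m1_os", "m2_dfs", "m2_os", "m3_dfs", "m3_os")
    miss <- setdiff(needed, names(config$survival))
    if (length(miss) > 0) {
      note("survival models missing: ", paste(miss, collapse = ", "))
    }
    for (nm in intersect(needed, names(config$survival))) {
      sm <- config$survival[[nm]]
      ok <- tryCatch({
        suppressWarnings(do.call(survival_model, sm)); TRUE
      }, error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) note("survival model '", nm, "': ", ok)
    }
  }

  if (length(problems) > 0) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(config)
}

#' Read / write a configuration as JSON
#'
#' @param path File path.
#' @param config A configuration list.
#' @return `load_config()` returns the validated configuration;
#'   `save_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  config <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  config$life_table <- as.data.frame(config$life_table)
  config$followup_cost <- as.numeric(unlist(config$followup_cost))
  validate_config(config)
  # surface the documented log-normal |gamma| warning at load time
  invisible(build_model_set(config))
  config
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

# survival_model objects for every configured curve
build_model_set <- function(config) {
  lapply(config$survival, function(sm) do.call(survival_model, sm))
}

# course costs (grand totals, yuan per patient) at current config prices
config_course_costs <- function(config) {
  bsa <- body_surface_area(config$patient$height_cm,
                           config$patient$weight_kg)
  prices <- config$prices
  tc <- course_cost(
    regimen_tc(prices, ae_cost = config$ae_cost$tc,
               admin_cost = config$admin_cost$tc,
               testing_cost = config$lab_cost$tc), bsa)
  act <- course_cost(
    regimen_act(prices, ae_cost = config$ae_cost$act,
                admin_cost = config$admin_cost$act,
                testing_cost = config$lab_cost$act), bsa)
  list(tc = tc, act = act)
}

#' Run the deterministic base case
#'
#' Builds the three pathway configurations from a configuration list,
#' runs both decision-tree strategies through the Markov engine and
#' returns strategy results together with the incremental analysis.
#'
#' @param config A configuration, see [base_case_config()].
#' @param models Internal: prebuilt survival models (reused across
#'   sensitivity-analysis reruns).
#' @return List with `strategy1` (TILs testing), `strategy2` (no
#'   testing), `cea` (a [compute_cea()] result at the configured WTP) and
#'   `course_costs`.
#' @examples
#' \donttest{
#' res <- run_base_case(base_case_config())
#' res$cea
#' }
#' @export
run_base_case <- function(config, models = NULL) {
  if (is.null(models)) {
    validate_config(config)
    models <- build_model_set(config)
  }
  costs <- config_course_costs(config)
  if (config$regimen_assignment == "cost_table") {
    m2_chemo <- costs$tc$grand_total
    m3_chemo <- costs$act$grand_total
  } else {
    m2_chemo <- costs$act$grand_total
    m3_chemo <- costs$tc$grand_total
  }
  u_chemo <- unlist(config$utilities$chemo)
  u_spared <- unlist(config$utilities$spared)
  common <- list(followup_cost = config$followup_cost,
                 recurrence_cost = config$recurrence_cost,
                 recurrence_cost_mode = config$recurrence_cost_mode)
  mk <- function(name, dfs, os, u) {
    do.call(pathway_config,
            c(list(name = name, dfs_model = dfs, os_model = os,
                   utilities = u), common))
  }
  m1 <- mk("M1", models$m1_dfs, models$m1_os, u_spared)
  m2 <- mk("M2", models$m2_dfs, models$m2_os, u_chemo)
  m3 <- mk("M3", models$m3_dfs, models$m3_os, u_chemo)

  settings <- list(start_age = config$start_age,
                   horizon_years = config$horizon_years,
                   discount_rate = config$discount_rate,
                   life_table = config$life_table)
  s1 <- do.call(run_strategy, c(list(
    name = "TILs testing",
    arms = list(list(pathway = m1, n = config$tils_split$m1,
                     chemo_cost = 0),
                list(pathway = m2, n = config$tils_split$m2,
                     chemo_cost = m2_chemo)),
    test_cost_per_patient = config$tils_test_cost), settings))
  s2 <- do.call(run_strategy, c(list(
    name = "No TILs testing",
    arms = list(list(pathway = m3, n = config$cohort_size,
                     chemo_cost = m3_chemo)),
    test_cost_per_patient = 0), settings))

  list(strategy1 = s1, strategy2 = s2,
       cea = compute_cea(s1, s2, wtp = config$wtp),
       course_costs = costs)
}

#' Assemble a base-case summary table
#'
#' One row per strategy component (pathway Markov costs/QALYs,
#' chemotherapy courses, biomarker testing) plus per-strategy totals, in
#' the layout of a published base-case results table.
#'
#' @param results Output of [run_base_case()].
#' @return Data frame `strategy`, `content`, `cost`, `qaly`,
#'   `total_cost_per_patient`, `total_qaly_per_patient`.
#' @export
render_report <- function(results) {
  one <- function(s) {
    comp <- s$components
    data.frame(strategy = s$name, content = comp$content,
               cost = comp$cost, qaly = comp$qaly,
               total_cost_per_patient = c(s$cost_per_patient,
                                          rep(NA, nrow(comp) - 1)),
               total_qaly_per_patient = c(s$qaly_per_patient,
                                          rep(NA, nrow(comp) - 1)))
  }
  rbind(one(results$strategy1), one(results$strategy2))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: optional pseudo-IPD reconstruction
#' and parametric refitting from digitized curves (replacing the
#' configured survival parameters), the deterministic base case, the
#' one-way sensitivity analysis and the PSA, writing delimited outputs
#' and a JSON run manifest with file checksums.
#'
#' @param config A configuration, see [base_case_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("base", "owsa", "psa")`.
#' @param curves Optional named list of `"digitized_curve"` objects (names
#'   among `m1_dfs`, ..., `m3_os`); each is reconstructed to pseudo-IPD,
#'   all families fitted, and the AIC-best model replaces the configured
#'   one.
#' @param psa_iterations,seed PSA settings.
#' @return The run manifest, invisibly: list with `seed`, `stages`,
#'   `selected_models` and `files` (path + md5 checksum).
#' @export
run_pipeline <- function(config, out_dir, stages = c("base", "owsa", "psa"),
                         curves = NULL, psa_iterations = 1000, seed = 1) {
  stages <- match.arg(stages, c("base", "owsa", "psa"), several.ok = TRUE)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  selected <- NULL
  if (!is.null(curves)) {
    selected <- lapply(curves, function(cv) {
      rec <- reconstruct_ipd(cv)
      fit_and_select(rec$ipd, criterion = "AIC")$best
    })
    for (nm in names(selected)) {
      m <- selected[[nm]]$model
      config$survival[[nm]] <- list(family = m$family, lambda = m$lambda,
                                    gamma = m$gamma, extra = m$extra)
    }
  }

  results <- NULL
  if ("base" %in% stages) {
    results <- run_base_case(config)
    emit(render_report(results), "base_case.csv")
    for (s in list(results$strategy1, results$strategy2)) {
      for (tr in s$traces) {
        emit(as.data.frame(tr),
             paste0("trace_", attr(tr, "pathway"), ".csv"))
      }
    }
  }
  if ("owsa" %in% stages) {
    emit(one_way(config), "tornado.csv")
  }
  if ("psa" %in% stages) {
    psa <- run_psa(config, n_iterations = psa_iterations, seed = seed)
    emit(psa$iterations, "psa_iterations.csv")
    emit(ceac(psa), "ceac.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tilcea")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, stages = stages,
    selected_models = if (is.null(selected)) NULL else {
      lapply(selected, function(f) {
        list(family = f$model$family, lambda = f$model$lambda,
             gamma = f$model$gamma, extra = f$model$extra,
             aic = f$aic, bic = f$bic)
      })
    },
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
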