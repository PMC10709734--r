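#' Markov pathway configuration
#'
#' One arm of the decision tree: a three-state (progression-free /
#' progressed / dead) annual-cycle cohort model driven by a disease-free
#' survival model (exit from PFS), an overall survival model (death after
#' progression), background mortality from a life table, state utilities
#' and state/transition costs.
#'
#' @param name Pathway label (`"M1"`, `"M2"`, `"M3"`, ...).
#' @param dfs_model,os_model [survival_model()] objects.
#' @param utilities Named numeric: `pfs`, `pd`, `death` utility weights
#'   per year; `death` must be 0, the others in `[0, 1]`.
#' @param upfront_cost Yuan per patient charged at cycle 0, undiscounted
#'   (chemotherapy course, biomarker test, ...).
#' @param followup_cost Numeric length 3: annual follow-up cost in PFS for
#'   year 1, year 2, and every later year.
#' @param recurrence_cost Yuan charged on entry to the progressed state
#'   (or annually while progressed when `recurrence_cost_mode =
#'   "annual"`).
#' @param recurrence_cost_mode `"once"` (default) or `"annual"`.
#' @return An object of class `"pathway_config"`.
#' @export
pathway_config <- function(name, dfs_model, os_model,
                           utilities = c(pfs = 0.8, pd = 0.5, death = 0),
                           upfront_cost = 0,
                           followup_cost = c(1846, 2128, 1564),
                           recurrence_cost = 70319.9,
                           recurrence_cost_mode = c("once", "annual")) {
  stopifnot(inherits(dfs_model, "survival_model"),
            inherits(os_model, "survival_model"))
  recurrence_cost_mode <- match.arg(recurrence_cost_mode)
  u <- utilities[c("pfs", "pd", "death")]
  if (anyNA(u) || any(u < 0) || any(u > 1)) {
    stop("utilities must be named pfs/pd/death, each in [0, 1]",
         call. = FALSE)
  }
  if (u[["death"]] != 0) stop("`death` utility must be 0", call. = FALSE)
  if (length(followup_cost) != 3L || any(followup_cost < 0)) {
    stop("`followup_cost` must be 3 non-negative values (year 1, year 2, ",
         "later)", call. = FALSE)
  }
  structure(list(name = name, dfs_model = dfs_model, os_model = os_model,
                 utilities = u, upfront_cost = upfront_cost,
                 followup_cost = followup_cost,
                 recurrence_cost = recurrence_cost,
                 recurrence_cost_mode = recurrence_cost_mode),
            class = "pathway_config")
}

#' Transition probabilities out of the progression-free state
#'
#' Death from PFS follows background age-specific mortality `q(age)`; the
#' remaining exit probability from the disease-free survival model's
#' cycle transition probability feeds progression,
#' `to_pd = max(0, tp_DFS(t) - q(age))`.
#'
#' @param pathway A [pathway_config()].
#' @param cycle_index Cycle number (>= 1); the cycle spans years
#'   `cycle_index - 1` to `cycle_index`.
#' @param age Attained age at the start of the cycle.
#' @param life_table Data frame `age`, `qx`.
#' @return Named numeric `(stay, to_pd, to_death)`, summing to 1.
#' @export
transition_row_pfs <- function(pathway, cycle_index, age, life_table) {
  stopifnot(inherits(pathway, "pathway_config"), cycle_index >= 1)
  q_bg <- life_table_q(life_table, age)
  tp <- cycle_transition_prob(pathway$dfs_model, t = cycle_index, u = 1)
  to_death <- min(q_bg, 1)
  to_pd <- max(0, min(tp - to_death, 1 - to_death))
  c(stay = 1 - to_pd - to_death, to_pd = to_pd, to_death = to_death)
}

#' Transition probabilities out of the progressed state
#'
#' Death after progression is the conditional one-cycle death probability
#' from the overall survival model, floored at background mortality:
#' `to_death = max(q(age), 1 - S_OS(t) / S_OS(t - 1))`.
#'
#' @inheritParams transition_row_pfs
#' @return Named numeric `(stay, to_death)`, summing to 1.
#' @export
transition_row_pd <- function(pathway, cycle_index, age, life_table) {
  stopifnot(inherits(pathway, "pathway_config"), cycle_index >= 1)
  q_bg <- life_table_q(life_table, age)
  tp_os <- cycle_transition_prob(pathway$os_model, t = cycle_index, u = 1)
  to_death <- min(max(q_bg, tp_os), 1)
  c(stay = 1 - to_death, to_death = to_death)
}

#' Run one Markov pathway
#'
#' The whole allocated cohort starts in the progression-free state at
#' cycle 0, when the per-patient upfront cost is charged undiscounted.
#' Each subsequent annual cycle applies the transition rows, then accrues
#' discounted QALYs on end-of-cycle occupancy, PFS follow-up costs per the
#' year schedule, and the recurrence cost on new entrants to the
#' progressed state, all with discount factor `(1 + r)^-k`.
#'
#' @param pathway A [pathway_config()].
#' @param allocated_n Patients entering this pathway (>= 0).
#' @param start_age Age at model entry (default 50).
#' @param horizon_years Number of annual cycles (default 27, to age 77).
#' @param discount_rate Annual discount rate (default 0.05).
#' @param life_table Data frame `age`, `qx`; must cover
#'   `start_age ... start_age + horizon_years - 1`.
#' @return An object of class `"cohort_trace"`: data frame with one row
#'   per cycle (`cycle`, `age`, `pfs`, `pd`, `death`, `new_pd`, `cost`,
#'   `disc_cost`, `qaly`, `disc_qaly`) and attributes `total_cost`,
#'   `total_qaly` (discounted, cohort-level).
#' @export
run_pathway <- function(pathway, allocated_n, start_age = 50,
                        horizon_years = 27, discount_rate = 0.05,
                        life_table = synthetic_life_table()) {
  stopifnot(inherits(pathway, "pathway_config"))
  if (allocated_n < 0) stop("`allocated_n` must be >= 0", call. = FALSE)
  if (horizon_years < 1) stop("`horizon_years` must be >= 1",
                              call. = FALSE)

  h <- as.integer(horizon_years)
  trace <- data.frame(
    cycle = 0:h, age = start_age + 0:h,
    pfs = NA_real_, pd = NA_real_, death = NA_real_, new_pd = NA_real_,
    cost = NA_real_, disc_cost = NA_real_,
    qaly = NA_real_, disc_qaly = NA_real_
  )
  trace[1L, c("pfs", "pd", "death", "new_pd")] <- c(allocated_n, 0, 0, 0)
  trace$cost[1L] <- trace$disc_cost[1L] <- pathway$upfront_cost * allocated_n
  trace$qaly[1L] <- trace$disc_qaly[1L] <- 0

  u <- pathway$utilities
  for (k in seq_len(h)) {
    age_k <- start_age + k - 1L
    row_pfs <- transition_row_pfs(pathway, k, age_k, life_table)
    row_pd <- transition_row_pd(pathway, k, age_k, life_table)
    pfs_prev <- trace$pfs[k]; pd_prev <- trace$pd[k]
    new_pd <- pfs_prev * row_pfs[["to_pd"]]
    pfs <- pfs_prev * row_pfs[["stay"]]
    pd <- pd_prev * row_pd[["stay"]] + new_pd
    death <- trace$death[k] + pfs_prev * row_pfs[["to_death"]] +
      pd_prev * row_pd[["to_death"]]
    df <- (1 + discount_rate)^(-k)
    fu <- pathway$followup_cost[[min(k, 3L)]]
    rec_cost <- if (pathway$recurrence_cost_mode == "once") {
      pathway$recurrence_cost * new_pd
    } else {
      pathway$recurrence_cost * pd
    }
    cost <- fu * pfs + rec_cost
    qaly <- u[["pfs"]] * pfs + u[["pd"]] * pd
    trace[k + 1L, c("pfs", "pd", "death", "new_pd")] <-
      c(pfs, pd, death, new_pd)
    trace$cost[k + 1L] <- cost
    trace$disc_cost[k + 1L] <- cost * df
    trace$qaly[k + 1L] <- qaly
    trace$disc_qaly[k + 1L] <- qaly * df
  }

  structure(trace, class = c("cohort_trace", "data.frame"),
            pathway = pathway$name,
            total_cost = sum(trace$disc_cost),
            total_qaly = sum(trace$disc_qaly))
}

#' Run a full strategy (decision-tree arm)
#'
#' Allocates the cohort over its Markov pathways, runs each, and adds the
#' strategy-level upfront components: chemotherapy course costs for the
#' treated arms and the biomarker test cost for every tested patient.
#'
#' @param name Strategy label.
#' @param arms List of arms, each a list with `pathway` (a
#'   [pathway_config()]), `n` (allocated patients) and `chemo_cost` (yuan
#'   per patient for the course given in that arm, 0 if spared).
#' @param test_cost_per_patient Biomarker test cost applied to the whole
#'   cohort (0 when no testing).
#' @inheritParams run_pathway
#' @return An object of class `"strategy_result"`: list with `name`,
#'   `cohort_size`, `components` (data frame `content`, `cost`, `qaly`),
#'   `total_cost`, `total_qaly` (cohort, discounted), `cost_per_patient`,
#'   `qaly_per_patient`, and `traces`.
#' @export
run_strategy <- function(name, arms, test_cost_per_patient = 0,
                         start_age = 50, horizon_years = 27,
                         discount_rate = 0.05,
                         life_table = synthetic_life_table()) {
  cohort <- sum(vapply(arms, function(a) a$n, numeric(1)))
  traces <- lapply(arms, function(a) {
    run_pathway(a$pathway, a$n, start_age = start_age,
                horizon_years = horizon_years,
                discount_rate = discount_rate, life_table = life_table)
  })
  comp <- do.call(rbind, lapply(seq_along(arms), function(i) {
    data.frame(content = paste0(arms[[i]]$pathway$name, " pathway"),
               cost = attr(traces[[i]], "total_cost"),
               qaly = attr(traces[[i]], "total_qaly"))
  }))
  chemo <- sum(vapply(arms, function(a) a$n * a$chemo_cost, numeric(1)))
  if (chemo > 0) {
    comp <- rbind(comp, data.frame(content = "Chemotherapy", cost = chemo,
                                   qaly = NA_real_))
  }
  if (test_cost_per_patient > 0) {
    comp <- rbind(comp, data.frame(content = "Biomarker test",
                                   cost = test_cost_per_patient * cohort,
                                   qaly = NA_real_))
  }
  total_cost <- sum(comp$cost)
  total_qaly <- sum(comp$qaly, na.rm = TRUE)
  structure(
    list(name = name, cohort_size = cohort, components = comp,
         total_cost = total_cost, total_qaly = total_qaly,
         cost_per_patient = total_cost / cohort,
         qaly_per_patient = total_qaly / cohort, traces = traces),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  cat("<strategy_result>", x$name, "| cohort", x$cohort_size, "\n")
  print(transform(x$components, cost = round(cost), qaly = round(qaly, 2)),
        row.names = FALSE)
  cat(sprintf("total cost %.0f yuan, total QALYs %.2f (%.0f / %.2f per patient)\n",
              x$total_cost, x$total_qaly, x$cost_per_patient,
              x$qaly_per_patient))
  invisible(x)
}
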