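test_that("PFS transition rows decompose background mortality and disease exit", {
  pw <- pathway_config("p",
                       dfs_model = survival_model("exponential", 0.034),
                       os_model = survival_model("weibull", 0.015, 1.16))
  # zero mortality, zero hazard: identity row
  inert <- inert_pathway()
  row0 <- transition_row_pfs(inert, 3, 52, flat_life_table(0))
  expect_equal(unname(row0), c(1, 0, 0))

  # exponential DFS with q = 0: constant exit probability
  for (k in c(1, 9, 20)) {
    row <- transition_row_pfs(pw, k, 49 + k, flat_life_table(0))
    expect_equal(row[["to_pd"]], 1 - exp(-0.034), tolerance = 1e-12)
  }

  # background mortality exceeding the DFS exit clips progression at 0
  slow <- pathway_config("s",
                         dfs_model = survival_model("exponential", 0.001),
                         os_model = survival_model("exponential", 0.001))
  row <- transition_row_pfs(slow, 1, 50, flat_life_table(0.5))
  expect_equal(row[["to_pd"]], 0)
  expect_equal(row[["to_death"]], 0.5)
  expect_equal(sum(row), 1, tolerance = 1e-12)
})

test_that("PD transition rows floor OS-based death at background mortality", {
  pw <- pathway_config("p",
                       dfs_model = survival_model("exponential", 0.034),
                       os_model = survival_model("weibull", 0.015, 1.16))
  # Weibull OS at t = 5 equals the direct survival ratio
  os <- survival_model("weibull", 0.015, 1.16)
  expected <- 1 - survival_fn(os, 5) / survival_fn(os, 4)
  row <- transition_row_pd(pw, 5, 54, flat_life_table(0))
  expect_equal(row[["to_death"]], expected, tolerance = 1e-12)

  # floor at q(age) regardless of the OS model
  lt <- flat_life_table(0.2)
  row2 <- transition_row_pd(inert_pathway(), 2, 51, lt)
  expect_equal(row2[["to_death"]], 0.2)
  expect_equal(sum(row2), 1, tolerance = 1e-12)
})

test_that("cohort mass is conserved and death is absorbing", {
  cfg <- base_case_config()
  models <- suppressWarnings(lapply(cfg$survival,
                                    function(s) do.call(survival_model, s)))
  pw <- pathway_config("M3", models$m3_dfs, models$m3_os)
  tr <- run_pathway(pw, allocated_n = 10000,
                    life_table = cfg$life_table)
  mass <- tr$pfs + tr$pd + tr$death
  expect_true(all(abs(mass - 10000) < 1e-9 * 10000))
  expect_true(all(diff(tr$death) >= 0))
  expect_true(all(tr$disc_qaly >= 0))
  expect_equal(nrow(tr), 28)  # cycle 0 plus 27 annual cycles
})

test_that("zero-hazard pathways match closed-form annuities", {
  # undiscounted: 27 years at utility 1
  tr <- run_pathway(inert_pathway(), 100, discount_rate = 0,
                    life_table = flat_life_table(0))
  expect_equal(sum(tr$disc_qaly), 27 * 100, tolerance = 1e-12)

  # discounted annuity at utility 0.94
  pw <- inert_pathway(utilities = c(pfs = 0.94, pd = 0.73, death = 0),
                      followup_cost = c(0, 0, 0))
  tr2 <- run_pathway(pw, 1, discount_rate = 0.05,
                     life_table = flat_life_table(0))
  annuity <- sum(1.05^-(1:27))
  expect_equal(sum(tr2$disc_qaly), 0.94 * annuity, tolerance = 1e-12)
  expect_equal(sum(tr2$disc_cost), 0, tolerance = 1e-12)
})

test_that("costs accrue per schedule: upfront, follow-up years, recurrence entry", {
  pw <- pathway_config("p",
                       dfs_model = survival_model("exponential", 0.5),
                       os_model = survival_model("exponential", 0.1),
                       upfront_cost = 1000,
                       followup_cost = c(100, 200, 50),
                       recurrence_cost = 5000)
  tr <- run_pathway(pw, 10, horizon_years = 3, discount_rate = 0,
                    life_table = flat_life_table(0))
  expect_equal(tr$cost[1], 10 * 1000)                # cycle-0 upfront
  p_stay <- exp(-0.5)
  new_pd1 <- 10 * (1 - p_stay)
  expect_equal(tr$new_pd[2], new_pd1, tolerance = 1e-12)
  expect_equal(tr$cost[2], 100 * 10 * p_stay + 5000 * new_pd1,
               tolerance = 1e-12)
  # year-2 follow-up tariff applies in cycle 2
  expect_equal(tr$cost[3],
               200 * 10 * p_stay^2 + 5000 * tr$new_pd[3],
               tolerance = 1e-12)
})

test_that("raising the discount rate weakly lowers post-upfront totals", {
  cfg <- base_case_config()
  models <- suppressWarnings(lapply(cfg$survival,
                                    function(s) do.call(survival_model, s)))
  pw <- pathway_config("M2", models$m2_dfs, models$m2_os)
  prev_c <- Inf; prev_q <- Inf
  for (r in c(0, 0.03, 0.05, 0.08)) {
    tr <- run_pathway(pw, 1000, discount_rate = r,
                      life_table = cfg$life_table)
    expect_lt(sum(tr$disc_cost), prev_c)
    expect_lt(sum(tr$disc_qaly), prev_q)
    prev_c <- sum(tr$disc_cost); prev_q <- sum(tr$disc_qaly)
  }
})

test_that("strategy assembly reproduces the decision-tree components", {
  cfg <- base_case_config()
  res <- suppressWarnings(run_base_case(cfg))
  s1 <- res$strategy1
  comp <- s1$components
  expect_equal(comp$cost[comp$content == "Biomarker test"], 3000 * 10000)
  expect_equal(comp$cost[comp$content == "Chemotherapy"],
               6667 * res$course_costs$tc$grand_total, tolerance = 1e-12)
  expect_equal(s1$total_cost, sum(comp$cost), tolerance = 1e-12)
  # degenerate allocation: all patients into one arm equals single pathway
  one_arm <- run_strategy(
    "all-M3",
    arms = list(list(pathway = pathway_config(
      "M3",
      suppressWarnings(do.call(survival_model, cfg$survival$m3_dfs)),
      suppressWarnings(do.call(survival_model, cfg$survival$m3_os))),
      n = 10000, chemo_cost = 0)),
    life_table = cfg$life_table)
  expect_equal(one_arm$total_qaly,
               attr(one_arm$traces[[1]], "total_qaly"), tolerance = 1e-12)
})
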