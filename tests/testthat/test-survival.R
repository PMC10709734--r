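test_that("survival functions satisfy boundary and shape constraints", {
  models <- list(
    survival_model("exponential", 0.034),
    survival_model("weibull", 0.015, 1.16),
    survival_model("gompertz", 0.05, 0.1),
    survival_model("log_logistic", 3, 2),
    survival_model("log_normal", 1.5, 0.5),
    survival_model("generalized_gamma", 1.2, 0.6, extra = 0.9)
  )
  t <- c(0, 0.5, 1, 2, 5, 10, 20, 50)
  for (m in models) {
    s <- survival_fn(m, t)
    expect_equal(s[1], 1, info = m$family)
    expect_true(all(s >= 0 & s <= 1), info = m$family)
    expect_true(all(diff(s) <= 1e-12), info = m$family)
  }
  # far-tail decay for the published M3 overall-survival Weibull
  expect_lt(survival_fn(survival_model("weibull", 0.015, 1.16), 200), 1e-3)
})

test_that("Weibull with shape 1 collapses to the exponential", {
  w <- survival_model("weibull", 0.034, 1)
  e <- survival_model("exponential", 0.034)
  for (t in c(1, 5, 10)) {
    expect_equal(survival_fn(w, t), survival_fn(e, t), tolerance = 1e-12)
  }
})

test_that("inadmissible parameters are rejected", {
  expect_error(survival_model("weibull", 0.1, -1), "inadmissible")
  expect_error(survival_model("log_logistic", -2, 1), "inadmissible")
  expect_error(survival_model("exponential", 0.1, gamma = 2), "no shape")
  expect_error(survival_model("generalized_gamma", 1, 0.5), "requires")
  expect_error(survival_model("log_normal", 1, -0.5,
                              allow_abs_gamma = FALSE), "positive")
})

test_that("negative log-normal shape is folded with a loud warning", {
  expect_warning(m <- survival_model("log_normal", 3.24, -0.12),
                 "negative")
  expect_equal(m$gamma, 0.12)
})

test_that("cycle transition probabilities: memorylessness, closed form, zero hazard", {
  e <- survival_model("exponential", 0.3)
  tp <- cycle_transition_prob(e, t = c(1, 7, 23), u = 1)
  expect_equal(tp, rep(1 - exp(-0.3), 3), tolerance = 1e-12)

  # Weibull closed form 1 - exp(la (t-u)^ga - la t^ga) vs ratio form,
  # including the published curve parameters
  for (pars in list(c(0.002, 1.040), c(0.015, 1.160), c(0.4, 0.7))) {
    w <- survival_model("weibull", pars[1], pars[2])
    for (t in c(1, 2, 5, 13, 27)) {
      closed <- 1 - exp(pars[1] * (t - 1)^pars[2] - pars[1] * t^pars[2])
      expect_equal(cycle_transition_prob(w, t, 1), closed,
                   tolerance = 1e-12)
    }
  }

  z <- survival_model("exponential", 0)
  expect_equal(cycle_transition_prob(z, t = 1:20, u = 1), rep(0, 20))
  expect_error(cycle_transition_prob(e, t = 0.5, u = 1), "at least")
})

test_that("transition probability stays in [0,1] across families and times", {
  models <- list(
    survival_model("weibull", 0.3, 2.5),
    survival_model("gompertz", 0.02, 0.3),
    survival_model("log_normal", 2.88, 0.061),  # near-degenerate drop
    survival_model("log_logistic", 2, 4)
  )
  for (m in models) {
    tp <- cycle_transition_prob(m, t = 1:40, u = 1)
    expect_true(all(tp >= 0 & tp <= 1), info = m$family)
  }
  # fully-failed cohort: S(t - u) = 0 defines tp = 1
  m <- survival_model("log_normal", 0.5, 0.05)
  expect_equal(cycle_transition_prob(m, t = 30, u = 1), 1)
})

test_that("Kaplan-Meier estimate matches hand computation and an independent oracle", {
  ipd <- data.frame(time = 1:4, event = 1)
  km <- km_estimate(ipd)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  all_censored <- data.frame(time = c(2, 3, 7), event = 0)
  expect_true(all(km_estimate(all_censored)$surv == 1))

  set.seed(42)
  mixed <- data.frame(time = round(rexp(50, 0.4), 2),
                      event = rbinom(50, 1, 0.7))
  mixed$time <- pmax(mixed$time, 0.01)
  km2 <- km_estimate(mixed)
  oracle <- product_limit_oracle(mixed)
  expect_equal(km_survival_at(km2, oracle$time), oracle$surv,
               tolerance = 1e-12)
})

test_that("all-event exponential fit reproduces the closed-form MLE", {
  set.seed(7)
  ipd <- data.frame(time = rexp(300, 0.5), event = 1)
  fit <- fit_parametric(ipd, "exponential")
  expect_equal(fit$model$lambda, sum(ipd$event) / sum(ipd$time),
               tolerance = 1e-5)
  expect_true(fit$converged)
})

test_that("AIC/BIC identities hold and degenerate inputs error", {
  set.seed(8)
  ipd <- simulate_ipd(survival_model("weibull", 0.1, 1.3), 400, seed = 8)
  for (fam in c("exponential", "weibull", "log_normal")) {
    f <- fit_parametric(ipd, fam)
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik, tolerance = 1e-12)
    expect_equal(f$bic, f$k * log(f$n) - 2 * f$loglik, tolerance = 1e-12)
  }
  expect_error(fit_parametric(data.frame(time = c(1, 2), event = c(1, 0)),
                              "exponential"), "at least 2 events")
})

test_that("model selection prefers the generating family and honours tie-breaks", {
  set.seed(9)
  ipd <- data.frame(time = rexp(5000, 0.2), event = 1)
  fits <- list(fit_parametric(ipd, "exponential"),
               fit_parametric(ipd, "weibull"))
  expect_equal(select_model(fits, "AIC")$model$family, "exponential")

  single <- fits[1]
  expect_identical(select_model(single), fits[[1]])

  # identical score and k: first by family order
  f1 <- fits[[1]]
  f2 <- f1
  f2$model$family <- "gompertz"
  expect_equal(select_model(list(f2, f1))$model$family, "exponential")
})
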