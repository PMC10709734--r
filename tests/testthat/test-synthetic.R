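test_that("simulated IPD is reproducible and matches analytic moments", {
  m <- survival_model("exponential", 0.034)
  a <- simulate_ipd(m, 500, seed = 11)
  b <- simulate_ipd(m, 500, seed = 11)
  expect_identical(a, b)

  # no censoring: sample mean ~ 1/lambda (Monte-Carlo error ~ sd/sqrt(n))
  big <- simulate_ipd(m, 10000, censoring = censor_spec(Inf), seed = 12)
  expect_true(all(big$event == 1))
  expect_equal(mean(big$time), 1 / 0.034,
               tolerance = 3 / sqrt(10000) * 1)  # ~3 SE relative
})

test_that("censoring composes administrative and dropout mechanisms", {
  m <- survival_model("exponential", 0.05)
  admin <- simulate_ipd(m, 2000, censoring = censor_spec(5), seed = 13)
  expect_true(all(admin$time <= 5))
  expect_true(all(admin$event[admin$time < 5 - 1e-12] == 1))

  dropped <- simulate_ipd(m, 2000,
                          censoring = censor_spec(5, dropout_rate = 0.5),
                          seed = 14)
  expect_gt(sum(dropped$event == 0 & dropped$time < 5), 0)
  expect_error(censor_spec(max_follow_up = 0), "positive")
})

test_that("zero-noise digitization reproduces the KM step function", {
  ipd <- simulate_ipd(survival_model("exponential", 0.3), 200, seed = 15)
  km <- km_estimate(ipd)
  cv <- digitize_km(km, grid_step = 0.25)
  expect_equal(cv$coords$surv, km_survival_at(km, cv$coords$time))
  expect_equal(cv$coords$time[1], 0)
  expect_equal(cv$coords$surv[1], 1)
  # risk counts exact from records, non-increasing
  expect_equal(cv$risk$n_risk[1], nrow(ipd))
  expect_true(all(diff(cv$risk$n_risk) <= 0))
})

test_that("jittered digitization stays a valid survival curve", {
  ipd <- simulate_ipd(survival_model("weibull", 0.1, 1.2), 300, seed = 16)
  km <- km_estimate(ipd)
  for (sd in c(0.005, 0.02, 0.1)) {
    cv <- digitize_km(km, noise_sd = sd, seed = 17)
    expect_true(all(diff(cv$coords$surv) <= 0))
    expect_true(all(cv$coords$surv >= 0 & cv$coords$surv <= 1))
    expect_equal(cv$coords$surv[1], 1)
  }
  expect_error(digitize_km(km, noise_sd = -0.1), ">= 0")
})

test_that("KM of simulated data converges to the generating survival curve", {
  m <- survival_model("weibull", 0.08, 1.3)
  ipd <- simulate_ipd(m, 20000, censoring = censor_spec(Inf), seed = 18)
  km <- km_estimate(ipd)
  grid <- c(1, 2, 3, 4, 5)
  dev <- abs(km_survival_at(km, grid) - survival_fn(m, grid))
  expect_lt(max(dev), 0.02)
})

test_that("synthetic life table has plausible, monotone, bounded rates", {
  lt <- synthetic_life_table()
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  q50 <- lt$qx[lt$age == 50]
  expect_gt(q50, 0.002)            # a few per 1,000 at midlife
  expect_lt(q50, 0.004)
  span <- lt$qx[lt$age %in% 50:77]
  expect_true(all(diff(span) > 0))  # Gompertz term strictly increasing

  zero <- synthetic_life_table(0, 0)
  expect_true(all(zero$qx == 0))
  # q = 1 - exp(-(a + b e^{c age})) evaluated directly
  expect_equal(q50, 1 - exp(-(5e-4 + 3e-5 * exp(0.09 * 50))),
               tolerance = 1e-12)
})

test_that("delimited interchange round-trips exactly", {
  tmp <- withr::local_tempdir()
  fx <- fixture_bundle(seed = 19, n = 120)

  p <- file.path(tmp, "ipd.csv")
  write_ipd(fx$ipd, p)
  expect_equal(read_ipd(p), fx$ipd, tolerance = 1e-12)

  cp <- file.path(tmp, "curve.csv"); rp <- file.path(tmp, "risk.csv")
  write_curve(fx$curve, cp, rp)
  back <- read_curve(cp, rp)
  expect_equal(back$coords, fx$curve$coords, tolerance = 1e-12)
  expect_equal(back$risk, fx$curve$risk)

  lp <- file.path(tmp, "life.csv")
  lt <- synthetic_life_table()
  write_life_table(lt, lp)
  expect_equal(read_life_table(lp), lt, tolerance = 1e-12)
})

test_that("fixture bundle is seed-deterministic and carries ground truth", {
  a <- fixture_bundle(seed = 20, n = 150)
  b <- fixture_bundle(seed = 20, n = 150)
  expect_identical(a$ipd, b$ipd)
  expect_identical(a$curve$coords, b$curve$coords)
  expect_s3_class(a$truth, "survival_model")
  expect_silent(validate_config(a$config))
})
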