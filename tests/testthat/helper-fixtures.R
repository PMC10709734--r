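# shared fixtures, built in code

# flat life table with constant annual death probability
flat_life_table <- function(q = 0, ages = 0:110) {
  data.frame(age = ages, qx = q)
}

# a pathway with no disease events: zero-hazard DFS and OS
inert_pathway <- function(utilities = c(pfs = 1, pd = 0.5, death = 0),
                          ...) {
  pathway_config("inert",
                 dfs_model = survival_model("exponential", 0),
                 os_model = survival_model("exponential", 0),
                 utilities = utilities, ...)
}

# independent textbook product-limit estimator (loop form), used as an
# oracle against km_estimate()
product_limit_oracle <- function(ipd) {
  times <- sort(unique(ipd$time[ipd$event == 1]))
  s <- 1
  surv <- numeric(length(times))
  for (i in seq_along(times)) {
    at_risk <- sum(ipd$time >= times[i])
    d <- sum(ipd$time == times[i] & ipd$event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}
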