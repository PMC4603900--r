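test_that("Kaplan-Meier estimate matches hand product-limit values", {
  # censored-only input: survival identically 1
  cv <- km_estimate(c(5, 8, 12), c(0, 0, 0))
  expect_length(cv$event_times, 0)
  expect_equal(survival_at(cv, c(0, 10, 100)), c(1, 1, 1))

  # all events at distinct times: S = 2/3, 1/3, 0
  cv <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(cv$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(cv$at_risk, c(3, 2, 1))
  # step function: right-continuous with carry-forward
  expect_equal(survival_at(cv, 0.5), 1)
  expect_equal(survival_at(cv, 2.5), 1 / 3)
  expect_equal(survival_at(cv, 10), 0)
  # Greenwood variance: S(t)^2 * sum d/(n(n-d))
  expect_equal(cv$variance[1], (2 / 3)^2 * (1 / 6))
  expect_equal(cv$variance[2], (1 / 3)^2 * (1 / 6 + 1 / 2))

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(11)
  for (rep in 1:5) {
    t <- sample(1:20, 30, replace = TRUE)  # heavy ties
    cv <- km_estimate(t, rep(1, 30))
    probe <- c(0, sort(unique(t)), 25)
    expect_equal(survival_at(cv, probe), vapply(probe, function(u)
      mean(t > u), numeric(1)))
    # and matches the hand product-limit oracle under random censoring
    ev <- rbinom(30, 1, 0.6)
    if (sum(ev) == 0) next
    cv2 <- km_estimate(t, ev)
    expect_equal(survival_at(cv2, 10), oracle_km_at(t, ev, 10))
  }
})

test_that("log-rank test matches symmetry, chi-square tail and hand oracle", {
  # identical multisets in both groups: statistic 0, p = 1
  t <- c(1, 3, 5, 7, 1, 3, 5, 7)
  e <- c(1, 0, 1, 1, 1, 0, 1, 1)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  # chi-square upper tail at the documented df
  expect_equal(stats::pchisq(3.84, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)

  # six-subject example against the hand O-E/V computation
  t6 <- c(2, 4, 6, 3, 5, 9)
  e6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- rep(c("x", "y"), each = 3)
  lr6 <- logrank_test(t6, e6, g6)
  expect_equal(lr6$statistic, oracle_logrank(t6, e6, g6),
               tolerance = 1e-10)
  expect_equal(lr6$p_value,
               stats::pchisq(lr6$statistic, 1, lower.tail = FALSE))

  # random small datasets against the oracle
  set.seed(21)
  for (rep in 1:10) {
    tt <- sample(1:12, 14, replace = TRUE)
    ee <- rbinom(14, 1, 0.7)
    gg <- rep(c("a", "b"), 7)
    if (sum(ee) == 0) next
    expect_equal(logrank_test(tt, ee, gg)$statistic,
                 oracle_logrank(tt, ee, gg), tolerance = 1e-8)
  }

  expect_error(logrank_test(t, e, factor(g, levels = c("a", "b", "c"))),
               "empty group")
})

test_that("log-rank equals the Cox score test on untied two-group data", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    t <- rexp(n) + cumsum(rep(1e-6, n))  # untied by construction
    e <- rbinom(n, 1, 0.8)
    z <- rep(0:1, n / 2)
    if (sum(e) < 2) next
    sc <- survival::coxph(survival::Surv(t, e) ~ z)$score
    expect_equal(logrank_test(t, e, z)$statistic, unname(sc),
                 tolerance = 1e-6)
  }
})

test_that("Cox fit maximizes the exact partial likelihood (grid oracle)", {
  # untied, 3 subjects
  t3 <- c(1, 2, 3); e3 <- c(1, 1, 1); x3 <- c(1, 0, 1)
  f3 <- cox_fit(t3, e3, cbind(x = x3))
  expect_equal(unname(f3$coefficients), oracle_grid_mle(t3, e3, x3),
               tolerance = 1e-4)

  # tied instances, up to 8 subjects, Efron and Breslow
  cases <- list(
    list(t = c(1, 1, 2, 2, 3, 4), e = c(1, 1, 1, 0, 1, 1),
         x = c(1, 0, 1, 1, 0, 0)),
    list(t = c(2, 2, 2, 5, 5, 7, 8, 8), e = c(1, 1, 0, 1, 1, 0, 1, 1),
         x = c(0, 1, 1, 0, 1, 0, 1, 0)))
  for (cs in cases) {
    for (ties in c("efron", "breslow")) {
      fit <- cox_fit(cs$t, cs$e, cbind(x = cs$x), ties = ties)
      b_oracle <- oracle_grid_mle(cs$t, cs$e, cs$x, ties = ties)
      expect_equal(unname(fit$coefficients), b_oracle, tolerance = 1e-4)
      # fitted likelihood no worse than the null
      expect_gte(oracle_partial_loglik(unname(fit$coefficients), cs$t,
                                       cs$e, cs$x, ties),
                 oracle_partial_loglik(0, cs$t, cs$e, cs$x, ties))
      expect_equal(fit$loglik,
                   oracle_partial_loglik(unname(fit$coefficients), cs$t,
                                         cs$e, cs$x, ties),
                   tolerance = 1e-6)
    }
  }
})

test_that("Cox fit reports Wald inference consistently and flags degeneracy", {
  sim <- sim_two_group(400, hr = 2, p_high = 0.5, rate = 0.05, cutoff = 30,
                       seed = 5)
  fit <- cox_fit(sim$time, sim$event, cbind(group = sim$z))
  expect_true(fit$converged)
  expect_equal(unname(fit$hr), exp(unname(fit$coefficients)))
  # CI brackets the HR and matches the log-scale construction
  expect_lt(fit$ci95[1, "lower"], fit$hr[1])
  expect_gt(fit$ci95[1, "upper"], fit$hr[1])
  expect_equal(unname(fit$ci95[1, "upper"] / fit$ci95[1, "lower"]),
               exp(2 * qnorm(0.975) * unname(fit$standard_errors[1])))
  expect_true(fit$wald_p[1] > 0 && fit$wald_p[1] <= 1)

  # constant covariate: non-identifiable
  expect_error(cox_fit(sim$time, sim$event, cbind(rep(1, 400))),
               "non-identifiable")
  expect_error(cox_fit(sim$time, rep(0, 400), cbind(sim$z)),
               "at least one event")
})

test_that("two-group recovery: estimated HR within 2 SE of the truth", {
  sim <- sim_two_group(2000, hr = 2, p_high = 0.5, rate = 0.02, cutoff = 40,
                       seed = 17)
  fit <- cox_fit(sim$time, sim$event, cbind(group = sim$z))
  expect_lt(abs(unname(fit$coefficients) - log(2)),
            2 * unname(fit$standard_errors))
})

test_that("Wald 95% CIs cover the null HR at the nominal rate", {
  covered <- logical(500)
  for (i in 1:500) {
    sim <- sim_two_group(150, hr = 1, p_high = 0.5, rate = 0.03,
                         cutoff = 40, seed = 1000 + i)
    fit <- cox_fit(sim$time, sim$event, cbind(group = sim$z))
    covered[i] <- fit$ci95[1, "lower"] <= 1 && fit$ci95[1, "upper"] >= 1
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})
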