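two_arm_sim <- function(n = 2000, rates = c(0.10, 0.065), seeds = c(21, 22),
                        admin = 15) {
  list(a = simulate_ipd(sim_spec("exponential", n = n, admin_censor = admin,
                                 rate = rates[1], seed = seeds[1],
                                 label = "ref_arm")),
       b = simulate_ipd(sim_spec("exponential", n = n, admin_censor = admin,
                                 rate = rates[2], seed = seeds[2],
                                 label = "trt_arm")))
}

test_that("identical arms give HR 1 and a null log-rank statistic", {
  ipd <- simulate_ipd(sim_spec("exponential", n = 120, admin_censor = 15,
                               rate = 0.08, seed = 31, label = "same"))
  hr <- cox_hr(ipd, ipd)
  expect_equal(hr$hr, 1, tolerance = 1e-8)
  expect_equal(hr$p, 1, tolerance = 1e-6)
  expect_equal(log_rank(ipd, ipd)$statistic, 0, tolerance = 1e-12)
})

test_that("Cox HR recovers the true rate ratio of exponential arms", {
  arms <- two_arm_sim()
  hr <- cox_hr(arms$b, arms$a)       # true HR = 0.065 / 0.10 = 0.65
  expect_gt(hr$hr, 0.60)
  expect_lt(hr$hr, 0.70)
  expect_true(hr$ci_low < hr$hr && hr$hr < hr$ci_high)
})

test_that("Cox comparison is label-antisymmetric", {
  arms <- two_arm_sim(n = 300)
  h1 <- cox_hr(arms$b, arms$a)
  h2 <- cox_hr(arms$a, arms$b)
  expect_equal(h1$log_hr, -h2$log_hr, tolerance = 1e-6)
  expect_equal(h1$se, h2$se, tolerance = 1e-6)
  expect_equal(h1$p, h2$p, tolerance = 1e-6)
  expect_equal(h1$ci_low, 1 / h2$ci_high, tolerance = 1e-6)
})

test_that("Cox beta matches maximizing the Efron partial likelihood directly", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    time <- round(rexp(n, 0.15), 1) + 0.1   # rounding induces ties
    event <- rbinom(n, 1, 0.75)
    x <- rbinom(n, 1, 0.5)
    if (sum(event[x == 1]) == 0 || sum(event[x == 0]) == 0) next
    ipd_a <- make_ipd(time[x == 1], event[x == 1], "a")
    ipd_b <- make_ipd(time[x == 0], event[x == 0], "b")
    fit <- tryCatch(cox_hr(ipd_a, ipd_b), error = function(e) NULL)
    if (is.null(fit)) next                  # monotone likelihood draw
    beta_oracle <- cox_oracle_beta(time, event, x)
    expect_equal(fit$log_hr, beta_oracle, tolerance = 1e-3)
  }
})

test_that("log-rank statistic equals brute-force O/E/V accumulation", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    time <- round(rexp(n, 0.2), 1) + 0.1
    event <- rbinom(n, 1, 0.8)
    x <- rbinom(n, 1, 0.5)
    if (sum(event) == 0 || length(unique(x)) < 2) next
    stat <- log_rank(make_ipd(time[x == 1], event[x == 1], "a"),
                     make_ipd(time[x == 0], event[x == 0], "b"))$statistic
    expect_equal(stat, logrank_oracle(time, event, x), tolerance = 1e-8)
  }
})

test_that("log-rank chi-square approximates the squared Cox Wald z", {
  arms <- two_arm_sim()
  hr <- cox_hr(arms$b, arms$a)
  lr <- log_rank(arms$b, arms$a)
  z2 <- (hr$log_hr / hr$se)^2
  expect_lt(abs(lr$statistic - z2) / z2, 0.10)
})

test_that("RMST matches the closed form for exponential survival", {
  ipd <- simulate_ipd(sim_spec("exponential", n = 5000, admin_censor = 16,
                               rate = 0.1, seed = 51, label = "exp"))
  r <- rmst(ipd, 15)
  expect_equal(r$rmst, (1 - exp(-1.5)) / 0.1, tolerance = 0.15 / 7.77)
  expect_true(r$ci_low < r$rmst && r$rmst < r$ci_high)
})

test_that("RMST handles the boundary cases of the milestone", {
  # no events before tau: area under S = 1
  ipd <- make_ipd(rep(20, 10), rep(0, 10))
  expect_equal(rmst(ipd, 15)$rmst, 15)
  expect_equal(rmst(ipd, 15)$se, 0)
  # tau -> 0 limit
  expect_equal(rmst(ipd, 1e-9)$rmst, 1e-9)
  # tau beyond follow-up fails loudly
  expect_error(rmst(ipd, 25), "exceeds")
})

test_that("RMST is nondecreasing in tau and bounded by it", {
  ipd <- simulate_ipd(sim_spec("weibull", n = 300, admin_censor = 18,
                               shape = 1.4, scale = 14, seed = 61,
                               label = "w"))
  taus <- c(2, 5, 9, 13, 17)
  vals <- vapply(taus, function(tau) rmst(ipd, tau)$rmst, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals <= taus + 1e-12))
})

test_that("RMST point estimate and SE agree with the survfit route", {
  ipd <- simulate_ipd(sim_spec("exponential", n = 400, admin_censor = 20,
                               rate = 0.08, seed = 71, label = "x"))
  r <- rmst(ipd, 15)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(ipd))
  tab <- summary(sf, rmean = 15)$table
  expect_equal(r$rmst, unname(tab["rmean"]), tolerance = 1e-8)
  expect_equal(r$se, unname(tab["se(rmean)"]), tolerance = 0.02)
})

test_that("RMST difference is null for identical arms and recovers a known gap", {
  ipd <- simulate_ipd(sim_spec("exponential", n = 200, admin_censor = 16,
                               rate = 0.09, seed = 81, label = "same"))
  d0 <- rmst_diff(ipd, ipd, 15)
  expect_equal(d0$diff, 0)
  expect_equal(d0$p, 1)

  arms <- two_arm_sim(seeds = c(91, 92), admin = 16)
  d <- rmst_diff(arms$b, arms$a, 15)
  true_gap <- (1 - exp(-15 * 0.065)) / 0.065 - (1 - exp(-15 * 0.10)) / 0.10
  expect_lt(abs(d$diff - true_gap), 3 * d$se)
  expect_true(d$ci_low < d$diff && d$diff < d$ci_high)
})
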