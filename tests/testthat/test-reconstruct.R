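halving_curve <- function()
  preprocess_curve(digitized_curve(c(0, 5, 10), c(1, 0.5, 0.25)))

test_that("event allocation follows the survival drops exactly", {
  alloc <- allocate_events_given_censoring(halving_curve(), 100, 0)
  expect_equal(alloc$total_events, 75)
  expect_equal(sum(alloc$event == 1 & alloc$time == 5), 50)
  expect_equal(sum(alloc$event == 1 & alloc$time == 10), 25)
  expect_equal(sum(alloc$event == 0 & alloc$time == 10), 25)
  expect_equal(length(alloc$time), 100)
})

test_that("a flat curve yields no events", {
  crv <- preprocess_curve(digitized_curve(c(0, 12), c(1, 1)))
  alloc <- allocate_events_given_censoring(crv, 10, 0)
  expect_equal(alloc$total_events, 0)
  expect_equal(alloc$time, rep(12, 10))
})

test_that("implied events are nonincreasing in the censoring count", {
  curves <- list(
    halving_curve(),
    preprocess_curve(digitized_curve(c(0, 2, 5, 9, 14),
                                     c(1, .9, .7, .55, .4))),
    preprocess_curve(digitized_curve(c(0, 1, 3, 4, 8, 12, 15),
                                     c(1, .95, .8, .78, .5, .45, .3))))
  for (crv in curves) for (N in c(10, 37, 80)) {
    implied <- vapply(0:N, function(c_in)
      allocate_events_given_censoring(crv, N, c_in)$total_events,
      numeric(1))
    expect_true(all(diff(implied) <= 0))
  }
})

test_that("reconstruction satisfies conservation on degenerate cohorts", {
  crv <- preprocess_curve(digitized_curve(c(0, 5, 10), c(1, 0.5, 0)))
  rec <- reconstruct_ipd(crv, curve_meta("z", 2, 2))
  expect_equal(sort(rec$time), c(5, 10))
  expect_equal(rec$event, c(1L, 1L))

  crv <- preprocess_curve(digitized_curve(c(0, 12), c(1, 1)))
  rec <- reconstruct_ipd(crv, curve_meta("flat", 10, 0))
  expect_equal(nrow(rec), 10)
  expect_equal(sum(rec$event), 0)
  expect_equal(rec$time, rep(12, 10))
})

test_that("round trip from exact KM coordinates reproduces the curve", {
  spec <- sim_spec("exponential", n = 100, admin_censor = 15, rate = 0.08,
                   seed = 1, label = "exp_arm")
  ipd <- simulate_ipd(spec)
  meta <- attr(ipd, "meta")
  crv <- ipd_to_curve(ipd)
  rec <- reconstruct_ipd(crv, meta)
  # conservation is exact
  expect_identical(nrow(rec), meta$n_patients)
  expect_identical(sum(rec$event), meta$n_events)
  # re-estimated KM matches input coordinates in sup norm
  km <- km_fit(rec)
  expect_lt(max(abs(km_survival_at(km, crv$times) - crv$surv)), 0.02)
})

test_that("conservation holds across simulated cohorts with mixed censoring", {
  for (seed in 1:5) {
    spec <- sim_spec("weibull", n = 150, admin_censor = 20,
                     random_censor_rate = 0.02, shape = 1.3, scale = 18,
                     seed = seed, label = "w")
    ipd <- simulate_ipd(spec)
    meta <- attr(ipd, "meta")
    rec <- reconstruct_ipd(ipd_to_curve(ipd), meta)
    expect_identical(nrow(rec), meta$n_patients)
    expect_identical(sum(rec$event), meta$n_events)
  }
})

test_that("reconstruction is deterministic", {
  crv <- preprocess_curve(
    digitized_curve(c(0, 2, 5, 9, 14), c(1, .9, .7, .55, .4)))
  meta <- curve_meta("det", 80, 40)
  r1 <- reconstruct_ipd(crv, meta)
  r2 <- reconstruct_ipd(crv, meta)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("curves inconsistent with the event count are rejected", {
  shallow <- preprocess_curve(digitized_curve(c(0, 10), c(1, 0.9)))
  expect_error(reconstruct_ipd(shallow, curve_meta("s", 20, 15)),
               "too shallow")
  # an early cliff forces events no censoring pattern can remove
  deep <- preprocess_curve(
    digitized_curve(c(0, 1, 100), c(1, 0.1, 0.05)))
  expect_error(reconstruct_ipd(deep, curve_meta("d", 100, 5)), "too deep")
  expect_error(
    reconstruct_ipd(shallow, curve_meta("m", 20, 1, max_follow_up = 5)),
    "shorter than the curve")
})

test_that("pooling concatenates records and adds the totals", {
  a <- simulate_ipd(sim_spec("exponential", n = 61, admin_censor = 15,
                             rate = 0.03, seed = 11, label = "cohort_a"))
  b <- simulate_ipd(sim_spec("exponential", n = 63, admin_censor = 15,
                             rate = 0.03, seed = 12, label = "cohort_b"))
  pooled <- pool_ipd(list(a, b), "pooled")
  m <- attr(pooled, "meta")
  expect_equal(m$n_patients, 124L)
  expect_equal(nrow(pooled), 124L)
  expect_equal(m$n_events, sum(a$event) + sum(b$event))
  expect_true(all(pooled$arm == "pooled"))

  single <- pool_ipd(list(a), "solo")
  expect_equal(single$time, a$time)
  expect_equal(single$event, a$event)

  expect_error(pool_ipd(list(), "none"), "nonempty")
})

test_that("IPD round-trips through its CSV representation", {
  ipd <- simulate_ipd(sim_spec("exponential", n = 30, admin_censor = 12,
                               rate = 0.07, seed = 3, label = "io"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ipd(ipd, path)
  back <- read_ipd(path)
  expect_equal(back$time, ipd$time)
  expect_equal(back$event, ipd$event)
  expect_equal(back$arm, ipd$arm)
})
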