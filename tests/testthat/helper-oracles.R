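# Brute-force oracles used to cross-check the survival machinery.
# Deliberately naive: explicit risk-set enumeration, no shortcuts shared
# with the implementation under test.

make_ipd <- function(time, event, arm = "x") {
  ipd_set(time, event, arm)
}

# Product-limit estimator by explicit risk-set enumeration.
km_oracle <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  var_sum <- 0
  se <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_i <- sum(time >= t)          # censored exactly at t still at risk
    d_i <- sum(time == t & event == 1)
    s <- s * (1 - d_i / n_i)
    if (n_i > d_i)
      var_sum <- var_sum + d_i / (n_i * (n_i - d_i))
    surv[i] <- s
    se[i] <- s * sqrt(var_sum)
  }
  data.frame(time = ev_times, surv = surv, se = se)
}

# Two-group log-rank statistic by direct O/E/V accumulation.
logrank_oracle <- function(time, event, x) {
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & x == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & x == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Efron-corrected two-group Cox partial log-likelihood, written from the
# definition; maximized with optimize() to get an independent beta-hat.
efron_loglik <- function(beta, time, event, x) {
  ev_times <- sort(unique(time[event == 1]))
  ll <- 0
  for (t in ev_times) {
    ties <- which(time == t & event == 1)
    d <- length(ties)
    risk <- exp(beta * x[time >= t])
    sum_risk <- sum(risk)
    sum_ties <- sum(exp(beta * x[ties]))
    ll <- ll + beta * sum(x[ties])
    for (l in seq_len(d) - 1L)
      ll <- ll - log(sum_risk - (l / d) * sum_ties)
  }
  ll
}

cox_oracle_beta <- function(time, event, x, interval = c(-5, 5)) {
  stats::optimize(efron_loglik, interval, time = time, event = event,
                  x = x, maximum = TRUE)$maximum
}

# Analytic gradient of the censored Weibull log-likelihood in (k, lambda).
weibull_grad <- function(ipd, k, lam) {
  t <- ipd$time
  d <- ipd$event
  z <- (t / lam)^k
  dk <- sum(d * (1 / k - log(lam) + log(t)) - z * log(t / lam))
  dl <- sum(-d * k / lam + z * k / lam)
  c(dk, dl)
}
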