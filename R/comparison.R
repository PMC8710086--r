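#' Two-group Cox proportional-hazards comparison
#'
#' Estimates the hazard ratio of arm `ipd_a` versus reference arm `ipd_b`
#' from the two-group Cox partial likelihood with the Efron correction for
#' tied event times (ties are frequent in reconstructed data, where many
#' subjects share a drop time). The fit is delegated to
#' [survival::coxph()]; the confidence interval is Wald on the log scale,
#' exp(beta +/- 1.96 se), and the p-value a two-sided Wald z-test.
#'
#' @param ipd_a treatment arm (`ipd`).
#' @param ipd_b reference arm (`ipd`).
#' @return An object of class `hr_result`: list with `hr`, `log_hr`, `se`,
#'   `ci_low`, `ci_high`, `p`, `arms`.
#' @export
cox_hr <- function(ipd_a, ipd_b) {
  stopifnot(inherits(ipd_a, "ipd"), inherits(ipd_b, "ipd"))
  if (nrow(ipd_a) == 0L || nrow(ipd_b) == 0L)
    stop("both arms must be nonempty")
  if (sum(ipd_a$event) + sum(ipd_b$event) == 0L)
    stop("no events in either arm; hazard ratio undefined")
  dat <- data.frame(time = c(ipd_a$time, ipd_b$time),
                    event = c(ipd_a$event, ipd_b$event),
                    x = rep(c(1L, 0L), c(nrow(ipd_a), nrow(ipd_b))))
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, data = dat,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop("Cox partial likelihood did not converge (monotone ",
             "likelihood, e.g. complete separation of event times): ",
             conditionMessage(w), call. = FALSE)
      suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ x, data = dat,
                        ties = "efron"))
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  if (!is.finite(beta) || !is.finite(se))
    stop("Cox partial likelihood did not converge")
  z <- beta / se
  structure(list(log_hr = beta, se = se, hr = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(z)),
                 arms = c(attr(ipd_a, "meta")$label,
                          attr(ipd_b, "meta")$label)),
            class = "hr_result")
}

#' @export
print.hr_result <- function(x, digits = 2, ...) {
  cat(sprintf("HR (%s vs %s) = %.*f (95%% CI %.*f to %.*f, p = %.3g)\n",
              x$arms[1L], x$arms[2L], digits, x$hr, digits, x$ci_low,
              digits + 1, x$ci_high, x$p))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Chi-square statistic (1 df) from observed minus expected events under
#' the hypergeometric null, accumulated over the distinct event times;
#' computed via [survival::survdiff()].
#'
#' @inheritParams cox_hr
#' @return List with `statistic` and `p`.
#' @export
log_rank <- function(ipd_a, ipd_b) {
  stopifnot(inherits(ipd_a, "ipd"), inherits(ipd_b, "ipd"))
  if (sum(ipd_a$event) + sum(ipd_b$event) == 0L)
    stop("no events in either arm")
  dat <- data.frame(time = c(ipd_a$time, ipd_b$time),
                    event = c(ipd_a$event, ipd_b$event),
                    x = rep(c(1L, 0L), c(nrow(ipd_a), nrow(ipd_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ x, data = dat)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Restricted mean survival time
#'
#' RMST at milestone `tau` is the area under the KM curve up to `tau`,
#' computed exactly as the sum of rectangle areas of the step function. Its
#' variance is
#' sum over event times t_i <= tau of
#' (integral of S from t_i to tau)^2 * d_i / (n_i (n_i - d_i)),
#' the standard large-sample form; the 95% CI is rmst +/- 1.96 se.
#'
#' @param ipd an `ipd` object.
#' @param tau milestone in months; must not exceed the arm's largest
#'   observed time (the KM estimate is undefined beyond it). See
#'   [run_study()] for the auto-truncation option used in pipelines.
#' @return An object of class `rmst_result`: list with `tau`, `rmst`, `se`,
#'   `ci_low`, `ci_high`, `arm`.
#' @export
rmst <- function(ipd, tau) {
  stopifnot(inherits(ipd, "ipd"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("`tau` must be a single positive number of months")
  if (nrow(ipd) == 0L)
    stop("empty arm")
  if (tau > max(ipd$time) + 1e-9)
    stop("milestone tau = ", tau, " exceeds the arm's follow-up (",
         max(ipd$time), " months)")
  km <- km_fit(ipd)
  tt <- km$event_times
  keep <- tt <= tau
  tt <- tt[keep]
  ss <- km$surv[keep]
  # rectangle areas of the right-continuous step function on [0, tau]
  grid <- c(0, tt, tau)
  sval <- c(1, ss)
  est <- sum(sval * diff(grid))
  # area of S from t_i to tau, per event time (reverse cumulative)
  if (length(tt) > 0L) {
    widths <- diff(grid)[-1L]            # widths to the right of each t_i
    tail_area <- rev(cumsum(rev(ss * widths)))
    n_i <- km$n_at_risk[keep]
    d_i <- km$n_events[keep]
    denom <- n_i * (n_i - d_i)
    term <- ifelse(denom > 0, d_i / denom, 0)
    v <- sum(tail_area^2 * term)
  } else {
    v <- 0
  }
  se <- sqrt(v)
  structure(list(tau = tau, rmst = est, se = se,
                 ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                 arm = attr(ipd, "meta")$label),
            class = "rmst_result")
}

#' @export
print.rmst_result <- function(x, ...) {
  cat(sprintf("RMST(%s) at %.4g months = %.2f (95%% CI %.2f to %.2f)\n",
              x$arm, x$tau, x$rmst, x$ci_low, x$ci_high))
  invisible(x)
}

#' Difference in restricted mean survival time between two arms
#'
#' diff = RMST_a - RMST_b at the common milestone, with standard error
#' sqrt(se_a^2 + se_b^2) (independent cohorts), Wald CI and two-sided
#' z-test.
#'
#' @inheritParams cox_hr
#' @param tau milestone in months, valid for both arms.
#' @return An object of class `rmst_diff`: list with `tau`, `diff`, `se`,
#'   `ci_low`, `ci_high`, `p`, `arms`.
#' @export
rmst_diff <- function(ipd_a, ipd_b, tau) {
  ra <- rmst(ipd_a, tau)
  rb <- rmst(ipd_b, tau)
  d <- ra$rmst - rb$rmst
  se <- sqrt(ra$se^2 + rb$se^2)
  z <- if (se > 0) d / se else 0
  structure(list(tau = tau, diff = d, se = se,
                 ci_low = d - 1.96 * se, ci_high = d + 1.96 * se,
                 p = 2 * stats::pnorm(-abs(z)),
                 arms = c(ra$arm, rb$arm)),
            class = "rmst_diff")
}

#' @export
print.rmst_diff <- function(x, ...) {
  cat(sprintf(
    "RMST difference (%s - %s) at %.4g months = %.2f (95%% CI %.2f to %.2f, p = %.3g)\n",
    x$arms[1L], x$arms[2L], x$tau, x$diff, x$ci_low, x$ci_high, x$p))
  invisible(x)
}
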