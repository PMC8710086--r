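#' Kaplan-Meier product-limit estimate from IPD
#'
#' Fits the product-limit estimator S(t) = prod over event times t_i <= t of
#' (1 - d_i/n_i), with Greenwood's variance
#' Var S(t) = S(t)^2 * sum d_i / (n_i (n_i - d_i)). Ties of events and
#' censorings at the same time follow the usual convention: events precede
#' censorings, i.e. censored subjects at t are still at risk for events at
#' t. The computation is delegated to [survival::survfit()].
#'
#' @param ipd an `ipd` object with at least one record.
#' @return An object of class `km_est`: list with `event_times`, `surv`,
#'   `se` (Greenwood standard errors), `n_at_risk`, `n_events` at each
#'   distinct event time, plus `max_time` (largest observed time) and the
#'   underlying `survfit` object in `$fit`. The step function is
#'   right-continuous and constant between event times, with S(0) = 1.
#' @export
km_fit <- function(ipd) {
  stopifnot(inherits(ipd, "ipd"))
  if (nrow(ipd) == 0L)
    stop("empty IPD")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(ipd), conf.type = "none")
  ev <- sf$n.event > 0
  se <- sf$std.err * sf$surv           # survfit std.err is on the log scale
  se[!is.finite(se)] <- 0
  structure(list(event_times = sf$time[ev],
                 surv = sf$surv[ev],
                 se = se[ev],
                 n_at_risk = sf$n.risk[ev],
                 n_events = sf$n.event[ev],
                 max_time = max(ipd$time),
                 n = nrow(ipd),
                 arm = attr(ipd, "meta")$label,
                 fit = sf),
            class = "km_est")
}

#' @export
print.km_est <- function(x, ...) {
  med <- median_survival(x)
  cat("KM estimate for '", x$arm, "': n = ", x$n, ", ",
      sum(x$n_events), " events, median OS = ",
      if (is.na(med)) "not reached" else paste(format(round(med, 2)), "months"),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.km_est <- function(object, ...) {
  data.frame(time = object$event_times, surv = object$surv, se = object$se,
             n_at_risk = object$n_at_risk, n_events = object$n_events)
}

#' Evaluate a KM step function at arbitrary times
#'
#' Right-continuous evaluation: S(t) is the survival after the last event
#' time not exceeding t, and 1 before the first event.
#'
#' @param km a `km_est` object.
#' @param times numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  stopifnot(inherits(km, "km_est"))
  if (length(km$event_times) == 0L)
    return(rep(1, length(times)))
  idx <- findInterval(times, km$event_times)
  c(1, km$surv)[idx + 1L]
}

#' Median survival from a KM estimate
#'
#' The smallest event time at which the survival estimate falls to 0.5 or
#' below; `NA` (printed as "not reached") when the curve never does.
#'
#' @param km a `km_est` object.
#' @return Median in months, or `NA_real_` when not reached.
#' @export
median_survival <- function(km) {
  stopifnot(inherits(km, "km_est"))
  hit <- which(km$surv <= 0.5 + 1e-12)
  if (length(hit) == 0L) NA_real_ else km$event_times[min(hit)]
}

#' Export a KM estimate as a delimited table
#'
#' Columns `time, survival, se, n_at_risk` — the coordinates needed to
#' re-plot the curve.
#'
#' @param km a `km_est` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_km <- function(km, path) {
  stopifnot(inherits(km, "km_est"))
  utils::write.csv(data.frame(time = c(0, km$event_times),
                              survival = c(1, km$surv),
                              se = c(0, km$se),
                              n_at_risk = c(km$n, km$n_at_risk)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Overlay KM curves from several arms
#'
#' Base-graphics step plot of one or more fitted curves, in the style of a
#' published multi-arm survival figure.
#'
#' @param kms list of `km_est` objects.
#' @param col line colours, recycled.
#' @param xlab,ylab axis labels.
#' @param ... further arguments to [plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_km <- function(kms, col = seq_along(kms), xlab = "Months",
                    ylab = "Overall survival", ...) {
  if (inherits(kms, "km_est"))
    kms <- list(kms)
  col <- rep_len(col, length(kms))
  xmax <- max(vapply(kms, function(k) k$max_time, numeric(1)))
  plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(kms)) {
    k <- kms[[i]]
    graphics::lines(c(0, k$event_times, k$max_time),
                    c(1, k$surv, k$surv[length(k$surv)]),
                    type = "s", col = col[i])
  }
  labs <- vapply(kms, function(k) k$arm, character(1))
  graphics::legend("bottomleft", legend = labs, col = col, lty = 1, bty = "n")
  invisible(NULL)
}
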