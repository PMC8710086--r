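#' Individual patient data container
#'
#' An `ipd` object is a data frame of subject records with columns `time`
#' (months), `event` (1 = death observed, 0 = censored) and `arm` (cohort
#' label), carrying its [curve_meta()] as an attribute. Reconstructed and
#' simulated cohorts share this representation.
#'
#' @param time numeric vector of observed times.
#' @param event integer vector of 0/1 event flags.
#' @param arm arm label (recycled).
#' @param meta optional [curve_meta()]; when omitted it is derived from the
#'   records themselves.
#' @return An object of classes `ipd` and `data.frame`.
#' @export
ipd_set <- function(time, event, arm, meta = NULL) {
  if (length(time) != length(event))
    stop("`time` and `event` must have the same length")
  if (!all(event %in% c(0, 1)))
    stop("`event` must be coded 0/1")
  if (any(time < 0))
    stop("negative observation times")
  df <- data.frame(time = as.numeric(time), event = as.integer(event),
                   arm = rep_len(as.character(arm), length(time)),
                   stringsAsFactors = FALSE)
  if (is.null(meta))
    meta <- curve_meta(df$arm[1L], nrow(df), sum(df$event),
                       max_follow_up = max(df$time))
  if (nrow(df) != meta$n_patients)
    stop("record count (", nrow(df), ") does not match metadata N (",
         meta$n_patients, ")")
  if (sum(df$event) != meta$n_events)
    stop("event count (", sum(df$event), ") does not match metadata D (",
         meta$n_events, ")")
  structure(df, meta = meta, class = c("ipd", "data.frame"))
}

#' @export
print.ipd <- function(x, ...) {
  m <- attr(x, "meta")
  cat("IPD set '", m$label, "': ", m$n_events, " events / ", m$n_patients,
      " patients, max observed time ", format(round(max(x$time), 2)),
      " months\n", sep = "")
  invisible(x)
}

#' Write / read subject records as delimited text
#'
#' Columns `time,event,arm`, events coded 1/0.
#'
#' @param ipd an `ipd` object.
#' @param path output (input) file path.
#' @return `write_ipd` returns `path` invisibly; `read_ipd` returns an
#'   `ipd` object.
#' @export
write_ipd <- function(ipd, path) {
  stopifnot(inherits(ipd, "ipd"))
  utils::write.csv(as.data.frame(ipd)[, c("time", "event", "arm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  if (!file.exists(path))
    stop("IPD file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "event", "arm")
  if (!all(need %in% names(tab)))
    stop("IPD file must have columns time,event,arm")
  ipd_set(tab$time, tab$event, tab$arm)
}

## Cumulative rounding: round the running sum, difference consecutive
## rounded values. Keeps sum(round_cum(x)) == round(sum(x)) so fractional
## counts never drift over many small intervals.
round_cumulative <- function(x) {
  r <- round(cumsum(x))
  as.integer(diff(c(0, r)))
}

#' Distribute events and censorings over curve intervals for a fixed
#' censoring count
#'
#' The low-level interval walk of the reconstruction. Given a preprocessed
#' curve with J intervals, the `c_in` in-follow-up censorings are spread
#' across intervals proportionally to interval width (cumulative rounding,
#' placed at interval midpoints). Walking intervals j = 1..J with `n`
#' subjects still at risk, the survival ratio r_j = S_j / S_{j-1} (clipped
#' to \[0, 1\]) implies raw events (n - c_j) (1 - r_j); raw counts become
#' integers by cumulative rounding so no drift accumulates. Events sit at
#' the drop time t_j. Subjects still at risk after the last interval are
#' censored at `max_follow_up`.
#'
#' @param curve preprocessed [digitized_curve()].
#' @param n_patients cohort size N.
#' @param c_in number of censorings to place inside follow-up, 0..N.
#' @param max_follow_up administrative end of follow-up (months); defaults
#'   to the last curve time.
#' @param label arm label for the candidate records.
#' @return A list with `time`, `event` vectors of the candidate records and
#'   `total_events`, the implied number of events.
#' @keywords internal
#' @export
allocate_events_given_censoring <- function(curve, n_patients, c_in,
                                            max_follow_up = NULL,
                                            label = "arm") {
  stopifnot(inherits(curve, "digitized_curve"))
  J <- length(curve$times) - 1L
  if (J < 1L)
    stop("curve with a single point cannot be reconstructed")
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L)
    stop("N must be positive")
  c_in <- as.integer(c_in)
  if (c_in < 0L || c_in > n_patients)
    stop("censoring count out of range")
  if (is.null(max_follow_up))
    max_follow_up <- curve$times[length(curve$times)]
  if (max_follow_up < curve$times[length(curve$times)])
    stop("`max_follow_up` shorter than the curve")

  widths <- diff(curve$times)
  midpoints <- (curve$times[-1L] + curve$times[-(J + 1L)]) / 2
  cens_raw <- c_in * widths / sum(widths)

  # raw interval walk in real arithmetic: the implied event total is then a
  # rounding of a quantity strictly decreasing in c_in, which keeps the
  # bisection in reconstruct_ipd() well founded
  r <- curve$surv[-1L] / curve$surv[-(J + 1L)]
  r[is.nan(r)] <- 1                 # 0/0 after the curve hits zero
  r <- pmin(pmax(r, 0), 1)
  m <- n_patients
  ev_raw <- numeric(J)
  for (j in seq_len(J)) {
    m_avail <- max(m - cens_raw[j], 0)
    ev_raw[j] <- m_avail * (1 - r[j])
    m <- m_avail - ev_raw[j]
  }
  d_int <- round_cumulative(ev_raw)
  c_int <- round_cumulative(cens_raw)

  n <- n_patients
  times <- numeric(0)
  events <- integer(0)
  for (j in seq_len(J)) {
    c_j <- min(c_int[j], n)
    if (c_j > 0L) {
      times <- c(times, rep(midpoints[j], c_j))
      events <- c(events, rep(0L, c_j))
    }
    d_j <- min(d_int[j], n - c_j)
    if (d_j > 0L) {
      times <- c(times, rep(curve$times[j + 1L], d_j))
      events <- c(events, rep(1L, d_j))
    }
    n <- n - c_j - d_j
  }
  if (n > 0L) {
    times <- c(times, rep(max_follow_up, n))
    events <- c(events, rep(0L, n))
  }
  list(time = times, event = events, total_events = sum(events))
}

#' Reconstruct individual patient data from a digitized KM curve
#'
#' Inverts a Kaplan-Meier curve into subject-level records consistent with
#' the curve shape, the total number of enrolled patients N and the total
#' number of events D — the three pieces of information available from a
#' published survival figure. Because no number-at-risk table is assumed,
#' in-follow-up censoring is taken uniform in time; its total count
#' `c_in` in \[0, N - D\] is the one free quantity, solved by integer
#' bisection (the implied event count is nonincreasing in `c_in`) so the
#' implied events match D. A residual mismatch of at most the number of
#' curve intervals — cumulative rounding can be off by a few at drop times —
#' is absorbed by swapping event/censoring status at the latest times; a
#' larger mismatch means the curve depth is inconsistent with D and is an
#' error.
#'
#' @param curve a preprocessed [digitized_curve()] (see
#'   [preprocess_curve()]).
#' @param meta a [curve_meta()] with the cohort's N, D and follow-up.
#' @return An `ipd` object with exactly `meta$n_patients` records and
#'   `meta$n_events` events.
#' @examples
#' crv <- preprocess_curve(digitized_curve(c(0, 5, 10), c(1, .5, .25)))
#' rec <- reconstruct_ipd(crv, curve_meta("ex", 100, 75))
#' table(rec$event)
#' @export
reconstruct_ipd <- function(curve, meta) {
  stopifnot(inherits(curve, "digitized_curve"), inherits(meta, "curve_meta"))
  last_t <- curve$times[length(curve$times)]
  mfu <- if (is.null(meta$max_follow_up)) last_t else meta$max_follow_up
  if (mfu < last_t)
    stop("metadata follow-up (", mfu, ") is shorter than the curve (",
         last_t, " months)")
  N <- meta$n_patients
  D <- meta$n_events
  J <- length(curve$times) - 1L

  implied <- function(c_in)
    allocate_events_given_censoring(curve, N, c_in, mfu, meta$label)$total_events

  lo <- 0L
  hi <- N - D
  f_lo <- implied(lo)          # maximal implied events
  if (f_lo < D - J)
    stop("curve for '", meta$label, "' is too shallow: at most ", f_lo,
         " events are consistent with it, but D = ", D)
  f_hi <- if (hi > lo) implied(hi) else f_lo
  if (f_hi > D + J)
    stop("curve for '", meta$label, "' is too deep: at least ", f_hi,
         " events are implied even with maximal censoring, but D = ", D)

  # integer bisection on the nonincreasing map c_in -> implied events
  best <- lo
  best_gap <- abs(f_lo - D)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    f_mid <- implied(mid)
    if (abs(f_mid - D) < best_gap) {
      best <- mid
      best_gap <- abs(f_mid - D)
    }
    if (f_mid >= D) lo <- mid else hi <- mid
  }
  for (c_try in unique(c(lo, hi))) {
    f <- implied(c_try)
    if (abs(f - D) < best_gap) {
      best <- c_try
      best_gap <- abs(f - D)
    }
  }

  cand <- allocate_events_given_censoring(curve, N, best, mfu, meta$label)
  time <- cand$time
  event <- cand$event
  delta <- D - sum(event)
  if (abs(delta) > J)
    stop("reconstruction residual (", delta, " events) exceeds the number ",
         "of curve intervals; curve and D are inconsistent for '",
         meta$label, "'")
  if (delta > 0L) {
    # too few events: promote the latest censored records
    cens <- which(event == 0L)
    cens <- cens[order(time[cens], decreasing = TRUE)]
    event[cens[seq_len(delta)]] <- 1L
  } else if (delta < 0L) {
    # too many events: demote the latest event records to censorings
    evs <- which(event == 1L)
    evs <- evs[order(time[evs], decreasing = TRUE)]
    event[evs[seq_len(-delta)]] <- 0L
  }
  ipd_set(time, event, meta$label, meta = curve_meta(meta$label, N, D, mfu))
}

#' Pool several IPD sets into one arm
#'
#' Concatenates reconstructed cohorts under a single treatment label, e.g.
#' two dose cohorts of one trial pooled into a single arm for comparison.
#' Patient and event totals add.
#'
#' @param parts nonempty list of `ipd` objects.
#' @param label label for the pooled arm.
#' @return An `ipd` object with `sum(N)` records and `sum(D)` events.
#' @export
pool_ipd <- function(parts, label) {
  if (!is.list(parts) || length(parts) == 0L)
    stop("`parts` must be a nonempty list of IPD sets")
  lapply(parts, function(p) stopifnot(inherits(p, "ipd")))
  time <- unlist(lapply(parts, function(p) p$time))
  event <- unlist(lapply(parts, function(p) p$event))
  metas <- lapply(parts, attr, "meta")
  mfu <- max(vapply(metas, function(m)
    if (is.null(m$max_follow_up)) -Inf else m$max_follow_up, numeric(1)),
    max(time))
  meta <- curve_meta(label, sum(vapply(metas, `[[`, 0L, "n_patients")),
                     sum(vapply(metas, `[[`, 0L, "n_events")), mfu)
  ipd_set(time, event, label, meta = meta)
}
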