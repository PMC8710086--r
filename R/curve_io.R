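#' Construct a digitized Kaplan-Meier curve object
#'
#' A `digitized_curve` holds the (time, survival) coordinate pairs read off a
#' published Kaplan-Meier figure for one treatment cohort. Times are in
#' months, survival on the probability scale. Raw coordinates straight from a
#' plot digitizer are accepted; [preprocess_curve()] normalizes them into a
#' valid right-continuous survival trace.
#'
#' @param times numeric vector of time coordinates (months).
#' @param surv numeric vector of survival coordinates, same length.
#' @return An object of class `digitized_curve`: a list with elements
#'   `times` and `surv`.
#' @seealso [read_curve_table()], [preprocess_curve()]
#' @export
digitized_curve <- function(times, surv) {
  if (length(times) != length(surv))
    stop("`times` and `surv` must have the same length")
  if (length(times) < 1L)
    stop("no coordinate rows")
  if (!is.numeric(times) || !is.numeric(surv))
    stop("curve coordinates must be numeric")
  if (anyNA(times) || anyNA(surv))
    stop("curve coordinates contain missing values")
  structure(list(times = as.numeric(times), surv = as.numeric(surv)),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat("Digitized KM curve:", length(x$times), "points, time range [",
      format(min(x$times)), ",", format(max(x$times)), "] months, survival",
      format(round(max(x$surv), 3)), "down to", format(round(min(x$surv), 3)),
      "\n")
  invisible(x)
}

#' Cohort metadata for a digitized curve
#'
#' The two numbers that, together with the curve coordinates, determine the
#' reconstruction: the number of patients ever at risk (`n_patients`) and the
#' total number of deaths observed over follow-up (`n_events`). These are the
#' published n/N figures of the source trial (e.g. 19/61 for one
#' pembrolizumab cohort).
#'
#' @param label cohort label.
#' @param n_patients total enrolled patients N (> 0).
#' @param n_events total observed events D, with 0 <= D <= N.
#' @param max_follow_up end of follow-up in months; defaults to the last
#'   curve time when the metadata is paired with a curve. Must not be shorter
#'   than the curve it is paired with.
#' @return An object of class `curve_meta`.
#' @export
curve_meta <- function(label, n_patients, n_events, max_follow_up = NULL) {
  n_patients <- as.integer(n_patients)
  n_events <- as.integer(n_events)
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 1L)
    stop("`n_patients` must be a single positive count")
  if (length(n_events) != 1L || is.na(n_events) || n_events < 0L)
    stop("`n_events` must be a single nonnegative count")
  if (n_events > n_patients)
    stop("`n_events` (", n_events, ") exceeds `n_patients` (", n_patients, ")")
  if (!is.null(max_follow_up)) {
    max_follow_up <- as.numeric(max_follow_up)
    if (length(max_follow_up) != 1L || is.na(max_follow_up) || max_follow_up <= 0)
      stop("`max_follow_up` must be a single positive number of months")
  }
  structure(list(label = as.character(label), n_patients = n_patients,
                 n_events = n_events, max_follow_up = max_follow_up),
            class = "curve_meta")
}

#' @export
print.curve_meta <- function(x, ...) {
  cat("Cohort ", x$label, ": ", x$n_events, "/", x$n_patients, " events",
      if (!is.null(x$max_follow_up))
        paste0(", follow-up ", format(x$max_follow_up), " months"),
      "\n", sep = "")
  invisible(x)
}

#' Read digitized curve coordinates from a delimited file
#'
#' Expects a header with a time column and a survival column (named `time`
#' and `survival`; common synonyms `t`/`months` and `surv`/`s`/`os` are also
#' recognized). Values are returned in file order, unmodified — run
#' [preprocess_curve()] before reconstruction.
#'
#' @param path path to a CSV (or other single-character-delimited) file.
#' @param sep field separator, default comma.
#' @return A [digitized_curve()].
#' @export
read_curve_table <- function(path, sep = ",") {
  if (!file.exists(path))
    stop("curve file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           strip.white = TRUE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    stop("no coordinate rows in ", path)
  nms <- tolower(names(tab))
  t_col <- which(nms %in% c("time", "t", "months", "month"))
  s_col <- which(nms %in% c("survival", "surv", "s", "os", "probability"))
  if (length(t_col) != 1L)
    stop("missing time column (or ambiguous) in ", path)
  if (length(s_col) != 1L)
    stop("missing survival column (or ambiguous) in ", path)
  times <- tab[[t_col]]
  surv <- tab[[s_col]]
  if (!is.numeric(times) || !is.numeric(surv))
    stop("non-numeric entries in curve table ", path)
  digitized_curve(times, surv)
}

#' Normalize raw digitized coordinates into a valid survival trace
#'
#' Plot digitization produces coordinates that are almost, but not exactly, a
#' survival function: axes may be in percent, pairs may be slightly out of
#' order, and noise can make the trace rise locally. This step enforces the
#' invariants the reconstruction relies on:
#'
#' * percent-scale detection: if the largest survival value exceeds 1.5 the
#'   axis is taken to be in percent and divided by 100 (`percent` overrides);
#' * values clipped to \[0, 1\] and sorted by time;
#' * a (0, 1) anchor prepended when absent;
#' * duplicate times collapsed keeping the minimum survival (a drop is real,
#'   a rise at the same instant is digitization noise);
#' * monotone nonincreasing survival enforced by running-minimum replacement
#'   (isotonic clip), preserving the time grid.
#'
#' The operation is idempotent.
#'
#' @param raw a [digitized_curve()].
#' @param percent force percent (`TRUE`) or probability (`FALSE`)
#'   interpretation of the survival axis; `NULL` (default) auto-detects.
#' @return A preprocessed [digitized_curve()] with `times[1] == 0`,
#'   `surv[1] == 1`, strictly increasing times and nonincreasing survival.
#' @export
preprocess_curve <- function(raw, percent = NULL) {
  stopifnot(inherits(raw, "digitized_curve"))
  times <- raw$times
  surv <- raw$surv
  if (any(times < 0))
    stop("negative time coordinates")
  if (is.null(percent))
    percent <- max(surv) > 1.5
  if (percent)
    surv <- surv / 100
  surv <- pmin(pmax(surv, 0), 1)
  if (all(surv == 0))
    stop("all-zero survival curve")
  ord <- order(times, surv)
  times <- times[ord]
  surv <- surv[ord]
  # collapse duplicate times keeping the lower survival
  keep <- !duplicated(times)
  times <- times[keep]
  surv <- surv[keep]
  # anchor at (0, 1)
  if (times[1L] > 0) {
    times <- c(0, times)
    surv <- c(1, surv)
  } else {
    surv[1L] <- 1
  }
  surv <- cummin(surv)
  if (length(times) == 1L)
    stop("curve reduces to a single point at time zero")
  if (all(surv == 0))
    stop("all-zero survival curve")
  digitized_curve(times, surv)
}
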