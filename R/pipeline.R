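#' Read a study configuration
#'
#' A study config is a YAML file describing the cohorts to reconstruct and
#' how to compare them:
#'
#' ```yaml
#' cohorts:
#'   - label: keynote164_a
#'     curve: cohort_a.csv
#'     n_patients: 61
#'     n_events: 19
#'     pool_into: pembrolizumab     # optional group label
#'   - ...
#' reference_arm: pembrolizumab
#' tau: 15            # RMST milestone, months
#' bootstrap_b: 1000  # MLS bootstrap draws
#' seed: 1
#' auto_truncate_tau: false
#' ```
#'
#' Relative curve paths are resolved against the config file's directory.
#'
#' @param path path to the YAML file.
#' @return A validated config list of class `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$dir <- dirname(normalizePath(path))
  validate_study_config(cfg)
}

#' @rdname read_study_config
#' @param cfg a config list built in code (same fields as the YAML).
#' @export
validate_study_config <- function(cfg) {
  if (is.null(cfg$cohorts) || length(cfg$cohorts) == 0L)
    stop("config must list at least one cohort")
  for (co in cfg$cohorts) {
    for (f in c("label", "curve", "n_patients", "n_events"))
      if (is.null(co[[f]]))
        stop("cohort entry is missing field '", f, "'")
  }
  arms <- unique(vapply(cfg$cohorts, function(co)
    if (!is.null(co$pool_into)) co$pool_into else co$label, character(1)))
  if (is.null(cfg$reference_arm))
    cfg$reference_arm <- arms[1L]
  if (!cfg$reference_arm %in% arms)
    stop("reference_arm '", cfg$reference_arm,
         "' does not name any (possibly pooled) arm; arms are: ",
         paste(arms, collapse = ", "))
  if (is.null(cfg$tau)) cfg$tau <- 15
  if (cfg$tau <= 0) stop("tau must be positive")
  if (is.null(cfg$bootstrap_b)) cfg$bootstrap_b <- 1000L
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$auto_truncate_tau)) cfg$auto_truncate_tau <- FALSE
  structure(cfg, class = "study_config")
}

resolve_path <- function(path, dir) {
  if (is.null(dir) || grepl("^(/|[A-Za-z]:)", path)) path
  else file.path(dir, path)
}

#' Run a reconstruction-and-comparison study
#'
#' The end-to-end pipeline: for each cohort, read and preprocess the
#' digitized curve and reconstruct IPD from (curve, N, D); pool cohorts
#' that share a `pool_into` label; then per arm fit the KM curve, median
#' OS, the Cox hazard ratio against the reference arm, RMST at the
#' milestone, and the Weibull fit with its extrapolated mean lifetime
#' survival; finally compute all pairwise RMST differences (unadjusted, as
#' is usual for indirect single-arm comparisons). Per-cohort failures are
#' collected and reported with the cohort label; the run aborts only when
#' the reference arm itself cannot be built.
#'
#' @param config a `study_config` (from [read_study_config()] or
#'   [validate_study_config()]).
#' @return An object of class `study_report`: list with `arms` (per-arm
#'   rows), `rmst_differences`, `errors`, `metadata`, and the underlying
#'   `ipd` sets in `$ipd`.
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config"))
    config <- validate_study_config(config)
  errors <- character(0)

  cohort_ipd <- list()
  for (co in config$cohorts) {
    res <- tryCatch({
      path <- resolve_path(co$curve, config$dir)
      curve <- preprocess_curve(read_curve_table(path))
      meta <- curve_meta(co$label, co$n_patients, co$n_events,
                         co$max_follow_up)
      reconstruct_ipd(curve, meta)
    }, error = function(e)
      structure(conditionMessage(e), class = "cohort_error"))
    if (inherits(res, "cohort_error"))
      errors <- c(errors, paste0("cohort '", co$label, "': ", res))
    else
      cohort_ipd[[co$label]] <- res
  }

  # pooling
  groups <- list()
  for (co in config$cohorts) {
    if (is.null(cohort_ipd[[co$label]])) next
    g <- if (!is.null(co$pool_into)) co$pool_into else co$label
    groups[[g]] <- c(groups[[g]], list(cohort_ipd[[co$label]]))
  }
  arms <- lapply(names(groups), function(g) pool_ipd(groups[[g]], g))
  names(arms) <- names(groups)

  ref <- config$reference_arm
  if (is.null(arms[[ref]]))
    stop("reference arm '", ref, "' could not be built: ",
         paste(errors, collapse = "; "))

  tau <- config$tau
  max_obs <- vapply(arms, function(a) max(a$time), numeric(1))
  if (tau > min(max_obs)) {
    if (isTRUE(config$auto_truncate_tau)) {
      tau <- min(max_obs)
      warning("milestone truncated to ", format(tau),
              " months, the shortest arm follow-up")
    } else {
      stop("milestone tau = ", tau, " exceeds follow-up of arm '",
           names(arms)[which.min(max_obs)], "' (", format(min(max_obs)),
           " months); set auto_truncate_tau to allow truncation")
    }
  }

  arm_rows <- list()
  for (g in names(arms)) {
    a <- arms[[g]]
    row <- tryCatch({
      km <- km_fit(a)
      hr <- if (g == ref) NULL else cox_hr(a, arms[[ref]])
      rm <- rmst(a, tau)
      wf <- weibull_fit(a)
      mls <- mean_lifetime_survival(wf, B = config$bootstrap_b,
                                    seed = config$seed)
      m <- attr(a, "meta")
      list(label = g, n_patients = m$n_patients, n_events = m$n_events,
           median_os = median_survival(km),
           hr = if (is.null(hr)) 1 else hr$hr,
           hr_ci_low = if (is.null(hr)) NA_real_ else hr$ci_low,
           hr_ci_high = if (is.null(hr)) NA_real_ else hr$ci_high,
           hr_p = if (is.null(hr)) NA_real_ else hr$p,
           rmst = rm$rmst, rmst_ci_low = rm$ci_low,
           rmst_ci_high = rm$ci_high,
           weibull_shape = wf$shape, weibull_scale = wf$scale,
           mls = mls$mls, mls_ci_low = mls$ci_low,
           mls_ci_high = mls$ci_high)
    }, error = function(e)
      structure(conditionMessage(e), class = "cohort_error"))
    if (inherits(row, "cohort_error")) {
      msg <- paste0("arm '", g, "': ", row)
      if (g == ref) stop(msg)
      errors <- c(errors, msg)
    } else {
      arm_rows[[g]] <- row
    }
  }

  pair_rows <- list()
  labs <- names(arm_rows)
  if (length(labs) > 1L) {
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i >= j) next
      rd <- tryCatch(rmst_diff(arms[[labs[j]]], arms[[labs[i]]], tau),
                     error = function(e) NULL)
      if (!is.null(rd))
        pair_rows[[paste(labs[j], "vs", labs[i])]] <-
          list(arm = labs[j], reference = labs[i], diff = rd$diff,
               ci_low = rd$ci_low, ci_high = rd$ci_high, p = rd$p)
    }
  }

  structure(list(
    arms = arm_rows,
    rmst_differences = pair_rows,
    errors = errors,
    ipd = arms,
    metadata = list(
      reference_arm = ref, tau = tau, bootstrap_b = config$bootstrap_b,
      seed = config$seed,
      assumptions = c(
        "uniform in-follow-up censoring in IPD reconstruction",
        "Efron correction for tied event times in the Cox model",
        "Wald (log-scale) 95% CI for the hazard ratio",
        "parametric bootstrap percentile 95% CI for MLS",
        "pairwise comparisons unadjusted for multiplicity"),
      package_version = as.character(utils::packageVersion("survrecon")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (reference arm:", x$metadata$reference_arm,
      "| milestone:", format(x$metadata$tau), "months)\n\n")
  fmt_med <- function(m) if (is.na(m)) "not reached" else sprintf("%.1f", m)
  for (r in x$arms)
    cat(sprintf(
      "  %-22s %d/%d  median %s  HR %s  RMST %.1f (%.1f-%.1f)  MLS %.1f (%.1f-%.1f)\n",
      r$label, r$n_events, r$n_patients, fmt_med(r$median_os),
      if (is.na(r$hr_p)) "1 (ref)" else
        sprintf("%.2f (%.2f-%.3f, p=%.3g)", r$hr, r$hr_ci_low,
                r$hr_ci_high, r$hr_p),
      r$rmst, r$rmst_ci_low, r$rmst_ci_high,
      r$mls, r$mls_ci_low, r$mls_ci_high))
  if (length(x$rmst_differences)) {
    cat("\n  RMST differences at the milestone:\n")
    for (d in x$rmst_differences)
      cat(sprintf("  %s vs %s: %.2f (95%% CI %.2f to %.2f, p=%.3g)\n",
                  d$arm, d$reference, d$diff, d$ci_low, d$ci_high, d$p))
  }
  if (length(x$errors))
    cat("\n  Errors:\n", paste("   ", x$errors, collapse = "\n"), "\n")
  invisible(x)
}

report_to_table <- function(report) {
  do.call(rbind, lapply(report$arms, function(r)
    data.frame(label = r$label,
               events_patients = paste0(r$n_events, "/", r$n_patients),
               median_os = if (is.na(r$median_os)) "not reached"
                           else sprintf("%.1f", r$median_os),
               hr = sprintf("%.2f", r$hr),
               hr_ci = if (is.na(r$hr_p)) "reference"
                       else sprintf("%.2f to %.3f", r$hr_ci_low, r$hr_ci_high),
               hr_p = if (is.na(r$hr_p)) "" else sprintf("%.3g", r$hr_p),
               rmst = sprintf("%.1f (%.1f to %.1f)", r$rmst,
                              r$rmst_ci_low, r$rmst_ci_high),
               mls = sprintf("%.1f (%.1f to %.1f)", r$mls,
                             r$mls_ci_low, r$mls_ci_high),
               stringsAsFactors = FALSE)))
}

#' Write a study report to disk
#'
#' Emits three renderings: `report.json` (machine-readable, medians that
#' are not reached serialized as the tag `"not reached"`), `report.csv`
#' (one row per arm) and `report.md` (a markdown table). Months are
#' formatted to one decimal, ratios to two, in the style of a published
#' summary table.
#'
#' @param report a `study_report`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (length(report$arms) == 0L)
    stop("report has no successfully analyzed arm; nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  json_arms <- lapply(report$arms, function(r) {
    r$median_os <- if (is.na(r$median_os)) "not reached" else r$median_os
    r
  })
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(arms = json_arms, rmst_differences = report$rmst_differences,
         errors = report$errors, metadata = report$metadata),
    json_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")

  tab <- report_to_table(report)
  csv_path <- file.path(dir, "report.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE)

  md_path <- file.path(dir, "report.md")
  hdr <- c("Arm", "n/N", "Median OS (mos)", "HR", "HR 95% CI", "p",
           "RMST (mos)", "MLS (mos)")
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
             apply(tab, 1L, function(r)
               paste0("| ", paste(r, collapse = " | "), " |")),
             "",
             "RMST differences at the milestone:",
             vapply(report$rmst_differences, function(d)
               sprintf("- %s vs %s: %.2f (95%% CI %.2f to %.2f, p=%.3g)",
                       d$arm, d$reference, d$diff, d$ci_low, d$ci_high,
                       d$p), character(1)))
  writeLines(lines, md_path)
  invisible(list(json = json_path, csv = csv_path, markdown = md_path))
}

#' Re-read a JSON study report
#'
#' @param path path to a `report.json` written by [write_report()].
#' @return The report as a plain list (arms, rmst_differences, errors,
#'   metadata).
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Rehydrate a study report from its JSON rendering
#'
#' Rebuilds a `study_report` object (minus the IPD sets, which are not
#' serialized) from `report.json`, so the table renderings can be
#' regenerated without re-running the analysis.
#'
#' @inheritParams read_report_json
#' @return A `study_report` object.
#' @export
rehydrate_report <- function(path) {
  x <- read_report_json(path)
  arms <- lapply(x$arms, function(r) {
    r$median_os <- if (identical(r$median_os, "not reached")) NA_real_
                   else as.numeric(r$median_os)
    for (f in c("hr_ci_low", "hr_ci_high", "hr_p"))
      r[[f]] <- if (is.null(r[[f]])) NA_real_ else as.numeric(r[[f]])
    r
  })
  names(arms) <- vapply(arms, `[[`, "", "label")
  structure(list(arms = arms, rmst_differences = x$rmst_differences,
                 errors = unlist(x$errors), ipd = NULL,
                 metadata = x$metadata),
            class = "study_report")
}
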