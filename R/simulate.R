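#' Specification of a synthetic survival cohort
#'
#' Describes one generative arm: the event-time distribution, cohort size,
#' administrative censoring horizon, an optional exponential random
#' (loss-to-follow-up) censoring rate, and the seed that makes the draw
#' reproducible. Supported distributions:
#'
#' * `exponential`: constant hazard, `rate` per month;
#' * `weibull`: `shape` and `scale` (months);
#' * `piecewise_exponential`: `breakpoints` (months, increasing) and
#'   `rates` (length = breakpoints + 1) — useful for the plateauing curves
#'   a single exponential cannot mimic.
#'
#' @param distribution one of `"exponential"`, `"weibull"`,
#'   `"piecewise_exponential"`.
#' @param n cohort size (>= 1).
#' @param admin_censor administrative censoring time in months (Inf for
#'   none).
#' @param random_censor_rate exponential censoring rate per month (0 for
#'   none).
#' @param seed integer seed.
#' @param label arm label.
#' @param rate,shape,scale,breakpoints,rates distribution parameters, see
#'   above.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(distribution = c("exponential", "weibull",
                                      "piecewise_exponential"),
                     n, admin_censor = Inf, random_censor_rate = 0,
                     seed = 1L, label = "sim",
                     rate = NULL, shape = NULL, scale = NULL,
                     breakpoints = NULL, rates = NULL) {
  distribution <- match.arg(distribution)
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("`n` must be a positive cohort size")
  if (admin_censor <= 0)
    stop("`admin_censor` must be positive (use Inf for none)")
  if (random_censor_rate < 0)
    stop("`random_censor_rate` must be nonnegative")
  pars <- switch(distribution,
    exponential = {
      if (is.null(rate) || rate <= 0) stop("`rate` must be positive")
      list(rate = rate)
    },
    weibull = {
      if (is.null(shape) || shape <= 0 || is.null(scale) || scale <= 0)
        stop("`shape` and `scale` must be positive")
      list(shape = shape, scale = scale)
    },
    piecewise_exponential = {
      if (is.null(breakpoints) || is.null(rates) ||
          length(rates) != length(breakpoints) + 1L)
        stop("need `rates` of length length(breakpoints) + 1")
      if (any(rates <= 0) || is.unsorted(breakpoints, strictly = TRUE) ||
          any(breakpoints <= 0))
        stop("rates must be positive and breakpoints increasing")
      list(breakpoints = breakpoints, rates = rates)
    })
  structure(c(list(distribution = distribution, n = n,
                   admin_censor = admin_censor,
                   random_censor_rate = random_censor_rate,
                   seed = as.integer(seed), label = label), pars),
            class = "sim_spec")
}

# inverse-CDF draw from a piecewise-exponential hazard
rpwexp <- function(n, breakpoints, rates) {
  bounds <- c(0, breakpoints)
  widths <- diff(c(bounds, Inf))
  cumhaz_at <- cumsum(c(0, rates[-length(rates)] * widths[-length(widths)]))
  u <- -log(stats::runif(n))          # target cumulative hazard
  idx <- findInterval(u, cumhaz_at)
  bounds[idx] + (u - cumhaz_at[idx]) / rates[idx]
}

#' Simulate a survival cohort
#'
#' Draws latent event times from the spec's distribution, a censoring time
#' as the minimum of the administrative horizon and (if the rate is
#' positive) an exponential random censoring draw, and observes
#' time = min(event, censoring) with the event flag set accordingly. Fully
#' determined by the spec's seed; the caller's RNG state is untouched.
#'
#' @param spec a [sim_spec()].
#' @return An `ipd` object of `spec$n` records.
#' @export
simulate_ipd <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  latent <- switch(spec$distribution,
    exponential = stats::rexp(spec$n, rate = spec$rate),
    weibull = stats::rweibull(spec$n, shape = spec$shape,
                              scale = spec$scale),
    piecewise_exponential = rpwexp(spec$n, spec$breakpoints, spec$rates))
  cens <- rep(spec$admin_censor, spec$n)
  if (spec$random_censor_rate > 0)
    cens <- pmin(cens, stats::rexp(spec$n, rate = spec$random_censor_rate))
  time <- pmin(latent, cens)
  event <- as.integer(latent <= cens)
  ipd_set(time, event, spec$label)
}

#' Exact KM step coordinates of an IPD set
#'
#' The inverse of reconstruction for testing purposes: emits the exact
#' product-limit step coordinates — (0, 1), then (drop time, post-drop
#' survival) for each distinct event time, ending at the largest observed
#' time. Feeding these coordinates back through [reconstruct_ipd()] with
#' the true N and D closes the round trip.
#'
#' @param ipd an `ipd` object.
#' @return A [digitized_curve()].
#' @export
ipd_to_curve <- function(ipd) {
  stopifnot(inherits(ipd, "ipd"))
  km <- km_fit(ipd)
  times <- c(0, km$event_times)
  surv <- c(1, km$surv)
  if (km$max_time > times[length(times)]) {
    times <- c(times, km$max_time)
    surv <- c(surv, surv[length(surv)])
  }
  digitized_curve(times, surv)
}

#' Perturb a curve to emulate digitization error
#'
#' Resamples the step function on an even time grid over \[0, max time\],
#' adds Gaussian noise (truncated so values stay in \[0, 1\]) to the
#' survival values, and re-runs [preprocess_curve()] so the output is again
#' a valid curve. With `sigma = 0` the survival values at the grid times
#' are unchanged.
#'
#' @param curve a preprocessed [digitized_curve()].
#' @param sigma noise standard deviation on the survival-probability scale.
#' @param grid_points number of grid points (>= 2).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return A valid [digitized_curve()] on the even grid.
#' @export
perturb_curve <- function(curve, sigma, grid_points, seed = 1L) {
  stopifnot(inherits(curve, "digitized_curve"))
  if (sigma < 0)
    stop("`sigma` must be nonnegative")
  grid_points <- as.integer(grid_points)
  if (grid_points < 2L)
    stop("need at least 2 grid points")
  grid <- seq(0, max(curve$times), length.out = grid_points)
  idx <- findInterval(grid, curve$times)
  s <- curve$surv[pmax(idx, 1L)]
  if (sigma > 0) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    }
    set.seed(seed)
    s <- pmin(pmax(s + stats::rnorm(grid_points, 0, sigma), 0), 1)
  }
  preprocess_curve(digitized_curve(grid, s), percent = FALSE)
}

#' Write synthetic fixtures for a simulated arm
#'
#' Materializes one synthetic cohort as the file triple the pipeline
#' consumes: the digitized-curve CSV, the IPD CSV, and a JSON sidecar with
#' the generative truth (spec fields, N, D), so a test or demo study can be
#' assembled without any external download.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @param noise_sigma,grid_points optional digitization noise applied to
#'   the emitted curve (defaults: none / exact coordinates).
#' @return Invisibly, a list with the three file paths and the `ipd`.
#' @export
write_sim_fixture <- function(spec, dir, noise_sigma = 0,
                              grid_points = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ipd <- simulate_ipd(spec)
  curve <- ipd_to_curve(ipd)
  if (noise_sigma > 0 || !is.null(grid_points)) {
    gp <- if (is.null(grid_points)) length(curve$times) else grid_points
    curve <- perturb_curve(curve, noise_sigma, gp, seed = spec$seed + 1L)
  }
  stem <- file.path(dir, spec$label)
  curve_path <- paste0(stem, "_curve.csv")
  ipd_path <- paste0(stem, "_ipd.csv")
  truth_path <- paste0(stem, "_truth.json")
  utils::write.csv(data.frame(time = curve$times, survival = curve$surv),
                   curve_path, row.names = FALSE)
  write_ipd(ipd, ipd_path)
  meta <- attr(ipd, "meta")
  jsonlite::write_json(
    list(spec = unclass(spec), n_patients = meta$n_patients,
         n_events = meta$n_events,
         max_follow_up = meta$max_follow_up),
    truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(curve = curve_path, ipd = ipd_path, truth = truth_path,
                 records = ipd))
}
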