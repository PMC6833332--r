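#' Sparse measurement-design strategy
#'
#' Ways of reducing the number of sampled passages when planning a
#' senescence time-course: drop the earliest passages, drop the latest,
#' sample at a regular stride ("skip"), or drop a consecutive block from
#' the middle.
#'
#' @param kind One of `"drop-first"`, `"drop-last"`, `"skip"`,
#'   `"drop-middle-block"`.
#' @param k Points removed (or the skip stride); `k = 0` leaves the design
#'   unchanged.
#' @return An object of class `sen_design_strategy`.
#' @export
design_strategy <- function(kind = c("drop-first", "drop-last", "skip",
                                     "drop-middle-block"), k = 0L) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop("k must be a non-negative integer",
                               call. = FALSE)
  structure(list(kind = kind, k = k), class = "sen_design_strategy")
}

#' Apply a design strategy to a dataset
#'
#' Removes whole passages (all markers, replicate rows following their
#' passage). `skip` with stride `s` retains the first passage and then
#' every `(s+1)`-th.
#'
#' @param dataset A validated dataset.
#' @param strategy A [design_strategy()].
#' @return The reduced dataset.
#' @export
apply_strategy <- function(dataset, strategy) {
  stopifnot(inherits(strategy, "sen_design_strategy"))
  dataset <- validate_dataset(dataset)
  k <- strategy$k
  if (k == 0L) return(dataset)
  passages <- sort(unique(dataset$passage))
  np <- length(passages)
  keep <- switch(strategy$kind,
    "drop-first" = if (k >= np) integer(0) else seq(k + 1L, np),
    "drop-last" = if (k >= np) integer(0) else seq_len(np - k),
    "skip" = seq(1L, np, by = k + 1L),
    "drop-middle-block" = {
      if (k >= np) integer(0) else {
        start <- (np - k) %/% 2L + 1L
        setdiff(seq_len(np), seq(start, start + k - 1L))
      }
    })
  if (length(keep) < 2L) {
    stop("strategy '", strategy$kind, "' with k = ", k,
         " leaves fewer than 2 passages", call. = FALSE)
  }
  reduced <- dataset[dataset$passage %in% passages[keep], , drop = FALSE]
  nt <- tapply(reduced$time_h, reduced$marker, function(x)
    length(unique(x)))
  if (any(nt < 2L)) {
    stop("strategy leaves a marker with fewer than 2 time points",
         call. = FALSE)
  }
  rownames(reduced) <- NULL
  reduced
}

#' Information cost of a sparse measurement design
#'
#' Refits the model on the strategy-reduced dataset and scores that refit on
#' the FULL dataset, reporting the percent increase over the full-data
#' baseline cost. The increase measures the information lost by not taking
#' the omitted measurements.
#'
#' @param dataset Full dataset.
#' @param strategy A [design_strategy()].
#' @param spec A [cost_spec()].
#' @param seed RNG seed for the refits.
#' @param ga GA configuration used for the (re)fits.
#' @param baseline Optional precomputed full-data `sen_fit`.
#' @param warm_start If `TRUE` (default) the reduced-data refit is seeded
#'   from the full-data optimum, keeping runtimes modest; set `FALSE` for a
#'   cold start.
#' @return Percent increase (scalar); the refit and baseline are attached
#'   as attributes `refit` and `baseline`.
#' @export
design_strategy_error <- function(dataset, strategy, spec = cost_spec(),
                                  seed = 1L, ga = ga_config(),
                                  baseline = NULL, warm_start = TRUE) {
  dataset <- validate_dataset(dataset)
  if (is.null(baseline)) {
    baseline <- fit_model(dataset, spec = spec, ga = ga, seed = seed)
  }
  if (strategy$k == 0L) {
    out <- 0
    attr(out, "baseline") <- baseline
    attr(out, "refit") <- baseline
    return(out)
  }
  reduced <- apply_strategy(dataset, strategy)
  refit <- fit_model(reduced, spec = spec, ga = ga, seed = seed,
                     init = if (warm_start) baseline else NULL,
                     N = baseline$N)
  cost_full <- model_cost(refit$params, refit$mparams, dataset, spec)
  out <- 100 * (cost_full - baseline$cost) / baseline$cost
  attr(out, "baseline") <- baseline
  attr(out, "refit") <- refit
  out
}

#' Two-parameter sensitivity surface over a rate ladder's endpoints
#'
#' For each grid point, the chosen ladder is rebuilt from the candidate
#' (youngest-age, oldest-age) endpoint pair with all other parameters held
#' at their supplied values, and the percent cost increase over the
#' supplied parameterization is recorded. The grid diagonal corresponds to
#' age-independent (flat) ladders.
#'
#' @param params,mparams Reference parameterization (the surface is 0 when
#'   the grid hits its ladder endpoints).
#' @param dataset Dataset the cost is evaluated on.
#' @param pair Which ladder: `"div"`, `"sen"`, `"arr"` or `"apo"`.
#' @param first_values Grid for the endpoint at doubling age 0 (x-axis).
#' @param last_values Grid for the endpoint at age N-1 (y-axis); defaults
#'   to `first_values`.
#' @param spec A [cost_spec()].
#' @return An object of class `sen_sensitivity_grid`: list with the axis
#'   grids, the matrix `increase_pct` (rows = `first_values`), the baseline
#'   cost and the location of the grid minimum. Simulation failures are
#'   recorded as `NA` cells.
#' @export
sensitivity_grid <- function(params, mparams, dataset,
                             pair = c("div", "sen", "arr", "apo"),
                             first_values, last_values = first_values,
                             spec = cost_spec()) {
  pair <- match.arg(pair)
  dataset <- validate_dataset(dataset)
  base_cost <- model_cost(params, mparams, dataset, spec)
  field <- paste0(pair, "_ladder")
  N <- params$N
  inc <- matrix(NA_real_, length(first_values), length(last_values))
  for (i in seq_along(first_values)) {
    for (j in seq_along(last_values)) {
      p2 <- params
      p2[[field]] <- linear_rate_ladder(first_values[i], last_values[j], N)
      cst <- tryCatch(model_cost(p2, mparams, dataset, spec),
                      error = function(e) NA_real_)
      inc[i, j] <- if (is.na(cst)) NA_real_ else
        100 * (cst - base_cost) / base_cost
    }
  }
  amin <- which(inc == min(inc, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  structure(list(pair = pair, first_values = first_values,
                 last_values = last_values, increase_pct = inc,
                 baseline_cost = base_cost,
                 argmin = c(first = first_values[amin[1L]],
                            last = last_values[amin[2L]])),
            class = "sen_sensitivity_grid")
}

#' One-parameter sensitivity scan
#'
#' @inheritParams sensitivity_grid
#' @param param_name One of `"m_GS"`, `"m_AD"`, `"frac_P_gH2AX"`,
#'   `"frac_G_Ki67"`, `"frac_G_gH2AX"`.
#' @param values Grid of candidate values.
#' @return Data frame with columns `value` and `increase_pct`; the grid
#'   argmin is attached as attribute `argmin`.
#' @export
sensitivity_scan <- function(params, mparams, dataset,
                             param_name = c("m_GS", "m_AD", "frac_P_gH2AX",
                                            "frac_G_Ki67", "frac_G_gH2AX"),
                             values, spec = cost_spec()) {
  param_name <- match.arg(param_name)
  dataset <- validate_dataset(dataset)
  base_cost <- model_cost(params, mparams, dataset, spec)
  inc <- vapply(values, function(v) {
    p2 <- params; m2 <- mparams
    if (param_name %in% c("m_GS", "m_AD")) p2[[param_name]] <- v
    else m2[[param_name]] <- v
    cst <- tryCatch(model_cost(p2, m2, dataset, spec),
                    error = function(e) NA_real_)
    if (is.na(cst)) NA_real_ else 100 * (cst - base_cost) / base_cost
  }, 0)
  out <- data.frame(value = values, increase_pct = inc)
  attr(out, "argmin") <- values[which.min(inc)]
  attr(out, "baseline_cost") <- base_cost
  out
}

#' Time of the peak growth-arrested fraction
#'
#' Locates the maximum of `G/TP` along a trajectory by discrete argmax plus
#' quadratic interpolation through the three surrounding grid points.
#'
#' @param trajectory A `sen_trajectory` spanning the peak.
#' @return Peak time in hours.
#' @export
peak_growth_arrest_time <- function(trajectory) {
  stopifnot(inherits(trajectory, "sen_trajectory"))
  f <- trajectory$G / trajectory$TP
  n <- length(f)
  i <- which.max(f)
  if (i == 1L || i == n) {
    stop(structure(class = c("senodyn_no_peak", "error", "condition"),
                   list(message = paste0(
                     "growth-arrested fraction is monotone over the window",
                     " (argmax at ", if (i == 1L) "start" else "end", ")"),
                     call = NULL)))
  }
  x <- trajectory$times[(i - 1L):(i + 1L)]
  y <- f[(i - 1L):(i + 1L)]
  # vertex of the parabola through the three surrounding points
  d1 <- x[2L] - x[1L]; d3 <- x[2L] - x[3L]
  den <- d1 * (y[2L] - y[3L]) - d3 * (y[2L] - y[1L])
  if (abs(den) < .Machine$double.eps) return(x[2L])
  x[2L] - 0.5 * (d1^2 * (y[2L] - y[3L]) - d3^2 * (y[2L] - y[1L])) / den
}

#' First time the senescent fraction reaches a threshold
#'
#' Simulates on a dense (1 h) grid and locates the first crossing of
#' `S/TP >= threshold` by interpolation within the bracketing step.
#'
#' @param params A [model_parameters()].
#' @param threshold Senescent fraction in \[0, 1).
#' @param horizon Simulation horizon in hours.
#' @param initial Optional initial state (default: all in `P_0`).
#' @return Crossing time in hours; signals a classed condition
#'   (`senodyn_not_reached`, carrying the final fraction as field
#'   `final_fraction`) if the threshold is not reached within the horizon.
#' @export
time_to_senescence_fraction <- function(params, threshold = 0.85,
                                        horizon = 10000, initial = NULL) {
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  if (threshold == 0) return(0)
  times <- seq(0, horizon, by = 1)
  traj <- simulate_population(params, t_end = horizon, output_times = times,
                              initial = initial)
  f <- traj$S / traj$TP
  idx <- which(f >= threshold)
  if (!length(idx)) {
    cond <- structure(
      class = c("senodyn_not_reached", "error", "condition"),
      list(message = sprintf(
        "senescent fraction reached only %.4f of threshold %.4f within %g h",
        f[length(f)], threshold, horizon),
        call = NULL, final_fraction = f[length(f)]))
    stop(cond)
  }
  i <- idx[1L]
  if (i == 1L) return(times[1L])
  # linear interpolation within the bracketing 1 h step
  t0 <- times[i - 1L]; t1 <- times[i]
  f0 <- f[i - 1L]; f1 <- f[i]
  if (f1 == f0) return(t1)
  t0 + (threshold - f0) / (f1 - f0) * (t1 - t0)
}
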