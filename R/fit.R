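#' Genetic-algorithm configuration
#'
#' Conventional real-coded GA settings: tournament selection, uniform
#' crossover, per-gene Gaussian mutation, elitism.
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param tournament_k Tournament size for selection.
#' @param p_crossover Probability of uniform crossover between two parents.
#' @param p_mutation Per-gene mutation probability.
#' @param mutation_sd_frac Mutation standard deviation as a fraction of each
#'   gene's box width.
#' @param elitism Number of best individuals copied unchanged.
#' @return An object of class `sen_ga_config`.
#' @export
ga_config <- function(pop_size = 200L, generations = 300L,
                      tournament_k = 3L, p_crossover = 0.7,
                      p_mutation = 0.15, mutation_sd_frac = 0.1,
                      elitism = 2L) {
  cfg <- list(pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              tournament_k = as.integer(tournament_k),
              p_crossover = p_crossover, p_mutation = p_mutation,
              mutation_sd_frac = mutation_sd_frac,
              elitism = as.integer(elitism))
  if (cfg$pop_size < 2L || cfg$generations < 1L || cfg$tournament_k < 1L ||
      cfg$p_crossover < 0 || cfg$p_crossover > 1 ||
      cfg$p_mutation < 0 || cfg$p_mutation > 1 ||
      cfg$mutation_sd_frac <= 0 || cfg$elitism < 0 ||
      cfg$elitism >= cfg$pop_size) {
    stop("infeasible GA configuration", call. = FALSE)
  }
  structure(cfg, class = "sen_ga_config")
}

new_fit_result <- function(theta, cost, N, seed, generations, config,
                           history = NULL, refined = FALSE,
                           grad_norm = NA_real_, warning_flag = FALSE,
                           initial_best_cost = NA_real_) {
  dec <- theta_decode(theta, N)
  structure(list(params = dec$params, mparams = dec$mparams,
                 theta = stats::setNames(theta, .theta_names),
                 cost = cost, N = N, seed = seed,
                 generations = generations, config = config,
                 history = history, refined = refined,
                 grad_norm = grad_norm, warning_flag = warning_flag,
                 initial_best_cost = initial_best_cost),
            class = "sen_fit")
}

#' @export
print.sen_fit <- function(x, ...) {
  cat("Senescence model fit: cost", format(x$cost, digits = 6),
      if (isTRUE(x$refined)) "(gradient-refined)" else "", "\n")
  cat("  seed", x$seed, "| generations", x$generations,
      "| N", x$N, "\n")
  if (is.finite(x$grad_norm))
    cat("  gradient norm at termination:", format(x$grad_norm), "\n")
  invisible(x)
}

#' Fit the 13 tunable model parameters with a genetic algorithm
#'
#' Real-coded GA over the log-rate / fraction box (rates log-uniform in
#' `[1e-5, 1e-1]` per hour, fractions in `[0, 1]`), minimizing
#' [model_cost()]. Deterministic for a fixed `seed`.
#'
#' @param dataset Marker dataset to fit (see [validate_dataset()]).
#' @param spec A [cost_spec()].
#' @param ga A [ga_config()].
#' @param seed Integer RNG seed.
#' @param N Number of doubling-age classes of the fitted model.
#' @param init Optional warm start: a `sen_fit` or a numeric theta vector;
#'   it is injected into the initial population together with jittered
#'   copies.
#' @return A `sen_fit` with the best parameters found, their cost, and
#'   search metadata (per-generation best-cost history, seed, config).
#' @export
fit_ga <- function(dataset, spec = cost_spec(), ga = ga_config(),
                   seed = 1L, N = 50L, init = NULL) {
  stopifnot(inherits(ga, "sen_ga_config"))
  dataset <- validate_dataset(dataset)
  fn <- theta_cost_fn(dataset, spec, N)
  b <- theta_bounds()
  d <- length(b$lower)
  width <- b$upper - b$lower
  set.seed(as.integer(seed))

  pop <- matrix(stats::runif(ga$pop_size * d, b$lower, b$upper),
                nrow = ga$pop_size, ncol = d, byrow = TRUE)
  if (!is.null(init)) {
    th0 <- if (inherits(init, "sen_fit")) init$theta else as.numeric(init)
    if (length(th0) != d) stop("init theta has wrong length", call. = FALSE)
    th0 <- pmin(pmax(th0, b$lower), b$upper)
    n_seeded <- min(max(2L, ga$pop_size %/% 10L), ga$pop_size)
    pop[1L, ] <- th0
    for (j in seq_len(n_seeded - 1L)) {
      pop[1L + j, ] <- pmin(pmax(
        th0 + stats::rnorm(d, 0, 0.02 * width), b$lower), b$upper)
    }
  }
  fitness <- apply(pop, 1L, fn)
  initial_best <- min(fitness)
  history <- numeric(ga$generations)

  for (gen in seq_len(ga$generations)) {
    ord <- order(fitness)
    elite <- pop[ord[seq_len(ga$elitism)], , drop = FALSE]
    newpop <- matrix(NA_real_, ga$pop_size, d)
    if (ga$elitism > 0L) newpop[seq_len(ga$elitism), ] <- elite
    for (k in seq(ga$elitism + 1L, ga$pop_size)) {
      # tournament selection of two parents
      pick <- function() {
        cand <- sample.int(ga$pop_size, ga$tournament_k)
        cand[which.min(fitness[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- if (stats::runif(1) < ga$p_crossover) {
        mask <- stats::runif(d) < 0.5
        ifelse(mask, p1, p2)
      } else p1
      mut <- stats::runif(d) < ga$p_mutation
      if (any(mut)) {
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, ga$mutation_sd_frac * width[mut])
      }
      newpop[k, ] <- pmin(pmax(child, b$lower), b$upper)
    }
    keep <- if (ga$elitism > 0L) seq_len(ga$elitism) else integer(0)
    newfit <- fitness[ord[keep]]
    rest <- seq(ga$elitism + 1L, ga$pop_size)
    newfit <- c(newfit, apply(newpop[rest, , drop = FALSE], 1L, fn))
    pop <- newpop
    fitness <- newfit
    history[gen] <- min(fitness)
  }
  best <- which.min(fitness)
  new_fit_result(theta = pop[best, ], cost = fitness[best], N = N,
                 seed = as.integer(seed), generations = ga$generations,
                 config = ga, history = history,
                 initial_best_cost = initial_best)
}

central_gradient <- function(fn, theta, lower, upper, h) {
  d <- length(theta)
  g <- numeric(d)
  for (j in seq_len(d)) {
    hj <- h[j]
    up <- theta; up[j] <- min(theta[j] + hj, upper[j])
    lo <- theta; lo[j] <- max(theta[j] - hj, lower[j])
    denom <- up[j] - lo[j]
    g[j] <- if (denom > 0) (fn(up) - fn(lo)) / denom else 0
  }
  g
}

#' Gradient-descent refinement of a fit
#'
#' Box-constrained quasi-Newton descent (`stats::optim` L-BFGS-B) with
#' central-difference gradients, started from a GA result, to polish the
#' optimum and verify a local minimum via the terminal gradient norm.
#'
#' @param start A `sen_fit` (or theta vector) to refine.
#' @param dataset Dataset the cost is evaluated on.
#' @param spec A [cost_spec()].
#' @param maxit Maximum L-BFGS-B iterations.
#' @return A `sen_fit` with cost no larger than the start's; `grad_norm`
#'   holds the central-difference gradient norm at termination and
#'   `warning_flag` is set if the line search failed (in which case the
#'   start is returned unchanged).
#' @export
refine_gradient <- function(start, dataset, spec = cost_spec(),
                            maxit = 500L) {
  N <- if (inherits(start, "sen_fit")) start$N else 50L
  th0 <- if (inherits(start, "sen_fit")) start$theta else as.numeric(start)
  dataset <- validate_dataset(dataset)
  fn <- theta_cost_fn(dataset, spec, N)
  b <- theta_bounds()
  h <- 1e-6 * (b$upper - b$lower)
  gr <- function(theta) central_gradient(fn, theta, b$lower, b$upper, h)
  start_cost <- if (inherits(start, "sen_fit")) start$cost else fn(th0)

  res <- tryCatch(
    stats::optim(par = as.numeric(th0), fn = fn, gr = gr,
                 method = "L-BFGS-B", lower = b$lower, upper = b$upper,
                 control = list(maxit = maxit, factr = 10, pgtol = 1e-10)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) || res$value > start_cost) {
    return(new_fit_result(
      theta = as.numeric(th0), cost = start_cost, N = N,
      seed = if (inherits(start, "sen_fit")) start$seed else NA_integer_,
      generations = if (inherits(start, "sen_fit")) start$generations else 0L,
      config = if (inherits(start, "sen_fit")) start$config else NULL,
      refined = FALSE, warning_flag = TRUE,
      grad_norm = sqrt(sum(gr(as.numeric(th0))^2))))
  }
  new_fit_result(
    theta = res$par, cost = res$value, N = N,
    seed = if (inherits(start, "sen_fit")) start$seed else NA_integer_,
    generations = if (inherits(start, "sen_fit")) start$generations else 0L,
    config = if (inherits(start, "sen_fit")) start$config else NULL,
    history = if (inherits(start, "sen_fit")) start$history else NULL,
    refined = TRUE, grad_norm = sqrt(sum(gr(res$par)^2)),
    initial_best_cost = if (inherits(start, "sen_fit"))
      start$initial_best_cost else NA_real_)
}

#' Full fit: genetic algorithm followed by gradient refinement
#'
#' @inheritParams fit_ga
#' @param refine If `TRUE` (default), polish the GA optimum with
#'   [refine_gradient()].
#' @return A `sen_fit`.
#' @export
fit_model <- function(dataset, spec = cost_spec(), ga = ga_config(),
                      seed = 1L, N = 50L, init = NULL, refine = TRUE) {
  fit <- fit_ga(dataset, spec = spec, ga = ga, seed = seed, N = N,
                init = init)
  if (refine) fit <- refine_gradient(fit, dataset, spec = spec)
  fit
}

#' Holdout analysis of fit robustness
#'
#' Repeatedly removes a random fraction of the records, refits, scores the
#' refit on the full dataset, and reports the relative cost increase over
#' the full-data baseline: small increases indicate redundant information.
#'
#' @param dataset Full dataset.
#' @param holdout_fraction Fraction of records removed per repetition
#'   (0 < f < 1).
#' @param reps Number of repetitions.
#' @param seed RNG seed controlling both the partitions and the refits.
#' @param spec A [cost_spec()].
#' @param ga GA configuration for the refits.
#' @param baseline Optional precomputed full-data `sen_fit`; refits are
#'   warm-started from it.
#' @return A data frame with one row per repetition: `rep`, `n_removed`,
#'   `cost_refit_full`, `rel_increase`; baseline cost in
#'   `attr(, "baseline_cost")`.
#' @export
holdout_analysis <- function(dataset, holdout_fraction = 0.2, reps = 5L,
                             seed = 1L, spec = cost_spec(),
                             ga = ga_config(), baseline = NULL) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must lie strictly between 0 and 1",
         call. = FALSE)
  }
  dataset <- validate_dataset(dataset)
  if (is.null(baseline)) {
    baseline <- fit_model(dataset, spec = spec, ga = ga, seed = seed)
  }
  n <- nrow(dataset)
  n_remove <- as.integer(round(holdout_fraction * n))
  set.seed(as.integer(seed))
  partitions <- lapply(seq_len(reps), function(r) sample.int(n, n_remove))
  out <- lapply(seq_len(reps), function(r) {
    if (n_remove == 0L) {
      # nothing removed: the refit is the baseline problem itself
      return(data.frame(rep = r, n_removed = 0L,
                        cost_refit_full = baseline$cost, rel_increase = 0))
    }
    drop_idx <- partitions[[r]]
    reduced <- dataset[-drop_idx, , drop = FALSE]
    nt <- tapply(reduced$time_h, reduced$marker,
                 function(x) length(unique(x)))
    if (length(nt) < length(unique(dataset$marker)) || any(nt < 2L)) {
      stop("holdout removal left a marker with fewer than 2 time points",
           call. = FALSE)
    }
    refit <- fit_model(reduced, spec = spec, ga = ga, seed = seed + r,
                       init = baseline, N = baseline$N)
    cost_full <- model_cost(refit$params, refit$mparams, dataset, spec)
    data.frame(rep = r, n_removed = n_remove, cost_refit_full = cost_full,
               rel_increase = (cost_full - baseline$cost) / baseline$cost)
  })
  res <- do.call(rbind, out)
  attr(res, "baseline_cost") <- baseline$cost
  res
}

#' Write a fit result to JSON
#' @param fit A `sen_fit`.
#' @param path Output `.json` path.
#' @export
write_fit <- function(fit, path) {
  out <- list(
    cost = fit$cost, seed = fit$seed, N = fit$N,
    generations = fit$generations, refined = fit$refined,
    grad_norm = fit$grad_norm,
    parameters = as.list(stats::setNames(
      c(10^as.numeric(fit$theta[1:10]), as.numeric(fit$theta[11:13])),
      .theta_names)),
    ga_config = unclass(fit$config),
    package_version = as.character(utils::packageVersion("senodyn")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
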