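test_that("the genetic algorithm is deterministic for a fixed seed", {
  ds <- noiseless_dataset()
  a <- fit_ga(ds, ga = ga_tiny(), seed = 9)
  b <- fit_ga(ds, ga = ga_tiny(), seed = 9)
  expect_identical(a$theta, b$theta)
  expect_identical(a$cost, b$cost)
  expect_identical(a$history, b$history)
  c2 <- fit_ga(ds, ga = ga_tiny(), seed = 10)
  expect_false(identical(a$theta, c2$theta))
})

test_that("GA plus refinement collapses the cost on noise-free data", {
  ds <- noiseless_dataset()
  fit <- fit_ga(ds, ga = ga_config(pop_size = 60, generations = 40),
                seed = 23)
  expect_lt(fit$cost, fit$initial_best_cost)  # search improves on chance
  refined <- refine_gradient(fit, ds, maxit = 150)
  expect_lt(refined$cost, 0.01 * fit$initial_best_cost)
  expect_lte(refined$cost, fit$cost)
  # all parameters inside the search box
  b <- senodyn:::theta_bounds()
  expect_true(all(refined$theta >= b$lower & refined$theta <= b$upper))
  expect_true(is.finite(refined$grad_norm))
})

test_that("refinement descends from a perturbed optimum without leaving bounds", {
  ref <- ref_set()
  ds <- noiseless_dataset()
  b <- senodyn:::theta_bounds()
  truth <- senodyn:::theta_encode(ref$params, ref$mparams)
  set.seed(29)
  start <- pmin(pmax(truth + 0.05 * (b$upper - b$lower) *
                       stats::rnorm(length(truth)), b$lower), b$upper)
  fn <- senodyn:::theta_cost_fn(ds, cost_spec(), 50L)
  start_cost <- fn(start)
  expect_gt(start_cost, 1e-6)
  out <- refine_gradient(start, ds, maxit = 60)
  expect_lt(out$cost, start_cost)
  expect_true(all(out$theta >= b$lower & out$theta <= b$upper))
})

test_that("a flat-ladder truth is recovered as approximately flat", {
  p_flat <- params_from_endpoints(0.02, 0.02, 0.002, 0.002, 0.003, 0.003,
                                  0.0017, 0.0017, 0.0007, 0.001, N = 50)
  mp <- marker_params(0.24, 0.99, 0.82)
  ds <- generate_dataset(p_flat, mp,
                         design_spec(stain_sd = 0, pd_sd = 0,
                                     replicates = 1), seed = 2)
  fit <- fit_model(ds, ga = ga_config(pop_size = 100, generations = 80),
                   seed = 21)
  for (lad in c("div_ladder", "sen_ladder", "arr_ladder", "apo_ladder")) {
    v <- fit$params[[lad]]
    expect_lt(abs(v[50] - v[1]) / mean(c(v[1], v[50])), 0.05)
  }
})

test_that("holdout refitting reports no information loss on redundant data", {
  ds <- noiseless_dataset()
  baseline <- fit_model(ds, ga = ga_small(), seed = 33)
  # removing zero records leaves the optimization problem unchanged
  ho0 <- holdout_analysis(ds, holdout_fraction = 0.001, reps = 1, seed = 3,
                          ga = ga_tiny(), baseline = baseline)
  expect_identical(ho0$n_removed, 0L)
  expect_identical(ho0$rel_increase, 0)
  # noise-free records are redundant: refits after a 20% holdout still sit
  # at the (near-zero) noise floor of the full dataset
  ho <- holdout_analysis(ds, holdout_fraction = 0.2, reps = 2, seed = 5,
                         ga = ga_tiny(), baseline = baseline)
  expect_identical(ho$n_removed, c(16L, 16L))
  marker_var <- mean(vapply(split(ds$value, ds$marker), function(v)
    stats::var(v) / diff(range(v))^2, 0))
  expect_lt(stats::median(ho$cost_refit_full), 1e-4 * marker_var)
  # identical partitions and results under the same seed
  ho2 <- holdout_analysis(ds, holdout_fraction = 0.2, reps = 2, seed = 5,
                          ga = ga_tiny(), baseline = baseline)
  expect_identical(ho$cost_refit_full, ho2$cost_refit_full)
  expect_error(holdout_analysis(ds, holdout_fraction = 1.2, reps = 1),
               "between 0 and 1")
})

test_that("holdout error increase is modest on noisy data", {
  # with measurement noise the baseline cost is a meaningful floor and the
  # relative increase from removing ~20% of records should be small
  base <- noisy_baseline_fit()
  ho <- holdout_analysis(noisy_dataset(), holdout_fraction = 0.2, reps = 2,
                         seed = 19, ga = ga_tiny(), baseline = base)
  expect_lt(stats::median(ho$rel_increase), 0.25)
  expect_gt(stats::median(ho$rel_increase), -0.05)
})

test_that("fit results re-evaluate to their reported cost and serialize", {
  ds <- noiseless_dataset()
  fit <- fit_ga(ds, ga = ga_tiny(), seed = 9)
  expect_equal(model_cost(fit$params, fit$mparams, ds), fit$cost,
               tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$cost, fit$cost)
  expect_equal(back$parameters$mGS, 10^fit$theta[["mGS"]])
  expect_identical(back$seed, 9L)
})

test_that("infeasible GA configurations are refused", {
  expect_error(ga_config(pop_size = 1), "infeasible")
  expect_error(ga_config(p_crossover = 1.5), "infeasible")
  expect_error(ga_config(elitism = 50, pop_size = 10), "infeasible")
})
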