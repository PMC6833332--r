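# Shared fixtures (memoised so expensive objects are built once per run)
# and independent numerical oracles.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

ref_set <- function() fixture("ref", reference_parameters)

# noise-free single-replicate dataset from the reference parameters
noiseless_dataset <- function() fixture("noiseless", function() {
  ref <- ref_set()
  generate_dataset(ref$params, ref$mparams,
                   design_spec(stain_sd = 0, pd_sd = 0, replicates = 1),
                   seed = 1)
})

# triplicate dataset with the default measurement noise
noisy_dataset <- function() fixture("noisy", function() {
  ref <- ref_set()
  generate_dataset(ref$params, ref$mparams, seed = 7)
})

# reference-parameter trajectory over the full 5000 h window, 1 h grid
reference_trajectory <- function() fixture("ref_traj", function() {
  simulate_population(ref_set()$params, t_end = 5000,
                      output_times = seq(0, 5000, by = 1))
})

# Fixed-step classical RK4 integrator over the R-level derivative();
# independent of both the compiled right-hand side and the adaptive solver.
rk4_states <- function(params, t_end, h, report_times, initial = NULL) {
  N <- params$N
  if (is.null(initial)) initial <- seed_state(N)
  y <- senodyn:::state_to_vec(initial)
  rhs <- function(v) {
    senodyn:::state_to_vec(
      derivative(senodyn:::vec_to_state(v, N), params))
  }
  steps <- round(t_end / h)
  stopifnot(abs(steps * h - t_end) < 1e-9)
  out <- matrix(NA_real_, length(report_times), length(y))
  t <- 0
  for (k in seq_len(steps)) {
    k1 <- rhs(y)
    k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2)
    k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- k * h
    hit <- which(abs(report_times - t) < h / 2)
    if (length(hit)) out[hit[1L], ] <- y
  }
  out
}

# hand-built trajectory object for unit tests of trajectory consumers
fake_trajectory <- function(times, G = 0, A = 0, S = 0, D = 0, TP = 1) {
  n <- length(times)
  G <- rep_len(G, n); A <- rep_len(A, n); S <- rep_len(S, n)
  D <- rep_len(D, n); TP <- rep_len(TP, n)
  P_total <- TP - G - A - S
  structure(list(times = times, P = matrix(P_total, ncol = 1L),
                 G = G, A = A, S = S, D = D,
                 P_total = P_total, TP = TP, N = 1L),
            class = "sen_trajectory")
}

# converged fit of the default noisy triplicate dataset, shared by the
# N-insensitivity, design-strategy and holdout checks
noisy_baseline_fit <- function() fixture("noisy_fit", function() {
  fit <- fit_ga(noisy_dataset(),
                ga = ga_config(pop_size = 80, generations = 60), seed = 11)
  refine_gradient(fit, noisy_dataset())
})

# small GA budgets used by the test suite (simulations are smooth and
# warm-started, so desk-scale budgets converge; the vignette discusses this)
ga_small <- function() ga_config(pop_size = 30L, generations = 25L)
ga_tiny <- function() ga_config(pop_size = 16L, generations = 4L)
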