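#' Population state of the culture at one instant
#'
#' @param P Numeric vector of length `N`: cell quantity in each proliferative
#'   doubling-age class (`P[i]` holds cells that have divided `i - 1` times).
#' @param G,A,S,D Scalar quantities of growth-arrested, apoptotic, senescent
#'   and dead cells. Dead cells are excluded from the live total.
#' @return An object of class `sen_state`.
#' @export
population_state <- function(P, G = 0, A = 0, S = 0, D = 0) {
  if (!is.numeric(P) || length(P) < 1L || anyNA(P)) {
    stop("P must be a numeric vector of per-age cell quantities",
         call. = FALSE)
  }
  scalars <- c(G = G, A = A, S = S, D = D)
  if (!is.numeric(scalars) || anyNA(scalars)) {
    stop("G, A, S and D must be numeric scalars", call. = FALSE)
  }
  if (any(P < 0) || any(scalars < 0)) {
    stop("cell quantities must be non-negative", call. = FALSE)
  }
  structure(list(P = as.numeric(P), G = as.numeric(G), A = as.numeric(A),
                 S = as.numeric(S), D = as.numeric(D)),
            class = "sen_state")
}

#' Default seed state: live total 1, entirely in the youngest class
#' @param N Number of doubling-age classes.
#' @return A `sen_state` with `P[1] = 1` and all other compartments 0.
#' @export
seed_state <- function(N) population_state(c(1, rep(0, N - 1L)))

#' Live total of a population state (dead cells excluded)
#' @param state A `sen_state`.
#' @return `sum(P) + G + A + S`.
#' @export
live_total <- function(state) sum(state$P) + state$G + state$A + state$S

# state <-> flat solver vector: c(P_1..P_N, G, A, S, D)
state_to_vec <- function(state) c(state$P, state$G, state$A, state$S, state$D)
vec_to_state <- function(y, N) {
  structure(list(P = y[seq_len(N)], G = y[N + 1L], A = y[N + 2L],
                 S = y[N + 3L], D = y[N + 4L]), class = "sen_state")
}

#' Instantaneous rates of change of the compartment model
#'
#' Pure R reference implementation of the model right-hand side. Mitosis
#' moves cells out of age class `i` at the division rate and deposits the
#' two daughters in class `i + 1` (twice the leaving flux); division out of
#' the oldest class `P_{N-1}` lands in S with the same factor 2. Jumps into
#' S, G and A carry cells one-for-one; G drains into S at `m_GS` and A into
#' the dead pool at `m_AD`.
#'
#' @param state A [population_state()].
#' @param params A [model_parameters()] with matching `N`.
#' @return A `sen_state`-shaped list of per-hour rates of change.
#' @export
derivative <- function(state, params) {
  N <- params$N
  if (length(state$P) != N) {
    stop("state has ", length(state$P), " proliferative classes but the ",
         "parameters define N = ", N, call. = FALSE)
  }
  P <- state$P
  exit <- params$div_ladder + params$sen_ladder +
    params$arr_ladder + params$apo_ladder
  dP <- -exit * P
  if (N > 1L) {
    dP[2:N] <- dP[2:N] + 2 * params$div_ladder[1:(N - 1L)] * P[1:(N - 1L)]
  }
  dG <- sum(params$arr_ladder * P) - params$m_GS * state$G
  dA <- sum(params$apo_ladder * P) - params$m_AD * state$A
  dS <- 2 * params$div_ladder[N] * P[N] + sum(params$sen_ladder * P) +
    params$m_GS * state$G
  dD <- params$m_AD * state$A
  structure(list(P = dP, G = dG, A = dA, S = dS, D = dD),
            class = "sen_state")
}

# parameter vector for the compiled RHS, padded to the fixed C-side length
sen_parms_vec <- function(params) {
  N <- params$N
  maxn <- 512L
  if (N > maxn) stop("N exceeds the compiled limit of ", maxn, call. = FALSE)
  p <- numeric(4L * maxn + 3L)
  p[1L] <- N
  p[1L + seq_len(N)] <- params$div_ladder
  p[1L + N + seq_len(N)] <- params$sen_ladder
  p[1L + 2L * N + seq_len(N)] <- params$arr_ladder
  p[1L + 3L * N + seq_len(N)] <- params$apo_ladder
  p[4L * N + 2L] <- params$m_GS
  p[4L * N + 3L] <- params$m_AD
  p
}

#' Simulate the transition of a culture towards senescence
#'
#' Integrates the compartment ODE system with an adaptive solver
#' (`deSolve::lsoda` over a compiled right-hand side) and returns the
#' trajectory at the requested output times.
#'
#' @param params A [model_parameters()].
#' @param t_end End of the simulation window, hours (> 0).
#' @param output_times Times (hours) at which the state is reported; default
#'   is a uniform 501-point grid over \[0, t_end\]. Must lie in
#'   \[0, t_end\].
#' @param initial Initial [population_state()]; default [seed_state()] with
#'   live total 1 entirely in `P_0`.
#' @param rtol,atol Solver relative and absolute tolerances.
#' @return An object of class `sen_trajectory`: list with `times`, matrix
#'   `P` (rows = times, columns = doubling-age classes), vectors `G`, `A`,
#'   `S`, `D`, plus derived `P_total` and `TP` (live total).
#' @export
simulate_population <- function(params, t_end, output_times = NULL,
                                initial = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "sen_params"))
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= 0) {
    stop("t_end must be a positive duration in hours", call. = FALSE)
  }
  N <- params$N
  if (is.null(initial)) initial <- seed_state(N)
  if (length(initial$P) != N) {
    stop("initial state and parameters disagree on N", call. = FALSE)
  }
  if (is.null(output_times)) output_times <- seq(0, t_end, length.out = 501L)
  output_times <- as.numeric(output_times)
  if (any(output_times < 0 | output_times > t_end) ||
      is.unsorted(output_times, strictly = TRUE)) {
    stop("output_times must be strictly increasing within [0, t_end]",
         call. = FALSE)
  }
  solver_times <- output_times
  prepend <- FALSE
  if (solver_times[1L] > 0) {  # lsoda integrates from the first time given
    solver_times <- c(0, solver_times)
    prepend <- TRUE
  }
  out <- deSolve::ode(
    y = state_to_vec(initial), times = solver_times,
    func = "senodyn_derivs", parms = sen_parms_vec(params),
    dllname = "senodyn", initfunc = "senodyn_initmod",
    method = "lsoda", rtol = rtol, atol = atol)
  if (prepend) out <- out[-1L, , drop = FALSE]
  y <- out[, -1L, drop = FALSE]
  if (anyNA(y) || any(!is.finite(y))) {
    bad <- which(apply(y, 1L, function(r) anyNA(r) || any(!is.finite(r))))[1L]
    stop("integration failed: non-finite state at t = ",
         output_times[bad], " h", call. = FALSE)
  }
  P <- y[, seq_len(N), drop = FALSE]
  G <- y[, N + 1L]; A <- y[, N + 2L]; S <- y[, N + 3L]; D <- y[, N + 4L]
  P_total <- rowSums(P)
  structure(list(times = output_times, P = P, G = G, A = A, S = S, D = D,
                 P_total = P_total, TP = P_total + G + A + S, N = N),
            class = "sen_trajectory")
}

#' Population doublings along a trajectory
#'
#' `PD(t) = log2(TP(t) / TP(0))` on the live total `TP = sum(P) + G + A + S`
#' (dead cells excluded).
#'
#' @param trajectory A `sen_trajectory`.
#' @return Numeric vector of PD values, one per output time; `PD = 0` at the
#'   first time.
#' @export
population_doublings <- function(trajectory) {
  stopifnot(inherits(trajectory, "sen_trajectory"))
  tp0 <- trajectory$TP[1L]
  if (!is.finite(tp0) || tp0 <= 0) {
    stop("initial live population must be positive to define doublings",
         call. = FALSE)
  }
  log2(trajectory$TP / tp0)
}

#' Extract the population state at one output time
#' @param trajectory A `sen_trajectory`.
#' @param i Row index into the trajectory's time grid.
#' @return A `sen_state`.
#' @export
state_at <- function(trajectory, i) {
  population_state(P = trajectory$P[i, ], G = max(trajectory$G[i], 0),
                   A = max(trajectory$A[i], 0), S = max(trajectory$S[i], 0),
                   D = max(trajectory$D[i], 0))
}

#' @export
as.data.frame.sen_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, P_total = x$P_total, G = x$G, A = x$A,
             S = x$S, D = x$D, TP = x$TP, PD = population_doublings(x))
}

#' @export
print.sen_trajectory <- function(x, ...) {
  cat("Senescence trajectory:", length(x$times), "output times over [",
      x$times[1L], ",", x$times[length(x$times)], "] h, N =", x$N, "\n")
  n <- length(x$times)
  cat(sprintf("  final composition (of TP): P %.3g%%, G %.3g%%, A %.3g%%, S %.3g%%\n",
              100 * x$P_total[n] / x$TP[n], 100 * x$G[n] / x$TP[n],
              100 * x$A[n] / x$TP[n], 100 * x$S[n] / x$TP[n]))
  invisible(x)
}

#' Write a trajectory as a delimited table
#' @param trajectory A `sen_trajectory`.
#' @param path Output CSV path (columns `time_h, P_total, G, A, S, D, TP, PD`).
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
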