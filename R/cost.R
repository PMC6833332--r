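#' Cost specification for model-data comparison
#'
#' The fitting cost is a range-normalized mean squared error: for each
#' marker, residuals (model minus observation, with replicates entering as
#' individual records) are divided by that marker's observed range, squared,
#' averaged, weighted and summed. Range normalization makes the doublings
#' channel (0-22) commensurate with the percentage channels (0-100) and
#' makes relative-error-increase statistics scale-free.
#'
#' @param weights Named positive weights per marker; defaults to 1 for each
#'   of `sen_markers`.
#' @param pd_offset_mode How observed PD values (which typically start at
#'   the cumulative doubling count of the seed passage, e.g. PD5) are
#'   aligned with model PD (which starts at 0): `"subtract-first"` (default;
#'   both sides are re-centred at the earliest observed PD time, so the
#'   alignment is unchanged when early records are dropped), `"free-offset"`
#'   (additive offset chosen to minimize the PD residual), or `"none"`.
#' @return An object of class `sen_cost_spec`.
#' @export
cost_spec <- function(weights = NULL,
                      pd_offset_mode = c("subtract-first", "free-offset",
                                         "none")) {
  pd_offset_mode <- match.arg(pd_offset_mode)
  w <- stats::setNames(rep(1, length(sen_markers)), sen_markers)
  if (!is.null(weights)) {
    if (is.null(names(weights)) || !all(names(weights) %in% sen_markers)) {
      stop("weights must be named by marker (", paste(sen_markers,
           collapse = ", "), ")", call. = FALSE)
    }
    w[names(weights)] <- weights
  }
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  structure(list(weights = w, pd_offset_mode = pd_offset_mode),
            class = "sen_cost_spec")
}

# Precompiled cost evaluator: index bookkeeping is done once per dataset so
# optimizer loops pay only for the ODE solve and a few vector operations.
make_cost_evaluator <- function(dataset, spec = cost_spec()) {
  dataset <- validate_dataset(dataset)
  times <- sort(unique(dataset$time_h))
  t_end <- max(times)
  ti <- match(dataset$time_h, times)
  mi <- match(dataset$marker, sen_markers)  # PD, SA-b-Gal, Ki-67, gH2AX, TUNEL
  present <- sort(unique(mi))
  per_marker <- lapply(present, function(m) which(mi == m))
  obs <- dataset$value
  # observed ranges (shift-invariant, so PD alignment does not change them)
  rng <- vapply(per_marker, function(idx) {
    r <- diff(range(obs[idx]))
    if (r <= 0) 1 else r
  }, 0)
  w <- spec$weights[sen_markers[present]]
  pd_pos <- match(1L, present)
  pd_shift <- 0
  pd_t1 <- NA_integer_
  if (!is.na(pd_pos) && spec$pd_offset_mode == "subtract-first") {
    idx <- per_marker[[pd_pos]]
    t0 <- min(dataset$time_h[idx])
    pd_shift <- mean(obs[idx][dataset$time_h[idx] == t0])
    pd_t1 <- match(t0, times)  # model PD is re-centred here too, so the
    # alignment is invariant to dropping early records
  }

  function(params, mparams) {
    traj <- simulate_population(params, t_end = t_end, output_times = times)
    TP <- traj$TP
    if (any(TP <= 0)) stop("live total vanished during simulation",
                           call. = FALSE)
    M <- cbind(
      log2(TP / TP[1L]),
      100 * traj$S / TP,
      100 * (traj$P_total + mparams$frac_G_Ki67 * traj$G) / TP,
      100 * (traj$S + traj$A + mparams$frac_P_gH2AX * traj$P_total +
               mparams$frac_G_gH2AX * traj$G) / TP,
      100 * traj$A / TP)
    pred <- M[cbind(ti, mi)]
    total <- 0
    for (k in seq_along(present)) {
      idx <- per_marker[[k]]
      o <- obs[idx]; p <- pred[idx]
      if (present[k] == 1L) {
        if (spec$pd_offset_mode == "subtract-first") {
          o <- o - pd_shift
          p <- p - M[pd_t1, 1L]
        } else if (spec$pd_offset_mode == "free-offset") {
          o <- o - mean(o - p)
        }
      }
      total <- total + w[[k]] * mean(((p - o) / rng[k])^2)
    }
    total
  }
}

#' Model-data discrepancy for a marker dataset
#'
#' Range-normalized weighted mean squared error between the model's marker
#' readouts and the observed records (see [cost_spec()] for the functional
#' form and PD alignment).
#'
#' @param params A [model_parameters()].
#' @param mparams A [marker_params()].
#' @param dataset A validated dataset (see [validate_dataset()]).
#' @param spec A [cost_spec()].
#' @return Non-negative scalar cost.
#' @export
model_cost <- function(params, mparams, dataset, spec = cost_spec()) {
  make_cost_evaluator(dataset, spec)(params, mparams)
}

# ---- 13-parameter optimization encoding -----------------------------------
# theta = (log10 of the 8 ladder endpoints + mGS + mAD, then 3 fractions).
# Rates are searched log-uniformly in [1e-5, 1e-1] /h; fractions in [0, 1].

.theta_names <- c("mP0P1", "mPN1PN", "mP0G", "mPN1G", "mP0S", "mPN1S",
                  "mP0A", "mPN1A", "mGS", "mAD",
                  "PgH2AX", "GKi67", "GgH2AX")

theta_bounds <- function() {
  list(lower = c(rep(-5, 10), rep(0, 3)),
       upper = c(rep(-1, 10), rep(1, 3)))
}

theta_decode <- function(theta, N = 50L) {
  r <- 10^theta[1:10]
  list(
    params = params_from_endpoints(
      mP0P1 = r[1], mPN1PN = r[2], mP0G = r[3], mPN1G = r[4],
      mP0S = r[5], mPN1S = r[6], mP0A = r[7], mPN1A = r[8],
      m_GS = r[9], m_AD = r[10], N = N),
    mparams = marker_params(frac_P_gH2AX = theta[11],
                            frac_G_Ki67 = theta[12],
                            frac_G_gH2AX = theta[13]))
}

theta_encode <- function(params, mparams) {
  N <- params$N
  th <- c(log10(c(params$div_ladder[1L], params$div_ladder[N],
                  params$arr_ladder[1L], params$arr_ladder[N],
                  params$sen_ladder[1L], params$sen_ladder[N],
                  params$apo_ladder[1L], params$apo_ladder[N],
                  params$m_GS, params$m_AD)),
          mparams$frac_P_gH2AX, mparams$frac_G_Ki67, mparams$frac_G_gH2AX)
  b <- theta_bounds()
  stats::setNames(pmin(pmax(th, b$lower), b$upper), .theta_names)
}

# cost as a function of theta; Inf on simulation failure
theta_cost_fn <- function(dataset, spec, N) {
  evaluator <- make_cost_evaluator(dataset, spec)
  function(theta) {
    dec <- tryCatch(theta_decode(theta, N), error = function(e) NULL)
    if (is.null(dec)) return(Inf)
    out <- tryCatch(evaluator(dec$params, dec$mparams),
                    error = function(e) Inf)
    if (!is.finite(out)) Inf else out
  }
}
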