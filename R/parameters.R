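#' Linear transition-rate ladder over doubling age
#'
#' Builds the vector of per-hour transition rates for the proliferative
#' doubling-age classes `i = 0, ..., N-1`, interpolated linearly between the
#' rate of the youngest class (`m_first`, at `P_0`) and the oldest
#' (`m_last`, at `P_{N-1}`).
#'
#' @param m_first Rate (per hour) at doubling age 0. Non-negative.
#' @param m_last Rate (per hour) at doubling age `N - 1`. Non-negative.
#' @param N Number of doubling-age classes (at least 2).
#' @return Numeric vector of length `N`; entry `i + 1` is the rate at
#'   doubling age `i`.
#' @examples
#' linear_rate_ladder(0.0259, 0.0063, 50)[c(1, 50)]
#' @export
linear_rate_ladder <- function(m_first, m_last, N) {
  if (!is.numeric(m_first) || !is.numeric(m_last) ||
      length(m_first) != 1L || length(m_last) != 1L ||
      !is.finite(m_first) || !is.finite(m_last) ||
      m_first < 0 || m_last < 0) {
    stop("ladder endpoints must be single finite non-negative rates",
         call. = FALSE)
  }
  N <- as.integer(N)
  if (is.na(N) || N < 2L) {
    stop("a rate ladder needs at least N = 2 doubling-age classes",
         call. = FALSE)
  }
  m_first + (0:(N - 1L)) * (m_last - m_first) / (N - 1L)
}

#' Model parameters for the senescence transition model
#'
#' Bundles the four doubling-age rate ladders (division, jump-to-senescence,
#' growth arrest, apoptosis), the two scalar rates (growth-arrested to
#' senescent, apoptotic to dead) and the division limit `N` (the
#' Hayflick-like maximum number of divisions).
#'
#' @param div_ladder,sen_ladder,arr_ladder,apo_ladder Numeric vectors of
#'   length `N` of non-negative per-hour rates, normally built with
#'   [linear_rate_ladder()]. `div_ladder[i]` is the rate at which cells of
#'   doubling age `i - 1` divide into the next age class; the other three
#'   are the rates of jumping into the senescent (S), growth-arrested (G)
#'   and apoptotic (A) states.
#' @param m_GS Scalar rate (per hour) of the G to S transition.
#' @param m_AD Scalar rate (per hour) of the A to dead transition.
#' @return An object of class `sen_params`.
#' @export
model_parameters <- function(div_ladder, sen_ladder, arr_ladder, apo_ladder,
                             m_GS, m_AD) {
  N <- length(div_ladder)
  ladders <- list(div = div_ladder, sen = sen_ladder,
                  arr = arr_ladder, apo = apo_ladder)
  for (nm in names(ladders)) {
    v <- ladders[[nm]]
    if (!is.numeric(v) || length(v) != N || anyNA(v) || any(!is.finite(v))) {
      stop("all four rate ladders must be finite numeric vectors of the ",
           "same length (got mismatch in '", nm, "' ladder)", call. = FALSE)
    }
    if (any(v < 0)) {
      stop("rate ladder '", nm, "' contains negative rates", call. = FALSE)
    }
  }
  if (N < 1L) stop("ladders must have at least one entry", call. = FALSE)
  for (r in list(m_GS = m_GS, m_AD = m_AD)) {
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0) {
      stop("m_GS and m_AD must be single finite non-negative rates",
           call. = FALSE)
    }
  }
  structure(
    list(div_ladder = as.numeric(div_ladder),
         sen_ladder = as.numeric(sen_ladder),
         arr_ladder = as.numeric(arr_ladder),
         apo_ladder = as.numeric(apo_ladder),
         m_GS = as.numeric(m_GS), m_AD = as.numeric(m_AD),
         N = as.integer(N)),
    class = "sen_params")
}

#' Model parameters from ladder endpoints
#'
#' Convenience constructor taking the eight ladder endpoint rates (the form
#' the optimizer works in), the two scalar rates and `N`.
#'
#' @param mP0P1,mPN1PN Division-rate endpoints at doubling ages 0 and `N-1`.
#' @param mP0G,mPN1G Growth-arrest-rate endpoints.
#' @param mP0S,mPN1S Senescence-jump-rate endpoints.
#' @param mP0A,mPN1A Apoptosis-rate endpoints.
#' @param m_GS,m_AD Scalar rates as in [model_parameters()].
#' @param N Number of doubling-age classes (default 50).
#' @return An object of class `sen_params`.
#' @export
params_from_endpoints <- function(mP0P1, mPN1PN, mP0G, mPN1G,
                                  mP0S, mPN1S, mP0A, mPN1A,
                                  m_GS, m_AD, N = 50L) {
  model_parameters(
    div_ladder = linear_rate_ladder(mP0P1, mPN1PN, N),
    sen_ladder = linear_rate_ladder(mP0S, mPN1S, N),
    arr_ladder = linear_rate_ladder(mP0G, mPN1G, N),
    apo_ladder = linear_rate_ladder(mP0A, mPN1A, N),
    m_GS = m_GS, m_AD = m_AD)
}

#' Marker-contribution parameters
#'
#' The three free fractions linking model populations to stain readouts:
#' the fraction of proliferative cells staining gammaH2AX-positive, and the
#' fractions of growth-arrested cells staining Ki-67- and
#' gammaH2AX-positive. Senescent and apoptotic cells contribute fully to
#' gammaH2AX; SA-beta-Gal and TUNEL map one-to-one onto S and A.
#'
#' @param frac_P_gH2AX Fraction in \[0, 1\] of P cells gammaH2AX-positive.
#' @param frac_G_Ki67 Fraction in \[0, 1\] of G cells Ki-67-positive.
#' @param frac_G_gH2AX Fraction in \[0, 1\] of G cells gammaH2AX-positive.
#' @return An object of class `sen_marker_params`.
#' @export
marker_params <- function(frac_P_gH2AX, frac_G_Ki67, frac_G_gH2AX) {
  fr <- c(frac_P_gH2AX = frac_P_gH2AX, frac_G_Ki67 = frac_G_Ki67,
          frac_G_gH2AX = frac_G_gH2AX)
  if (!is.numeric(fr) || anyNA(fr) || any(fr < 0 | fr > 1)) {
    stop("marker contribution fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(fr), class = "sen_marker_params")
}

#' Packaged reference parameter set
#'
#' Reads the optimized reference parameter file shipped with the package
#' (division ladder 0.0259 to 0.0063 per hour, N = 50, etc.).
#'
#' @return A list with elements `params` ([model_parameters()]) and
#'   `mparams` ([marker_params()]).
#' @export
reference_parameters <- function() {
  read_params(system.file("extdata", "senescence_reference_params.json",
                          package = "senodyn", mustWork = TRUE))
}

#' @export
print.sen_params <- function(x, ...) {
  cat("Senescence model parameters (N =", x$N, "doubling-age classes)\n")
  ep <- function(v) sprintf("%.4g -> %.4g /h", v[1], v[length(v)])
  cat("  division   P_i -> P_{i+1}:", ep(x$div_ladder), "\n")
  cat("  senescence P_i -> S     :", ep(x$sen_ladder), "\n")
  cat("  arrest     P_i -> G     :", ep(x$arr_ladder), "\n")
  cat("  apoptosis  P_i -> A     :", ep(x$apo_ladder), "\n")
  cat("  m_GS:", format(x$m_GS), "/h   m_AD:", format(x$m_AD), "/h\n")
  invisible(x)
}

#' @export
print.sen_marker_params <- function(x, ...) {
  cat("Marker contribution fractions:\n")
  cat("  P gammaH2AX+:", x$frac_P_gH2AX,
      "  G Ki-67+:", x$frac_G_Ki67,
      "  G gammaH2AX+:", x$frac_G_gH2AX, "\n")
  invisible(x)
}
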