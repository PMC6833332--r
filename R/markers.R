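#' Canonical marker names used throughout the package
#'
#' `"PD"` (population doublings), `"SA-b-Gal"`, `"Ki-67"`, `"gH2AX"`,
#' `"TUNEL"`.
#' @export
sen_markers <- c("PD", "SA-b-Gal", "Ki-67", "gH2AX", "TUNEL")

#' Map a population trajectory onto the five experimental readouts
#'
#' Stain channels are percentages of the live total `TP`:
#' SA-beta-Gal = S, TUNEL = A, Ki-67 = all of P plus a fraction of G, and
#' gammaH2AX = all of S and A plus fractions of P and G. Dead cells are
#' invisible to all markers. PD is reported in doublings.
#'
#' @param trajectory A `sen_trajectory` from [simulate_population()].
#' @param mparams A [marker_params()].
#' @return A data frame of class `sen_marker_series` with columns `time_h`,
#'   `pd`, `sa_b_gal`, `ki67`, `gH2AX`, `tunel` (stains in percent, 0-100).
#' @export
marker_readouts <- function(trajectory, mparams) {
  stopifnot(inherits(trajectory, "sen_trajectory"),
            inherits(mparams, "sen_marker_params"))
  TP <- trajectory$TP
  if (any(!is.finite(TP) | TP <= 0)) {
    stop("live total TP must be positive at every output time to define ",
         "marker percentages", call. = FALSE)
  }
  P <- trajectory$P_total; G <- trajectory$G
  A <- trajectory$A; S <- trajectory$S
  out <- data.frame(
    time_h = trajectory$times,
    pd = population_doublings(trajectory),
    sa_b_gal = 100 * S / TP,
    ki67 = 100 * (P + mparams$frac_G_Ki67 * G) / TP,
    gH2AX = 100 * (S + A + mparams$frac_P_gH2AX * P +
                     mparams$frac_G_gH2AX * G) / TP,
    tunel = 100 * A / TP)
  class(out) <- c("sen_marker_series", class(out))
  out
}

#' Reshape a marker series to long (one row per time and marker) form
#'
#' @param series A `sen_marker_series` from [marker_readouts()].
#' @return Data frame with columns `time_h`, `marker`, `value` (stains in
#'   percent; PD in doublings).
#' @export
marker_series_long <- function(series) {
  cols <- c(PD = "pd", `SA-b-Gal` = "sa_b_gal", `Ki-67` = "ki67",
            gH2AX = "gH2AX", TUNEL = "tunel")
  do.call(rbind, lapply(names(cols), function(m) {
    data.frame(time_h = series$time_h, marker = m,
               value = series[[cols[[m]]]])
  }))
}

#' Write a marker series as a long delimited table
#' @param series A `sen_marker_series`.
#' @param path Output CSV path (columns `time_h, marker, value_percent`;
#'   the PD rows are in doublings, not percent).
#' @export
write_marker_series <- function(series, path) {
  long <- marker_series_long(series)
  names(long)[3L] <- "value_percent"
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
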