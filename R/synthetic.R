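#' Experimental design for synthetic marker datasets
#'
#' Defaults emulate a 16-passage replicative-senescence time-course
#' (passages 5 to 20, one sampling every 160 h over 0-2400 h) with all
#' five markers measured in triplicate, additive Gaussian measurement
#' noise, and PD reported cumulatively from the seed passage's doubling
#' count (offset +5).
#'
#' @param times Passage sampling times in hours, strictly increasing.
#' @param replicates Replicates per (passage, marker); at least 1.
#' @param stain_sd Noise standard deviation for the four stain channels, in
#'   percentage points.
#' @param pd_sd Noise standard deviation for PD, in doublings.
#' @param pd_offset Constant added to model PD before noise, mimicking the
#'   cumulative doubling count of the seed passage.
#' @param passage_start Passage number of the first sampling time.
#' @return An object of class `sen_design_spec`.
#' @export
design_spec <- function(times = seq(0, 2400, by = 160), replicates = 3L,
                        stain_sd = 3, pd_sd = 0.2, pd_offset = 5,
                        passage_start = 5L) {
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("design times must be strictly increasing and non-negative",
         call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be a positive integer", call. = FALSE)
  }
  if (stain_sd < 0 || pd_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  structure(list(times = as.numeric(times), replicates = replicates,
                 stain_sd = stain_sd, pd_sd = pd_sd, pd_offset = pd_offset,
                 passage_start = as.integer(passage_start)),
            class = "sen_design_spec")
}

#' Generate a synthetic marker dataset from known parameters
#'
#' Simulates the model, evaluates the marker readouts at the design's
#' passage times, and adds independent Gaussian noise per replicate. Stain
#' channels are truncated to \[0, 100\] and PD to non-negative values.
#' Deterministic for a fixed `seed`.
#'
#' @param params A [model_parameters()].
#' @param mparams A [marker_params()].
#' @param design A [design_spec()].
#' @param seed Integer RNG seed.
#' @return A dataset data frame (columns `time_h`, `passage`, `marker`,
#'   `replicate`, `value`) with one row per replicate measurement.
#' @export
generate_dataset <- function(params, mparams, design = design_spec(),
                             seed = 1L) {
  stopifnot(inherits(design, "sen_design_spec"))
  times <- design$times
  traj <- simulate_population(params, t_end = max(times),
                              output_times = times)
  series <- marker_readouts(traj, mparams)
  clean <- marker_series_long(series)
  clean$value[clean$marker == "PD"] <-
    clean$value[clean$marker == "PD"] + design$pd_offset
  passages <- design$passage_start + seq_along(times) - 1L
  clean$passage <- passages[match(clean$time_h, times)]

  set.seed(as.integer(seed))
  rows <- lapply(seq_len(design$replicates), function(r) {
    noisy <- clean
    is_pd <- noisy$marker == "PD"
    sd_vec <- ifelse(is_pd, design$pd_sd, design$stain_sd)
    noisy$value <- noisy$value + stats::rnorm(nrow(noisy), 0, sd_vec)
    noisy$value[is_pd] <- pmax(noisy$value[is_pd], 0)
    noisy$value[!is_pd] <- pmin(pmax(noisy$value[!is_pd], 0), 100)
    noisy$replicate <- r
    noisy
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$passage, match(out$marker, sen_markers),
                   out$replicate), ]
  rownames(out) <- NULL
  out[, c("time_h", "passage", "marker", "replicate", "value")]
}
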