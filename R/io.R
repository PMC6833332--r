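#' Validate a marker dataset
#'
#' A dataset is a data frame with columns `time_h`, `passage`, `marker`,
#' `replicate`, `value`; one row per individual measurement. Stain markers
#' are percentages in \[0, 100\], PD values are non-negative doublings.
#'
#' @param dataset Data frame to validate.
#' @param require_two_times If `TRUE` (default), require at least two
#'   distinct time points per marker, the minimum for fitting.
#' @return The dataset, invisibly, with `value` numeric.
#' @export
validate_dataset <- function(dataset, require_two_times = TRUE) {
  need <- c("time_h", "passage", "marker", "replicate", "value")
  missing_cols <- setdiff(need, names(dataset))
  if (length(missing_cols)) {
    stop("dataset is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(dataset) == 0L) stop("dataset has no records", call. = FALSE)
  bad <- which(!(dataset$marker %in% sen_markers))
  if (length(bad)) {
    stop("unknown marker name(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (allowed: ", paste(sen_markers, collapse = ", "), ")",
         call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(dataset$value))
  bad <- which(is.na(v) | !is.finite(v))
  if (length(bad)) {
    stop("non-numeric or non-finite value at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  pct <- dataset$marker != "PD"
  bad <- which(pct & (v < 0 | v > 100))
  if (length(bad)) {
    stop("percentage marker outside [0, 100] at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(!pct & v < 0)
  if (length(bad)) {
    stop("negative PD value at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (anyNA(dataset$time_h) || any(!is.finite(dataset$time_h)) ||
      any(dataset$time_h < 0)) {
    stop("time_h must be finite and non-negative", call. = FALSE)
  }
  if (require_two_times) {
    nt <- tapply(dataset$time_h, dataset$marker, function(x)
      length(unique(x)))
    short <- names(nt)[nt < 2L]
    if (length(short)) {
      stop("marker(s) with fewer than 2 distinct time points: ",
           paste(short, collapse = ", "), call. = FALSE)
    }
  }
  dataset$value <- v
  invisible(dataset)
}

#' Read a marker dataset from CSV
#'
#' @param path CSV file with header
#'   `time_h,passage,marker,replicate,value` (any column order).
#' @param require_two_times Passed to [validate_dataset()].
#' @return Validated dataset data frame.
#' @export
read_dataset <- function(path, require_two_times = TRUE) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("could not parse '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  validate_dataset(df, require_two_times = require_two_times)
  df$value <- as.numeric(df$value)
  df[, c("time_h", "passage", "marker", "replicate", "value")]
}

#' Write a marker dataset to CSV
#' @param dataset A valid dataset data frame.
#' @param path Output path.
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset, require_two_times = FALSE)
  utils::write.csv(
    dataset[, c("time_h", "passage", "marker", "replicate", "value")],
    path, row.names = FALSE)
  invisible(path)
}

.param_keys <- c("mP0P1", "mPN1PN", "mP0G", "mPN1G", "mP0S", "mPN1S",
                 "mP0A", "mPN1A", "mGS", "mAD")
.frac_keys <- c("PgH2AX", "GKi67", "GgH2AX")

#' Read model + marker parameters from a flat JSON or YAML file
#'
#' Keys: the eight ladder endpoints `mP0P1, mPN1PN, mP0G, mPN1G, mP0S,
#' mPN1S, mP0A, mPN1A`, scalar rates `mGS`, `mAD` (all per hour), marker
#' fractions `PgH2AX`, `GKi67`, `GgH2AX`, and optionally `N` (default 50).
#' Ladders are rebuilt with [linear_rate_ladder()] from the endpoint pairs.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return List with elements `params` and `mparams`.
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  missing_keys <- setdiff(c(.param_keys, .frac_keys), names(vals))
  if (length(missing_keys)) {
    stop("parameter file '", path, "' is missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  N <- if (is.null(vals$N)) 50L else as.integer(vals$N)
  rates <- vapply(.param_keys, function(k) as.numeric(vals[[k]]), 0)
  if (anyNA(rates) || any(rates < 0)) {
    stop("rates must be non-negative numbers (h^-1)", call. = FALSE)
  }
  params <- params_from_endpoints(
    mP0P1 = rates[["mP0P1"]], mPN1PN = rates[["mPN1PN"]],
    mP0G = rates[["mP0G"]], mPN1G = rates[["mPN1G"]],
    mP0S = rates[["mP0S"]], mPN1S = rates[["mPN1S"]],
    mP0A = rates[["mP0A"]], mPN1A = rates[["mPN1A"]],
    m_GS = rates[["mGS"]], m_AD = rates[["mAD"]], N = N)
  mparams <- marker_params(frac_P_gH2AX = as.numeric(vals$PgH2AX),
                           frac_G_Ki67 = as.numeric(vals$GKi67),
                           frac_G_gH2AX = as.numeric(vals$GgH2AX))
  list(params = params, mparams = mparams)
}

#' Write model + marker parameters to a flat JSON file
#' @param params A [model_parameters()].
#' @param mparams A [marker_params()].
#' @param path Output `.json` path.
#' @export
write_params <- function(params, mparams, path) {
  N <- params$N
  vals <- list(
    mP0P1 = params$div_ladder[1L], mPN1PN = params$div_ladder[N],
    mP0G = params$arr_ladder[1L], mPN1G = params$arr_ladder[N],
    mP0S = params$sen_ladder[1L], mPN1S = params$sen_ladder[N],
    mP0A = params$apo_ladder[1L], mPN1A = params$apo_ladder[N],
    mGS = params$m_GS, mAD = params$m_AD,
    PgH2AX = mparams$frac_P_gH2AX, GKi67 = mparams$frac_G_Ki67,
    GgH2AX = mparams$frac_G_gH2AX, N = N)
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
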