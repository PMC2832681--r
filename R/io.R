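# Measurement CSV reader/writer and JSON report serialization.
#
# CSV contract: header `time,<channel1>,<channel2>,...`; one row per sample
# instant; an empty cell marks an unobserved (time, channel) pair. A sidecar
# JSON (same path + ".json") records the noise covariance R, the generator
# seed and schedule provenance, so a series round-trips losslessly.

#' Write a measurement series to CSV (+ sidecar JSON)
#'
#' @param data a [measurement_series()].
#' @param path CSV output path; the sidecar is written to `paste0(path, ".json")`.
#' @param sidecar write the sidecar (default `TRUE`).
#' @returns `path`, invisibly.
#' @export
write_measurements <- function(data, path, sidecar = TRUE) {
  stopifnot(inherits(data, "measurement_series"))
  df <- data.frame(time = data$times, data$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (sidecar) {
    jsonlite::write_json(
      list(format = "hekf-measurements", version = 1L,
           channels = data$channels, R = data$R, seed = data$seed,
           n_times = length(data$times)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a measurement series from CSV
#'
#' @param path CSV path (see [write_measurements()] for the format).
#' @param R per-channel noise variances; if `NULL`, taken from the sidecar
#'   JSON next to `path`.
#' @returns a [measurement_series()].
#' @export
read_measurements <- function(path, R = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = "")
  if (!"time" %in% names(raw) || ncol(raw) < 2)
    stop("read_measurements: need a `time` column plus >= 1 channel column")
  conv <- function(col, nm) {
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(out))
    if (length(bad))
      stop(sprintf("read_measurements: non-numeric value in column '%s' at data row %d",
                   nm, bad[1]))
    out
  }
  times <- conv(raw$time, "time")
  if (anyNA(times)) stop("read_measurements: missing time value")
  if (anyDuplicated(times))
    stop("read_measurements: duplicate time at data row ",
         which(duplicated(times))[1])
  if (any(diff(times) <= 0))
    stop("read_measurements: times not strictly increasing at data row ",
         which(diff(times) <= 0)[1] + 1)
  chans <- setdiff(names(raw), "time")
  values <- sapply(chans, function(nm) conv(raw[[nm]], nm))
  if (!is.matrix(values)) values <- matrix(values, nrow = length(times))
  seed <- NULL
  if (is.null(R)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("read_measurements: no R supplied and no sidecar found at ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    R <- as.numeric(meta$R)
    if (!is.null(meta$seed)) seed <- meta$seed
    if (!is.null(meta$channels) && !identical(as.character(meta$channels), chans))
      stop("read_measurements: sidecar channels disagree with the CSV header")
  }
  measurement_series(times, values, R, channels = chans, seed = seed)
}

# ---- JSON reports -----------------------------------------------------------

report_of_test <- function(rep) {
  if (is.null(rep)) return(NULL)
  list(gamma = rep$gamma, df = rep$df, overall_pass = rep$overall_pass,
       channels = rep$table)
}

#' Convert a result object to a serializable report list
#'
#' Methods exist for filter trajectories, variance-test reports, pipeline
#' results and model-selection reports. The report carries every table-style
#' chi-squared summary (point estimates, intervals, true variances, verdicts)
#' so text tables can be regenerated from the JSON alone.
#'
#' @param x result object.
#' @param ... further arguments; `covariances = TRUE` adds per-step covariance
#'   diagonals for trajectories.
#' @returns a plain list ready for [jsonlite::write_json].
#' @export
as_report <- function(x, ...) UseMethod("as_report")

#' @export
as_report.variance_test_report <- function(x, ...) {
  c(list(type = "variance_test"), report_of_test(x))
}

#' @export
as_report.filter_trajectory <- function(x, covariances = FALSE, ...) {
  steps <- lapply(x$steps, function(s) {
    out <- list(k = s$k, t = s$t, x_constrained = s$x_constrained,
                innovation = s$innovation)
    if (covariances) out$P_post_diag <- diag(s$P_post)
    out
  })
  list(type = "filter_trajectory", diverged = isTRUE(x$diverged),
       final_params = as.list(x$final_params), steps = steps)
}

#' @export
as_report.pipeline_result <- function(x, covariances = FALSE, ...) {
  list(type = "pipeline", schema_version = 1L,
       stage = x$stage, gamma = x$gamma,
       estimate = as.list(x$estimate),
       test_hekf = report_of_test(x$test_hekf),
       test_final = report_of_test(x$test_final),
       refinement = if (is.null(x$refined)) NULL else
         list(cost = x$refined$cost, start_cost = x$refined$start_cost,
              iterations = x$refined$iterations,
              converged = x$refined$converged),
       hekf = as_report(x$hekf, covariances = covariances))
}

#' @export
as_report.model_selection_report <- function(x, ...) {
  list(type = "model_selection", schema_version = 1L, gamma = x$gamma,
       retained = x$retained, rejected = x$rejected,
       diverged = x$diverged,
       best = if (is.na(x$best)) NULL else x$best,
       scores = as.list(x$scores),
       reports = lapply(x$reports, report_of_test))
}

#' Write a result object to a JSON report file
#'
#' @param x a supported result object (see [as_report()]).
#' @param path output path.
#' @param ... passed to [as_report()].
#' @returns `path`, invisibly.
#' @export
write_report <- function(x, path, ...) {
  jsonlite::write_json(as_report(x, ...), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
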