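# Discrete-time measurement container shared by the filter, the chi-squared
# test, the refinement stage and the CSV reader/writer.

#' Construct a measurement series
#'
#' Discrete-time, possibly non-uniformly sampled, possibly per-channel
#' incomplete observations of a process, together with the (known) diagonal
#' measurement-noise covariance R that anchors the chi-squared variance test.
#'
#' @param times strictly increasing sample instants.
#' @param values numeric matrix, `length(times)` rows, one column per channel;
#'   `NA` marks an unobserved (time, channel) pair. Every row must have at
#'   least one observed channel.
#' @param R diagonal noise covariance: a matrix, or the vector of per-channel
#'   variances `sigma_j^2`.
#' @param channels optional channel names (default `y1, y2, ...`).
#' @param seed generator seed, recorded when the series is synthetic.
#' @returns object of class `measurement_series` with fields `times`, `values`,
#'   `mask` (logical matrix of observed pairs), `R` (variance vector),
#'   `channels`, `n_channels`, `seed`.
#' @export
measurement_series <- function(times, values, R, channels = NULL, seed = NULL) {
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (length(times) < 1)
    stop("measurement_series: need at least one time point")
  if (length(times) != nrow(values))
    stop("measurement_series: length(times) must equal nrow(values)")
  if (any(diff(times) <= 0))
    stop("measurement_series: times must be strictly increasing")
  if (is.matrix(R) && nrow(R) > 1) {
    if (max(abs(R - diag(diag(R)))) > 0)
      stop("measurement_series: R must be diagonal")
    R <- diag(R)
  }
  R <- as.numeric(R)
  if (length(R) == 1) R <- rep(R, ncol(values))
  if (length(R) != ncol(values))
    stop("measurement_series: R must have one variance per channel")
  mask <- !is.na(values)
  if (any(rowSums(mask) == 0))
    stop("measurement_series: every time point needs at least one observed channel")
  if (is.null(channels)) channels <- paste0("y", seq_len(ncol(values)))
  colnames(values) <- channels
  structure(list(times = times, values = values, mask = mask, R = R,
                 channels = channels, n_channels = ncol(values), seed = seed),
            class = "measurement_series")
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf(
    "<measurement_series: %d time points, %d channel(s) [%s], %d observations>\n",
    length(x$times), x$n_channels, paste(x$channels, collapse = ", "),
    sum(x$mask)))
  invisible(x)
}
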