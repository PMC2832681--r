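# A posteriori chi-squared identifiability test.
#
# If an estimate is good, the residuals between the data and the predicted
# outputs are samples of the measurement noise, whose statistics are known.
# Each channel's noise variance is point-estimated from the zero-mean sum of
# squares of the residuals; a chi-squared interval estimate at confidence
# gamma either contains the known true variance (estimate accepted) or not
# (estimate rejected with confidence gamma). The test is estimator-agnostic:
# predictions may come from the model solution at an estimated parameter set
# or from the filter's state estimates.

#' Build per-channel residual samples
#'
#' `e_j(t_k) = y_j(t_k) - yhat_j(t_k)` over the observed (time, channel) pairs
#' only. Under a correct estimate these are zero-mean Gaussian samples with
#' the known noise variances.
#'
#' @param data a [measurement_series()].
#' @param predicted numeric matrix of predicted outputs, same shape as
#'   `data$values`; must be non-`NA` at every observed pair.
#' @returns object of class `residual_set`: list with `residuals` (list of
#'   per-channel numeric vectors), `n` (per-channel sample counts), `channels`.
#' @export
residual_set <- function(data, predicted) {
  stopifnot(inherits(data, "measurement_series"))
  predicted <- as.matrix(predicted)
  if (!all(dim(predicted) == dim(data$values)))
    stop("residual_set: predicted must match the shape of the data values")
  if (any(is.na(predicted[data$mask])))
    stop("residual_set: missing prediction at an observed (time, channel) pair")
  res <- lapply(seq_len(data$n_channels), function(j) {
    obs <- data$mask[, j]
    data$values[obs, j] - predicted[obs, j]
  })
  structure(list(residuals = res, n = vapply(res, length, integer(1)),
                 channels = data$channels),
            class = "residual_set")
}

#' Point estimate of a channel's noise variance
#'
#' Zero-mean form `S_j = (1/N_j) sum_k e_j(t_k)^2`: the noise mean is known to
#' be zero by assumption, so no sample mean is subtracted and no degree of
#' freedom is spent on it.
#'
#' @param res a [residual_set()].
#' @param j channel index.
#' @returns nonnegative scalar `S_j`.
#' @export
variance_point_estimate <- function(res, j) {
  stopifnot(inherits(res, "residual_set"))
  if (res$n[j] < 2)
    stop("variance_point_estimate: need at least 2 residual samples")
  mean(res$residuals[[j]]^2)
}

#' Chi-squared interval estimate of a noise variance
#'
#' With `N S / sigma^2` chi-squared distributed on `N` degrees of freedom, the
#' true variance lies in `[N S / q_{(1+gamma)/2}, N S / q_{(1-gamma)/2}]` with
#' probability `gamma`, where `q_p` is the `p`-th chi-squared quantile.
#'
#' @param S variance point estimate ([variance_point_estimate()]).
#' @param N residual sample count for the channel.
#' @param gamma confidence coefficient in (0, 1); common values 0.9, 0.95,
#'   0.997.
#' @param df degrees of freedom convention: `"N"` (default; zero-mean residuals,
#'   no mean estimated) or `"N-1"`.
#' @returns numeric `c(lo, hi)`; degenerate `c(0, 0)` when `S = 0`.
#' @export
variance_interval <- function(S, N, gamma, df = c("N", "N-1")) {
  if (!(gamma > 0 && gamma < 1))
    stop("variance_interval: gamma must be in (0, 1)")
  if (N < 2) stop("variance_interval: need N >= 2")
  if (S < 0) stop("variance_interval: S must be nonnegative")
  df <- match.arg(df)
  nu <- if (df == "N") N else N - 1
  if (S == 0) return(c(0, 0))
  c(lo = N * S / stats::qchisq((1 + gamma) / 2, nu),
    hi = N * S / stats::qchisq((1 - gamma) / 2, nu))
}

#' Chi-squared variance test
#'
#' For each channel, forms the residual-variance point estimate and interval
#' estimate and checks whether the known true variance `sigma_j^2` (the
#' diagonal of R) lies inside the interval. The estimate behind `predicted` is
#' accepted only if every channel passes.
#'
#' @param data a [measurement_series()].
#' @param predicted predicted-output matrix (see [residual_set()]).
#' @param R true noise variances (matrix or per-channel vector); defaults to
#'   the series' own R. All entries must be strictly positive.
#' @param gamma confidence coefficient (default 0.95).
#' @param df degrees-of-freedom convention, see [variance_interval()].
#' @returns object of class `variance_test_report`: data frame `table` (per
#'   channel: `channel`, `n`, `point`, `lo`, `hi`, `true_variance`, `pass`,
#'   `degenerate`), `gamma`, `overall_pass`, plus the residual means
#'   (`mean_error`) for reporting.
#' @export
chi2_test <- function(data, predicted, R = NULL, gamma = 0.95,
                      df = c("N", "N-1")) {
  df <- match.arg(df)
  if (is.null(R)) R <- data$R
  if (is.matrix(R)) R <- diag(R)
  R <- as.numeric(R)
  if (length(R) != data$n_channels)
    stop("chi2_test: R must have one variance per channel")
  if (any(R <= 0)) stop("chi2_test: R entries must be strictly positive")
  res <- residual_set(data, predicted)
  rows <- lapply(seq_len(data$n_channels), function(j) {
    S <- variance_point_estimate(res, j)
    ci <- variance_interval(S, res$n[j], gamma, df)
    data.frame(channel = data$channels[j], n = res$n[j],
               mean_error = mean(res$residuals[[j]]),
               point = S, lo = ci[1], hi = ci[2], true_variance = R[j],
               pass = (R[j] >= ci[1] & R[j] <= ci[2]),
               degenerate = (S == 0))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, gamma = gamma, df = df,
                 overall_pass = all(tab$pass), residuals = res),
            class = "variance_test_report")
}

#' @export
print.variance_test_report <- function(x, ...) {
  cat(sprintf("Chi-squared variance test (gamma = %g, df = %s)\n",
              x$gamma, x$df))
  tab <- x$table
  for (j in seq_len(nrow(tab))) {
    cat(sprintf(
      "  %-8s N=%-3d point=%-12.6g interval=[%.6g, %.6g]  true=%-10.6g %s%s\n",
      tab$channel[j], tab$n[j], tab$point[j], tab$lo[j], tab$hi[j],
      tab$true_variance[j], if (tab$pass[j]) "pass" else "FAIL",
      if (tab$degenerate[j]) " (degenerate: S = 0)" else ""))
  }
  cat(sprintf("  overall: %s\n", if (x$overall_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Predicted outputs from the model solution at a parameter set
#'
#' Solves the model ODE at `theta` from `x0` and evaluates the output map at
#' the sample times -- the default prediction source for the chi-squared test
#' ("the solution corresponding to the estimate").
#'
#' @param ext an [extend_state()] result.
#' @param theta free-parameter values (named or in `ext$free_params` order).
#' @param x0 initial dynamic state.
#' @param data a [measurement_series()].
#' @param t0 time at which `x0` holds (default 0, the input-step instant).
#' @param rtol,atol integrator tolerances.
#' @param max_steps integrator step budget.
#' @returns matrix of predicted outputs (`NA` at unobserved pairs untouched:
#'   all channels are returned; masking is applied downstream).
#' @export
predict_outputs_model <- function(ext, theta, x0, data, t0 = 0,
                                  rtol = 1e-8, atol = 1e-10,
                                  max_steps = 1e5) {
  stopifnot(inherits(ext, "extended_model"))
  nf <- length(ext$free_params)
  theta <- as.numeric(theta)
  if (length(theta) != nf)
    stop("predict_outputs_model: theta must have one value per free parameter")
  if (data$times[1] < t0)
    stop("predict_outputs_model: data precede t0")
  # integrate the base system only: the parameter components are constants
  base <- ext$base
  p <- ext$assemble_params(theta)
  f <- function(t, x) base$rhs(x, base$input(t), t, p)
  states <- ode_at(f, x0, t0 = t0, times = data$times,
                   rtol = rtol, atol = atol, max_steps = max_steps)
  ext_states <- cbind(states, matrix(theta, nrow(states), length(theta),
                                     byrow = TRUE))
  raw <- vapply(seq_along(data$times),
                function(k) ext$output$h(ext_states[k, ], k),
                numeric(data$n_channels))
  out <- t(matrix(raw, nrow = data$n_channels))
  colnames(out) <- data$channels
  out
}

#' Predicted outputs from filter state estimates
#'
#' Evaluates the output map at the constrained a posteriori state estimates --
#' the prediction source used for model selection, which tolerates unknown
#' initial conditions.
#'
#' @param traj a [run_hekf()] result covering every time point of `data`.
#' @param data a [measurement_series()].
#' @returns matrix of predicted outputs.
#' @export
predict_outputs_filter <- function(traj, data) {
  stopifnot(inherits(traj, "filter_trajectory"))
  if (length(traj$steps) < length(data$times))
    stop("predict_outputs_filter: trajectory does not cover all time points")
  ext <- traj$ext
  raw <- vapply(seq_along(data$times),
                function(k) ext$output$h(traj$steps[[k]]$x_constrained, k),
                numeric(data$n_channels))
  out <- t(matrix(raw, nrow = data$n_channels))
  colnames(out) <- data$channels
  out
}
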