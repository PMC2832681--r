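# Constrained hybrid extended Kalman filter.
#
# Continuous-time prediction: the extended-state ODE and the differential
# Lyapunov equation P' = F P + P F' + Q are integrated jointly as one stacked
# system, with F = d f_ext / d x_ext evaluated along the evolving state
# estimate. Discrete-time correction: linearized Kalman gain and measurement
# update on the observed channels. If a linear constraint set is configured,
# any infeasible a posteriori estimate is replaced by the solution of a
# strictly convex QP (the constrained maximum of the conditional Gaussian
# log-density).

divergence_error <- function(msg, k) {
  structure(
    class = c("hekf_divergence", "error", "condition"),
    list(message = sprintf("%s (at step %d)", msg, k), call = NULL, step = k))
}

#' Filter configuration
#'
#' @param x0_ext initial extended-state estimate (expected value of the initial
#'   state; the parameter components hold the initial parameter guesses).
#' @param P0 initial error covariance (symmetric positive definite matrix, or
#'   its diagonal as a vector). Default: `diag(pmax(x0_ext^2, 1))`, i.e.
#'   squared initial-guess magnitudes floored at 1 -- a deliberate package
#'   choice, since no canonical value exists.
#' @param R measurement-noise covariance: matrix or per-channel variance
#'   vector. If `NULL`, the measurement series' own R is used.
#' @param t0 filter start time (default 0; the first sample may be later).
#' @param rtol,atol integrator tolerances for the prediction step.
#' @param averaging_window number of trailing a posteriori estimates averaged
#'   into the final parameter estimate (default 10).
#' @param joseph use the Joseph-form covariance update (more robust to
#'   round-off) instead of the plain `(I - K H) P` form. Default `FALSE`.
#' @param max_cond innovation-covariance condition number above which the
#'   filter declares divergence (default 1e12).
#' @param max_steps integrator step budget per prediction interval.
#' @returns object of class `filter_config`.
#' @export
filter_config <- function(x0_ext, P0 = NULL, R = NULL, t0 = 0,
                          rtol = 1e-6, atol = 1e-8, averaging_window = 10,
                          joseph = FALSE, max_cond = 1e12, max_steps = 1e5) {
  x0_ext <- as.numeric(x0_ext)
  n <- length(x0_ext)
  if (is.null(P0)) P0 <- diag(pmax(x0_ext^2, 1), n)
  if (!is.matrix(P0)) P0 <- diag(as.numeric(P0), n)
  if (!all(dim(P0) == n)) stop("filter_config: P0 dimension mismatch")
  if (max(abs(P0 - t(P0))) > 1e-12)
    stop("filter_config: P0 must be symmetric (to 1e-12)")
  if (any(eigen(P0, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("filter_config: P0 must be positive definite")
  if (!is.null(R)) {
    if (is.matrix(R)) R <- diag(R)
    R <- as.numeric(R)
    if (any(R <= 0)) stop("filter_config: R diagonal must be strictly positive")
  }
  structure(list(x0_ext = x0_ext, P0 = P0, R = R, t0 = t0,
                 rtol = rtol, atol = atol,
                 averaging_window = as.integer(averaging_window),
                 joseph = joseph, max_cond = max_cond, max_steps = max_steps),
            class = "filter_config")
}

symmetrize <- function(P) (P + t(P)) / 2

# Symmetrize and floor tiny negative eigenvalues at zero. Eigenvalues more
# negative than a small multiple of the matrix scale indicate genuine numerical
# breakdown and raise a divergence error.
sanitize_cov <- function(P, k = 0L) {
  P <- symmetrize(P)
  e <- eigen(P, symmetric = TRUE)
  scale <- max(1, max(abs(e$values)))
  if (min(e$values) < -1e-8 * scale)
    stop(divergence_error("covariance lost positive semidefiniteness", k))
  if (min(e$values) < 0) {
    v <- pmax(e$values, 0)
    P <- symmetrize(e$vectors %*% (v * t(e$vectors)))
  }
  P
}

#' Time update (prediction)
#'
#' Propagates the extended state through the model ODE and the error
#' covariance through the differential Lyapunov equation
#' `P' = F P + P F' + Q` over `[t_prev, t_next]`, as one stacked system.
#'
#' @param x_prev,P_prev previous a posteriori (constrained) estimate and
#'   covariance.
#' @param ext an [extend_state()] result.
#' @param t_prev,t_next interval endpoints, `t_next > t_prev`.
#' @param cfg a [filter_config()].
#' @returns list with `x_prior` and `P_prior` (symmetrized).
#' @export
time_update <- function(x_prev, P_prev, ext, t_prev, t_next, cfg) {
  n <- ext$n_ext
  if (t_next <= t_prev) stop("time_update: t_next must exceed t_prev")
  Q <- ext$Q
  rhs_stacked <- function(t, z) {
    x <- z[seq_len(n)]
    P <- matrix(z[-seq_len(n)], n, n)
    F <- rhs_jacobian(ext, x, t)
    dP <- F %*% P + P %*% t(F) + Q
    c(ext$rhs_ext(t, x), as.numeric(dP))
  }
  sol <- ode_solve(rhs_stacked, c(x_prev, as.numeric(P_prev)),
                   t_prev, t_next, rtol = cfg$rtol, atol = cfg$atol,
                   max_steps = cfg$max_steps)
  z <- sol$y1
  list(x_prior = z[seq_len(n)],
       P_prior = symmetrize(matrix(z[-seq_len(n)], n, n)))
}

#' Kalman gain
#'
#' `K = P- H' (H P- H' + R_k)^{-1}`, computed through a linear solve (no
#' explicit inverse). `R_k` is the diagonal block of R for the channels
#' observed at the current step.
#'
#' @param P_prior a priori covariance.
#' @param H output Jacobian, rows = observed channels.
#' @param R_k observed-channel noise covariance (matrix or variance vector).
#' @param max_cond condition-number threshold for declaring divergence.
#' @param k step index used in error messages.
#' @returns gain matrix (`n_ext x` observed channels).
#' @export
kalman_gain <- function(P_prior, H, R_k, max_cond = 1e12, k = 0L) {
  if (!is.matrix(R_k)) R_k <- diag(as.numeric(R_k), nrow(H))
  S <- symmetrize(H %*% P_prior %*% t(H) + R_k)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > max_cond)
    stop(divergence_error("innovation covariance is numerically singular", k))
  t(solve(S, H %*% P_prior))
}

#' Measurement update (correction)
#'
#' Incorporates the observed channels at step `k` into the a priori estimate:
#' innovation `y_k - h_k(x-)`, state update `x+ = x- + K nu`, covariance update
#' `P+ = (I - K H) P-` (or the Joseph form).
#'
#' @param x_prior,P_prior a priori estimate and covariance.
#' @param y_k observed values (observed channels only, in mask order).
#' @param ext an [extend_state()] result.
#' @param k time index.
#' @param cfg a [filter_config()].
#' @param mask logical observation mask at `k` (defaults to the output map's).
#' @returns list with `x_post`, `P_post`, `gain`, `innovation`.
#' @export
measurement_update <- function(x_prior, P_prior, y_k, ext, k, cfg,
                               mask = NULL) {
  om <- ext$output
  if (is.null(mask)) mask <- om$mask(k)
  if (!any(mask)) stop("measurement_update: no observed channel at step ", k)
  R <- if (!is.null(cfg$R)) cfg$R else
    stop("measurement_update: no R available in the configuration")
  H <- output_jacobian(ext, k, x_prior, mask)
  K <- kalman_gain(P_prior, H, R[mask], max_cond = cfg$max_cond, k = k)
  innovation <- as.numeric(y_k) - output_eval(om, k, x_prior, mask)
  x_post <- as.numeric(x_prior + K %*% innovation)
  n <- length(x_prior)
  IKH <- diag(n) - K %*% H
  P_post <- if (isTRUE(cfg$joseph)) {
    IKH %*% P_prior %*% t(IKH) + K %*% diag(R[mask], nrow(H)) %*% t(K)
  } else {
    IKH %*% P_prior
  }
  P_post <- sanitize_cov(P_post, k)
  list(x_post = x_post, P_post = P_post, gain = K, innovation = innovation)
}

#' Project an estimate onto a linear constraint set
#'
#' If the a posteriori estimate violates the constraints it is replaced by the
#' minimizer of `(x - x+)' P+^{-1} (x - x+)` subject to them -- the maximum of
#' the conditional Gaussian density under the constraints -- via a strictly
#' convex quadratic program (Goldfarb-Idnani dual active-set method). A
#' feasible estimate is returned unchanged (bitwise).
#'
#' @param x_post a posteriori estimate.
#' @param P_post a posteriori covariance (regularized by `+1e-12 I` before
#'   inversion if needed).
#' @param constraints a [linear_constraints()] object, or `NULL`.
#' @param tol feasibility tolerance.
#' @returns constrained estimate (numeric vector, feasible to `tol`).
#' @export
constrain_estimate <- function(x_post, P_post, constraints, tol = 1e-9) {
  if (is.null(constraints) || constraints_satisfied(constraints, x_post, tol))
    return(x_post)
  n <- length(x_post)
  Preg <- symmetrize(P_post)
  sol <- NULL
  ridge <- 0
  for (attempt in 1:4) {
    W <- tryCatch(solve(Preg + ridge * diag(n)), error = function(e) NULL)
    if (!is.null(W)) {
      W <- symmetrize(W)
      sol <- tryCatch(
        quadprog::solve.QP(Dmat = W, dvec = as.numeric(W %*% x_post),
                           Amat = t(constraints$G), bvec = constraints$h),
        error = function(e) NULL)
    }
    if (!is.null(sol)) break
    ridge <- if (ridge == 0) 1e-12 * max(1, mean(diag(Preg))) else ridge * 1e3
  }
  if (is.null(sol))
    stop("constrain_estimate: quadratic program could not be solved")
  x_c <- sol$solution
  if (!constraints_satisfied(constraints, x_c, tol = 1e-7))
    stop("constrain_estimate: projected estimate is not feasible")
  # snap tiny active-set residuals so downstream feasibility checks at 1e-9 hold
  viol <- constraints$h - constraints$G %*% x_c
  if (any(viol > 0)) {
    act <- which(abs(viol) < 1e-7)
    if (length(act)) {
      Ga <- constraints$G[act, , drop = FALSE]
      x_snap <- tryCatch(
        x_c + as.numeric(t(Ga) %*% solve(Ga %*% t(Ga),
                                         (constraints$h - constraints$G %*% x_c)[act])),
        error = function(e) x_c)
      if (constraints_satisfied(constraints, x_snap, tol)) x_c <- x_snap
    }
  }
  x_c
}

#' Run the constrained hybrid extended Kalman filter
#'
#' Executes the full recursion on a measurement series: initialization from
#' the configured `x0_ext`/`P0`, then per sample time a prediction (model ODE
#' plus Lyapunov covariance ODE), gain computation, measurement correction on
#' the observed channels, and constraint check/projection. The final parameter
#' estimate is the mean of the parameter components over the last
#' `averaging_window` constrained a posteriori estimates.
#'
#' Divergence (non-finite values, ill-conditioned innovation covariance,
#' integration failure) is flagged, not raised: the partial trajectory is
#' retained with `diverged = TRUE`.
#'
#' @param ext an [extend_state()] result.
#' @param data a [measurement_series()].
#' @param cfg a [filter_config()].
#' @returns object of class `filter_trajectory`: list with `steps` (per-step
#'   records with `k`, `t`, `x_prior`, `x_post`, `x_constrained`, `P_prior`,
#'   `P_post`, `gain`, `innovation`), `final_params` (named vector, `NULL` if
#'   no free parameters or if diverged too early), `final_state`, `diverged`.
#' @export
run_hekf <- function(ext, data, cfg) {
  stopifnot(inherits(ext, "extended_model"),
            inherits(data, "measurement_series"),
            inherits(cfg, "filter_config"))
  if (length(cfg$x0_ext) != ext$n_ext)
    stop("run_hekf: x0_ext length must equal the extended dimension")
  if (any(diff(data$times) <= 0))
    stop("run_hekf: measurement times must be strictly increasing")
  N <- length(data$times)
  if (cfg$averaging_window > N)
    stop("run_hekf: averaging_window exceeds the number of measurement steps")
  if (is.null(cfg$R)) cfg$R <- data$R
  if (length(cfg$R) != data$n_channels)
    stop("run_hekf: R inconsistent with the number of channels")

  x_c <- constrain_estimate(cfg$x0_ext, cfg$P0, ext$constraints)
  P <- cfg$P0
  t_prev <- cfg$t0
  if (data$times[1] < t_prev)
    stop("run_hekf: first measurement precedes the filter start time")

  steps <- vector("list", N)
  diverged <- FALSE
  for (k in seq_len(N)) {
    t_k <- data$times[k]
    res <- tryCatch({
      if (t_k > t_prev) {
        tu <- time_update(x_c, P, ext, t_prev, t_k, cfg)
      } else {
        tu <- list(x_prior = x_c, P_prior = P)
      }
      mask <- data$mask[k, ]
      y_k <- data$values[k, mask]
      mu <- measurement_update(tu$x_prior, tu$P_prior, y_k, ext, k, cfg, mask)
      if (!all(is.finite(mu$x_post)))
        stop(divergence_error("non-finite state estimate", k))
      xc <- constrain_estimate(mu$x_post, mu$P_post, ext$constraints)
      list(k = k, t = t_k, x_prior = tu$x_prior, P_prior = tu$P_prior,
           x_post = mu$x_post, P_post = mu$P_post,
           x_constrained = xc, gain = mu$gain, innovation = mu$innovation)
    },
    hekf_divergence = function(e) e,
    hekf_integration_error = function(e) e)
    if (inherits(res, "condition")) {
      diverged <- TRUE
      attr(diverged, "message") <- conditionMessage(res)
      steps <- steps[seq_len(k - 1)]
      break
    }
    steps[[k]] <- res
    x_c <- res$x_constrained
    P <- res$P_post
    t_prev <- t_k
  }

  traj <- structure(list(steps = steps, ext = ext, diverged = diverged,
                         final_params = NULL, final_state = NULL),
                    class = "filter_trajectory")
  if (length(steps)) {
    traj$final_state <- steps[[length(steps)]]$x_constrained
    nf <- length(ext$free_params)
    if (nf > 0 && length(steps) >= cfg$averaging_window)
      traj$final_params <- final_estimate(traj, cfg$averaging_window)
  }
  traj
}

#' Final parameter estimate by trailing-window averaging
#'
#' Arithmetic mean of the parameter components of the last `window`
#' constrained a posteriori estimates -- the filter oscillates around the true
#' values once converged, so a single number is extracted by averaging.
#'
#' @param traj a [run_hekf()] result.
#' @param window number of trailing steps to average (default 10).
#' @returns named numeric vector, one entry per free parameter.
#' @export
final_estimate <- function(traj, window = 10) {
  stopifnot(inherits(traj, "filter_trajectory"))
  ns <- length(traj$steps)
  if (window < 1 || window > ns)
    stop("final_estimate: window must be between 1 and the number of steps")
  ext <- traj$ext
  nf <- length(ext$free_params)
  if (nf == 0) stop("final_estimate: model has no free parameters")
  idx <- ext$n_states + seq_len(nf)
  tail_steps <- traj$steps[(ns - window + 1):ns]
  est <- rowMeans(matrix(vapply(tail_steps,
                                function(s) s$x_constrained[idx],
                                numeric(nf)), nrow = nf))
  names(est) <- ext$free_params
  est
}

#' @export
print.filter_trajectory <- function(x, ...) {
  cat(sprintf("<filter_trajectory: %d steps%s>\n", length(x$steps),
              if (isTRUE(x$diverged)) ", DIVERGED" else ""))
  if (!is.null(x$final_params)) {
    cat("final parameter estimate (trailing-window average):\n")
    print(x$final_params)
  }
  invisible(x)
}
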