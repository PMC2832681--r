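# Core model representation: ODE models, output maps, linear constraint sets,
# state extension, Jacobians and trajectory simulation.
#
# Extended-state ordering convention used throughout the package: dynamic
# states first, then free parameters in declaration order. Every covariance
# matrix (P0, Q, filter covariances) follows this ordering.

#' Define an ODE process model
#'
#' A model is the right-hand side `dx/dt = f(x, u, t, theta)` of a system of
#' ordinary differential equations together with parameter metadata, an
#' optional external input `u(t)` (e.g. a temperature regime) and optional
#' analytic Jacobians. States typically hold concentrations or molecule
#' counts.
#'
#' @param n_states number of dynamic state variables.
#' @param rhs function `(x, u, t, params)` returning the length-`n_states`
#'   derivative; `params` is a named numeric vector covering `param_names`.
#' @param param_names character vector of parameter identifiers (ordered).
#' @param params named numeric vector of default parameter values (must cover
#'   `param_names`).
#' @param input function of time returning the input value; defaults to a
#'   constant zero input. Step inputs should be piecewise-constant callables.
#' @param x0 default initial state (optional).
#' @param jacobian_x optional analytic state Jacobian `(x, u, t, params)` ->
#'   `n_states x n_states` matrix.
#' @param jacobian_theta optional analytic parameter Jacobian
#'   `(x, u, t, params, free)` -> `n_states x length(free)` matrix, columns in
#'   the order of `free`.
#' @param name model identifier used in reports.
#' @returns object of class `ode_model`.
#' @export
ode_model <- function(n_states, rhs, param_names, params,
                      input = function(t) 0, x0 = NULL,
                      jacobian_x = NULL, jacobian_theta = NULL,
                      name = "model") {
  stopifnot(is.function(rhs), n_states >= 1)
  param_names <- as.character(param_names)
  params <- unlist(params)
  if (!all(param_names %in% names(params)))
    stop("ode_model: `params` must provide a value for every parameter name")
  params <- params[param_names]
  if (!is.null(x0) && length(x0) != n_states)
    stop("ode_model: x0 length must equal n_states")
  structure(list(n_states = as.integer(n_states), rhs = rhs,
                 param_names = param_names, params = params, input = input,
                 x0 = x0, jacobian_x = jacobian_x,
                 jacobian_theta = jacobian_theta, name = name),
            class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("<ode_model '%s': %d states, %d parameters>\n",
              x$name, x$n_states, length(x$param_names)))
  invisible(x)
}

#' Define an output map
#'
#' Relates the (extended) state to the measurable channels. `h` always returns
#' the full channel vector; the per-time-index `mask` says which channels are
#' actually observed at index `k`, allowing measurements of different species
#' at different times. Observed rows are extracted by [output_eval()] /
#' [output_jacobian()].
#'
#' @param n_channels number of measurable quantities.
#' @param h function `(x_ext, k)` returning a length-`n_channels` vector.
#' @param mask function `(k)` returning a logical vector of length
#'   `n_channels`; defaults to all channels observed at every index.
#' @param jacobian optional analytic Jacobian `(x_ext, k)` ->
#'   `n_channels x n_ext` matrix.
#' @returns object of class `output_map`.
#' @export
output_map <- function(n_channels, h, mask = NULL, jacobian = NULL) {
  stopifnot(is.function(h), n_channels >= 1)
  if (is.null(mask)) mask <- function(k) rep(TRUE, n_channels)
  structure(list(n_channels = as.integer(n_channels), h = h, mask = mask,
                 jacobian = jacobian),
            class = "output_map")
}

#' Output map selecting a subset of state components
#'
#' The common case where each channel reads one state component directly.
#'
#' @param state_idx integer indices of the measured components.
#' @param n_ext extended-state dimension (for the analytic Jacobian).
#' @returns an [output_map()].
#' @export
state_output_map <- function(state_idx, n_ext) {
  state_idx <- as.integer(state_idx)
  p <- length(state_idx)
  H <- matrix(0, p, n_ext)
  H[cbind(seq_len(p), state_idx)] <- 1
  output_map(p,
             h = function(x_ext, k) x_ext[state_idx],
             jacobian = function(x_ext, k) H)
}

#' Evaluate the observed channels of an output map
#'
#' @param omap an [output_map()].
#' @param k time index.
#' @param x_ext extended state vector.
#' @param mask optional logical vector overriding `omap$mask(k)` (used to
#'   honour the observation pattern of a measurement series).
#' @returns numeric vector of the observed channel values at `k`.
#' @export
output_eval <- function(omap, k, x_ext, mask = NULL) {
  if (is.null(mask)) mask <- omap$mask(k)
  if (!any(mask)) stop("output_eval: no observed channel at index ", k)
  full <- omap$h(x_ext, k)
  full[mask]
}

# ---- linear constraints -----------------------------------------------------

#' Define a set of linear inequality constraints
#'
#' Constraints of the form `A x (sense) b`, row-wise, over the extended state.
#' Feasibility of the region is checked at construction by solving a strictly
#' convex feasibility program (minimum-norm point subject to the constraints).
#'
#' @param A coefficient matrix (rows = constraints, cols = extended states).
#' @param b right-hand-side vector, `length(b) == nrow(A)`.
#' @param sense per-row direction, each `">="` or `"<="` (recycled).
#' @returns object of class `linear_constraints`.
#' @export
linear_constraints <- function(A, b, sense = ">=") {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (nrow(A) != length(b))
    stop("linear_constraints: nrow(A) must equal length(b)")
  sense <- rep(sense, length.out = nrow(A))
  if (!all(sense %in% c(">=", "<=")))
    stop("linear_constraints: sense entries must be '>=' or '<='")
  # normalize to G x >= h
  flip <- sense == "<="
  G <- A; G[flip, ] <- -G[flip, , drop = FALSE]
  h <- b; h[flip] <- -h[flip]
  cs <- structure(list(A = A, b = b, sense = sense, G = G, h = h,
                       n = ncol(A)),
                  class = "linear_constraints")
  feas <- tryCatch(
    quadprog::solve.QP(Dmat = diag(ncol(A)), dvec = rep(0, ncol(A)),
                       Amat = t(G), bvec = h)$solution,
    error = function(e) NULL)
  if (is.null(feas) || !constraints_satisfied(cs, feas, tol = 1e-7))
    stop("linear_constraints: constraint set is infeasible")
  cs
}

#' Nonnegativity constraints on all components
#'
#' The package default for biochemical fixtures: states and parameters are
#' molecule counts, concentrations or positive rates.
#'
#' @param n extended-state dimension.
#' @returns a [linear_constraints()] object encoding `x_i >= 0` for all `i`.
#' @export
nonneg_constraints <- function(n) {
  linear_constraints(diag(n), rep(0, n), ">=")
}

#' Check a point against a constraint set
#'
#' @param cs a [linear_constraints()] object (or `NULL` for "no constraints").
#' @param x point to check.
#' @param tol feasibility tolerance.
#' @returns logical.
#' @export
constraints_satisfied <- function(cs, x, tol = 1e-9) {
  if (is.null(cs)) return(TRUE)
  all(cs$G %*% x - cs$h >= -tol)
}

# ---- state extension --------------------------------------------------------

#' Extend a model's state with its unknown parameters
#'
#' Converts parameter estimation into state estimation: the extended state is
#' `[x ; theta_free]`, the free parameters evolve with derivative identically
#' zero, and the base right-hand side reads its free parameters from the
#' extended state.
#'
#' @param model an [ode_model()].
#' @param free_params character vector of parameter names to estimate; may be
#'   empty (pure state estimation).
#' @param fixed_values named values for the remaining parameters; defaults to
#'   the model's default values.
#' @param output an [output_map()] over the extended state.
#' @param Q diagonal process-noise covariance of size
#'   `n_states + length(free_params)`; either a matrix or the diagonal vector.
#'   Larger entries express lower confidence in the model equations.
#' @param constraints optional [linear_constraints()] over the extended state.
#' @returns object of class `extended_model` with fields `n_ext`, `rhs_ext`
#'   (`function(t, x_ext)`), `jac_ext` (analytic, or `NULL`), `output`, `Q`,
#'   `constraints`, `free_params`, `base`.
#' @export
extend_state <- function(model, free_params, fixed_values = NULL,
                         output, Q, constraints = NULL) {
  stopifnot(inherits(model, "ode_model"), inherits(output, "output_map"))
  free_params <- as.character(free_params)
  unknown <- setdiff(free_params, model$param_names)
  if (length(unknown))
    stop("extend_state: unknown parameter name(s): ",
         paste(unknown, collapse = ", "))
  fixed_names <- setdiff(model$param_names, free_params)
  if (is.null(fixed_values)) {
    fixed_values <- model$params[fixed_names]
  } else {
    fixed_values <- unlist(fixed_values)
    if (!setequal(names(fixed_values), fixed_names))
      stop("extend_state: fixed_values must cover exactly the non-free parameters")
    fixed_values <- fixed_values[fixed_names]
  }
  n <- model$n_states
  nf <- length(free_params)
  n_ext <- n + nf

  if (is.matrix(Q)) {
    if (!all(dim(Q) == n_ext))
      stop("extend_state: Q dimension mismatch (need ", n_ext, ")")
    if (max(abs(Q - diag(diag(Q)))) > 0)
      stop("extend_state: Q must be diagonal")
    qd <- diag(Q)
  } else {
    qd <- as.numeric(Q)
    if (length(qd) == 1) qd <- rep(qd, n_ext)
    if (length(qd) != n_ext)
      stop("extend_state: Q dimension mismatch (need ", n_ext, ")")
  }
  if (any(qd < 0)) stop("extend_state: Q diagonal must be nonnegative")
  Q <- diag(qd, n_ext)

  if (!is.null(constraints) && constraints$n != n_ext)
    stop("extend_state: constraint matrix has wrong number of columns")

  template <- model$params
  template[fixed_names] <- fixed_values
  free_idx <- match(free_params, model$param_names)
  assemble <- function(theta_free) {
    p <- template
    if (nf) p[free_idx] <- theta_free
    p
  }

  rhs_ext <- function(t, x_ext) {
    x <- x_ext[seq_len(n)]
    p <- assemble(x_ext[n + seq_len(nf)])
    c(model$rhs(x, model$input(t), t, p), rep(0, nf))
  }

  jac_ext <- NULL
  if (!is.null(model$jacobian_x)) {
    jac_ext <- function(t, x_ext) {
      x <- x_ext[seq_len(n)]
      u <- model$input(t)
      p <- assemble(x_ext[n + seq_len(nf)])
      J <- matrix(0, n_ext, n_ext)
      J[seq_len(n), seq_len(n)] <- model$jacobian_x(x, u, t, p)
      if (nf) {
        Jt <- if (!is.null(model$jacobian_theta)) {
          model$jacobian_theta(x, u, t, p, free_params)
        } else {
          fd_jacobian(function(th) model$rhs(x, u, t, assemble(th)),
                      x_ext[n + seq_len(nf)])
        }
        J[seq_len(n), n + seq_len(nf)] <- Jt
      }
      J
    }
  }

  structure(list(base = model, free_params = free_params,
                 fixed_params = fixed_values, n_states = n, n_ext = n_ext,
                 output = output, Q = Q, constraints = constraints,
                 rhs_ext = rhs_ext, jac_ext = jac_ext,
                 assemble_params = assemble),
            class = "extended_model")
}

#' @export
print.extended_model <- function(x, ...) {
  cat(sprintf("<extended_model on '%s': %d states + %d free parameters (%s)>\n",
              x$base$name, x$n_states, length(x$free_params),
              if (length(x$free_params)) paste(x$free_params, collapse = ", ")
              else "none"))
  invisible(x)
}

# ---- Jacobians --------------------------------------------------------------

# Central finite-difference Jacobian, relative step sqrt(eps) * max(|x_i|, 1).
fd_jacobian <- function(fun, x, rel_step = sqrt(.Machine$double.eps)) {
  f0 <- fun(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    h <- rel_step * max(abs(x[i]), 1)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    fp <- fun(xp); fm <- fun(xm)
    if (!all(is.finite(fp)) || !all(is.finite(fm)))
      stop("fd_jacobian: function not evaluable at perturbation of component ", i)
    J[, i] <- (fp - fm) / (2 * h)
  }
  J
}

#' Jacobian of the extended right-hand side
#'
#' `d f_ext / d x_ext` at a point. Uses the model's analytic Jacobian when
#' supplied, otherwise central finite differences with per-component relative
#' step `sqrt(machine eps) * max(|x_i|, 1)`. Parameter rows are identically
#' zero by construction.
#'
#' @param ext an [extend_state()] result.
#' @param x_ext extended state vector.
#' @param t time.
#' @returns `n_ext x n_ext` matrix.
#' @export
rhs_jacobian <- function(ext, x_ext, t) {
  stopifnot(inherits(ext, "extended_model"), length(x_ext) == ext$n_ext)
  if (!is.null(ext$jac_ext)) return(ext$jac_ext(t, x_ext))
  J <- fd_jacobian(function(z) ext$rhs_ext(t, z), x_ext)
  nf <- ext$n_ext - ext$n_states
  if (nf) J[ext$n_states + seq_len(nf), ] <- 0  # exact: parameter rows are zero
  J
}

#' Jacobian of the output map at a time index
#'
#' Rows are the observed channels at index `k`, in mask order; columns span the
#' extended state. Analytic if the output map carries a Jacobian, else central
#' finite differences.
#'
#' @param ext an [extend_state()] result.
#' @param k time index.
#' @param x_ext extended state vector.
#' @param mask optional logical observation mask overriding the output map's.
#' @returns `(observed channels) x n_ext` matrix.
#' @export
output_jacobian <- function(ext, k, x_ext, mask = NULL) {
  om <- ext$output
  if (is.null(mask)) mask <- om$mask(k)
  if (!any(mask)) stop("output_jacobian: no observed channel at index ", k)
  if (!is.null(om$jacobian)) {
    H <- om$jacobian(x_ext, k)
  } else {
    H <- fd_jacobian(function(z) om$h(z, k), x_ext)
  }
  H[mask, , drop = FALSE]
}

# ---- simulation -------------------------------------------------------------

#' Simulate an extended model
#'
#' Deterministic dense solution of the extended ODE over a time span. Free
#' parameter components stay constant along the trajectory (zero derivative)
#' to within integrator tolerance.
#'
#' @param ext an [extend_state()] result.
#' @param x0_ext initial extended state `[x0 ; theta_free]`.
#' @param t_span numeric length-2 vector `c(t0, t1)`, `t1 > t0`.
#' @param rtol,atol integrator tolerances.
#' @returns an `hekf_ode_solution` (see [ode_solve()]); query with `$interp()`.
#' @export
simulate_model <- function(ext, x0_ext, t_span, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(ext, "extended_model"), length(x0_ext) == ext$n_ext,
            length(t_span) == 2)
  ode_solve(ext$rhs_ext, x0_ext, t_span[1], t_span[2],
            rtol = rtol, atol = atol)
}
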