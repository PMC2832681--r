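# Standard in-silico experiment setups for the fixture models. These bundle
# the generator design (schedule, noise), the extension (free parameters,
# process noise, constraints) and the filter configuration (initial guesses,
# P0) so tests, the acceptance script and the CLI all run the same designs.

#' Heat-shock estimation experiment
#'
#' Generates synthetic measurements of chaperones and sigma-32 on the 22-point
#' dense-then-sparse schedule and assembles the extended model and filter
#' configuration for estimating `free` parameters. Defaults reproduce the
#' small-parameter-space design: two free parameters (`k_syn`, `k_seq`, both
#' with true value 3), initial guesses of 1, nonnegativity constraints on the
#' whole extended state, and additive Gaussian noise with variances
#' `R = c(50, 0.02)` (roughly 5% of the post-shock steady-state outputs).
#'
#' @param seed generator seed.
#' @param free names of parameters to estimate.
#' @param guess initial parameter guesses (same length/order as `free`).
#' @param R per-channel noise variances.
#' @param q_states,q_params process-noise diagonal entries for state and
#'   parameter components.
#' @param P0_params prior variance of the parameter components (state
#'   components use the squared-magnitude default).
#' @param rtol,atol filter integrator tolerances.
#' @returns list with `model`, `ext`, `data`, `cfg`, `truth` (named true
#'   values of the free parameters) and `x0` (true initial state).
#' @export
heat_shock_experiment <- function(seed = NULL,
                                  free = c("k_syn", "k_seq"),
                                  guess = rep(1, length(free)),
                                  R = c(50, 0.02),
                                  q_states = 1e-6, q_params = 0.05,
                                  P0_params = 4,
                                  rtol = 1e-6, atol = 1e-8) {
  model <- heat_shock_model()
  times <- heat_shock_schedule()
  data <- simulate_measurements(model, times = times, observed = c(1L, 2L),
                                R = R, seed = seed)
  n_ext <- model$n_states + length(free)
  ext <- extend_state(model, free,
                      output = state_output_map(c(1L, 2L), n_ext),
                      Q = c(rep(q_states, length.out = model$n_states),
                            rep(q_params, length.out = length(free))),
                      constraints = nonneg_constraints(n_ext))
  x0_ext <- c(model$x0, guess)
  P0 <- diag(c(pmax(model$x0^2, 1),
               rep(P0_params, length.out = length(free))), n_ext)
  cfg <- filter_config(x0_ext, P0 = P0, R = R, t0 = 0,
                       rtol = rtol, atol = atol)
  list(model = model, ext = ext, data = data, cfg = cfg,
       truth = model$params[free], x0 = model$x0)
}

#' Heat-shock large-parameter-space experiment
#'
#' Six free parameters on the same measurements as the small case. With six
#' unknowns the extended system is effectively unobservable from two channels
#' and 22 points, so the raw filter estimate typically fails the chi-squared
#' test and the moment-matching refinement stage is exercised. Initial guesses
#' are offset from the truth by `guess_factor`; per-parameter process noise
#' and prior spread scale with the guess magnitudes (rates span four orders of
#' magnitude, so absolute values would be meaningless).
#'
#' @param seed generator seed.
#' @param free the six estimated parameters.
#' @param guess_factor multiplicative offset of the initial guesses.
#' @returns as [heat_shock_experiment()].
#' @export
heat_shock_large_experiment <- function(seed = NULL,
                                        free = c("k_syn", "k_dD", "eta_s1",
                                                 "k_seq", "k_d0", "k_fold"),
                                        guess_factor = 1.5) {
  truth <- heat_shock_model()$params[free]
  guess <- unname(truth) * guess_factor
  heat_shock_experiment(seed = seed, free = free, guess = guess,
                        q_params = (0.05 * guess)^2,
                        P0_params = (0.5 * guess)^2)
}

#' Heat-shock model-selection experiment
#'
#' Data are generated from the spike model ([heat_shock_model()]); the two
#' candidates are the generating model and the no-spike variant, both with all
#' parameters known (pure state estimation) and both started from the same
#' deliberately offset initial state estimate, emulating unknown initial
#' conditions.
#'
#' @param seed generator seed.
#' @param R per-channel noise variances.
#' @param q_states process-noise diagonal for the (3) state components.
#' @param x0_offset multiplicative offset applied to the true initial state to
#'   form both candidates' initial estimates.
#' @returns list with `candidates` (list of [candidate()]), `data`.
#' @export
heat_shock_selection_experiment <- function(seed = NULL, R = c(50, 0.02),
                                            q_states = 1e-4,
                                            x0_offset = 1.5) {
  m1 <- heat_shock_model()
  m2 <- heat_shock_nospike_model()
  data <- simulate_measurements(m1, times = heat_shock_schedule(),
                                observed = c(1L, 2L), R = R, seed = seed)
  mk <- function(model) {
    ext <- extend_state(model, character(0),
                        output = state_output_map(c(1L, 2L), model$n_states),
                        Q = rep(q_states, model$n_states),
                        constraints = nonneg_constraints(model$n_states))
    cfg <- filter_config(m1$x0 * x0_offset, R = R, t0 = 0)
    candidate(model$name, ext, cfg)
  }
  list(candidates = list(mk(m1), mk(m2)), data = data)
}

#' Repressilator estimation experiment
#'
#' Thirty equally spaced measurements of the three mRNA channels over the
#' default horizon, with relative Gaussian noise (variance = `noise_frac`
#' times each channel's signal mean). All 18 rates are free by default.
#'
#' @param seed generator seed.
#' @param n_points number of equally spaced samples (default 30).
#' @param horizon sampling horizon (default 30 time units, about three
#'   periods of the default limit cycle).
#' @param noise_frac relative noise level (default 0.05).
#' @param free names of free parameters (default: all 18).
#' @param guess_factor multiplicative offset of the initial parameter guesses
#'   from the truth (default 1.5).
#' @param q_states process-noise diagonal for the state components.
#' @param q_params process-noise diagonal for the parameter components;
#'   default `(0.05 * guess)^2`, i.e. relative to each rate's magnitude, since
#'   the 18 rates span orders of magnitude.
#' @param P0_params prior variance of the parameter components; default
#'   `(0.5 * guess)^2` for the same reason.
#' @param rtol,atol filter integrator tolerances.
#' @returns list with `model`, `ext`, `data`, `cfg`, `truth`, `x0`.
#' @export
repressilator_experiment <- function(seed = NULL, n_points = 30, horizon = 30,
                                     noise_frac = 0.05,
                                     free = names(repressilator_model()$params),
                                     guess_factor = 1.5,
                                     q_states = 1e-6, q_params = NULL,
                                     P0_params = NULL,
                                     rtol = 1e-6, atol = 1e-8) {
  model <- repressilator_model()
  times <- uniform_schedule(n_points, horizon)
  data <- simulate_measurements(model, times = times, observed = 1:3,
                                noise_frac = noise_frac, seed = seed)
  n_ext <- model$n_states + length(free)
  guess <- unname(model$params[free]) * guess_factor
  if (is.null(q_params)) q_params <- (0.05 * guess)^2
  ext <- extend_state(model, free,
                      output = state_output_map(1:3, n_ext),
                      Q = c(rep(q_states, length.out = model$n_states),
                            rep(q_params, length.out = length(free))),
                      constraints = nonneg_constraints(n_ext))
  x0_ext <- c(model$x0, guess)
  if (is.null(P0_params)) P0_params <- (0.5 * guess)^2
  P0 <- diag(c(pmax(model$x0^2, 1), rep(P0_params, length.out = length(free))),
             n_ext)
  cfg <- filter_config(x0_ext, P0 = P0, R = data$R, t0 = 0,
                       rtol = rtol, atol = atol)
  list(model = model, ext = ext, data = data, cfg = cfg,
       truth = model$params[free], x0 = model$x0)
}
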