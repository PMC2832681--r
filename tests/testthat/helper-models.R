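# Small models and oracles shared across test files. Everything here is built
# in code at test time; no stored fixtures.

# scalar exponential decay x' = -a x, one free parameter `a`
scalar_decay_model <- function(a = 0.5) {
  ode_model(1, function(x, u, t, p) -p[["a"]] * x,
            param_names = "a", params = c(a = a),
            x0 = 1, name = "scalar_decay")
}

scalar_decay_ext <- function(a = 0.5, q = c(0, 0)) {
  m <- scalar_decay_model(a)
  extend_state(m, "a", output = state_output_map(1L, 2L), Q = q)
}

# linear time-invariant system x' = A x, all parameters fixed
lti_model <- function(A) {
  n <- nrow(A)
  ode_model(n, function(x, u, t, p) as.numeric(A %*% x),
            param_names = "unused", params = c(unused = 0),
            x0 = rep(1, n),
            jacobian_x = function(x, u, t, p) A,
            name = "lti")
}

lti_ext <- function(A, observed = seq_len(nrow(A)), Q = 0) {
  m <- lti_model(A)
  extend_state(m, character(0),
               output = state_output_map(observed, m$n_states),
               Q = rep(Q, length.out = m$n_states))
}

# random symmetric positive definite matrix
random_spd <- function(n) {
  M <- matrix(rnorm(n * n), n)
  crossprod(M) + diag(n) * 0.5
}

# textbook discrete-time Kalman filter oracle for x' = A x observed linearly:
# exact discretization via the van Loan augmented-matrix exponential.
discrete_kf_oracle <- function(A, Q, H, R, x0, P0, times, ys, t0 = 0) {
  n <- nrow(A)
  x <- x0; P <- P0; t_prev <- t0
  out <- vector("list", length(times))
  for (k in seq_along(times)) {
    dt <- times[k] - t_prev
    M <- rbind(cbind(-A, Q), cbind(matrix(0, n, n), t(A))) * dt
    E <- as.matrix(Matrix::expm(M))
    Phi <- t(E[(n + 1):(2 * n), (n + 1):(2 * n)])
    Qd <- Phi %*% E[1:n, (n + 1):(2 * n)]
    x <- as.numeric(Phi %*% x)
    P <- Phi %*% P %*% t(Phi) + Qd
    S <- H %*% P %*% t(H) + R
    K <- t(solve(S, H %*% P))
    x <- x + as.numeric(K %*% (ys[k, ] - H %*% x))
    P <- (diag(n) - K %*% H) %*% P
    out[[k]] <- list(x = x, P = P)
    t_prev <- times[k]
  }
  out
}
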