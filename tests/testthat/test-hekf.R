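test_that("time update: constant dynamics and scalar Lyapunov closed form", {
  # f == 0, Q = q I: x unchanged, P grows linearly
  m <- ode_model(2, function(x, u, t, p) c(0, 0), "unused", c(unused = 0))
  ext <- extend_state(m, character(0), output = state_output_map(1:2, 2),
                      Q = c(0.3, 0.3))
  cfg <- filter_config(c(1, 2), P0 = diag(2), R = c(1, 1),
                       rtol = 1e-10, atol = 1e-12)
  tu <- time_update(c(1, 2), diag(2), ext, 0, 2, cfg)
  expect_equal(tu$x_prior, c(1, 2), tolerance = 1e-10)
  expect_equal(tu$P_prior, diag(2) + 0.3 * 2 * diag(2), tolerance = 1e-8)

  # scalar x' = a x: P(D) = e^{2aD} P0 + q (e^{2aD} - 1) / (2a)
  a <- -1; D <- 0.5; P0 <- 1; q <- 0.2
  m1 <- ode_model(1, function(x, u, t, p) a * x, "unused", c(unused = 0),
                  jacobian_x = function(x, u, t, p) matrix(a))
  ext1 <- extend_state(m1, character(0), output = state_output_map(1, 1),
                       Q = q)
  cfg1 <- filter_config(1, P0 = matrix(P0), R = 1,
                        rtol = 1e-10, atol = 1e-12)
  tu1 <- time_update(1, matrix(P0), ext1, 0, D, cfg1)
  P_exact <- exp(2 * a * D) * P0 + q * (exp(2 * a * D) - 1) / (2 * a)
  expect_equal(tu1$P_prior[1, 1], P_exact, tolerance = 1e-8)
  expect_equal(tu1$x_prior, exp(a * D), tolerance = 1e-8)
})

test_that("time update with Q = 0 matches the matrix-exponential propagation", {
  A <- matrix(c(-0.5, 0.2, 0.1, -0.3), 2)
  ext <- lti_ext(A, Q = 0)
  P0 <- random_spd(2)
  cfg <- filter_config(c(1, -1), P0 = P0, R = c(1, 1),
                       rtol = 1e-10, atol = 1e-12)
  tu <- time_update(c(1, -1), P0, ext, 0, 0.8, cfg)
  Phi <- as.matrix(Matrix::expm(A * 0.8))
  expect_equal(tu$P_prior, Phi %*% P0 %*% t(Phi), tolerance = 1e-8)
})

test_that("kalman gain: scalar value, distrust limit, defining identity", {
  expect_equal(kalman_gain(matrix(1), matrix(1), 1)[1, 1], 0.5)
  expect_lt(abs(kalman_gain(matrix(1), matrix(1), 1e12)[1, 1]), 1e-10)
  set.seed(3)
  P <- random_spd(5)
  H <- matrix(rnorm(10), 2, 5)
  R <- diag(c(0.5, 2))
  K <- kalman_gain(P, H, R)
  expect_equal(K %*% (H %*% P %*% t(H) + R), P %*% t(H), tolerance = 1e-10)
})

test_that("measurement update: zero innovation, scalar arithmetic, Loewner order", {
  ext <- lti_ext(matrix(-1))
  cfg <- filter_config(0, P0 = matrix(1), R = 1)
  mu <- measurement_update(2, matrix(1), y_k = 2, ext, 1, cfg)
  expect_equal(mu$x_post, 2)          # y == h(x_prior)
  expect_equal(mu$innovation, 0)

  mu <- measurement_update(0, matrix(1), y_k = 2, ext, 1, cfg)
  expect_equal(mu$gain[1, 1], 0.5)
  expect_equal(mu$x_post, 1)
  expect_equal(mu$P_post[1, 1], 0.5)
})

test_that("joint masked update matches the conjugate-Gaussian posterior", {
  # linear model, Gaussian prior: the Kalman update IS the Bayes posterior
  A <- diag(-0.1, 3)
  ext <- lti_ext(A, observed = c(1, 3))
  cfg <- filter_config(rep(0, 3), P0 = diag(3), R = c(0.5, 1.5))
  set.seed(5)
  P <- random_spd(3)
  x <- rnorm(3)
  y <- rnorm(2)
  mu <- measurement_update(x, P, y, ext, 1, cfg)
  H <- rbind(c(1, 0, 0), c(0, 0, 1))
  Rm <- diag(c(0.5, 1.5))
  Ppost <- solve(solve(P) + t(H) %*% solve(Rm) %*% H)
  xpost <- as.numeric(Ppost %*% (solve(P) %*% x + t(H) %*% solve(Rm) %*% y))
  expect_equal(mu$x_post, xpost, tolerance = 1e-8)
  expect_equal(mu$P_post, (Ppost + t(Ppost)) / 2, tolerance = 1e-8)
})

test_that("sequential nonlinear updates differ from the joint update", {
  # relinearization between channels makes sequential != joint for nonlinear h
  m <- heat_shock_model()
  om2 <- output_map(2, h = function(x, k) c(x[1]^2 / (50 + x[1]),
                                            x[2]^2 / (1 + x[2])))
  ext <- extend_state(m, character(0), output = om2, Q = rep(0, 3))
  cfg <- filter_config(m$x0, R = c(1, 0.01))
  x <- c(12, 0.3, 18)
  # cross-correlated prior: the first update moves x2, so h2 relinearizes
  P <- matrix(c(4, 0.3, 0.5,
                0.3, 0.04, 0.1,
                0.5, 0.1, 9), 3, 3)
  y <- c(2.5, 0.1)
  joint <- measurement_update(x, P, y, ext, 1, cfg)
  s1 <- measurement_update(x, P, y[1], ext, 1, cfg, mask = c(TRUE, FALSE))
  s2 <- measurement_update(s1$x_post, s1$P_post, y[2], ext, 1, cfg,
                           mask = c(FALSE, TRUE))
  expect_gt(max(abs(s2$x_post - joint$x_post)), 1e-8)
})

test_that("full filter matches the discrete Kalman filter on an LTI system", {
  A <- matrix(c(-0.4, 0.1, 0.2, -0.6), 2)
  q <- 0.05
  ext <- lti_ext(A, observed = 1L, Q = q)
  times <- c(0.3, 0.7, 1.2, 1.6, 2.3, 2.9, 3.3, 4.1)
  set.seed(9)
  ys <- matrix(rnorm(length(times), sd = 2), ncol = 1)
  data <- measurement_series(times, ys, R = 0.4)
  x0 <- c(1, -1); P0 <- diag(c(2, 1))
  cfg <- filter_config(x0, P0 = P0, R = 0.4, rtol = 1e-11, atol = 1e-13,
                       averaging_window = 1)
  traj <- run_hekf(ext, data, cfg)
  oracle <- discrete_kf_oracle(A, diag(q, 2), matrix(c(1, 0), 1), matrix(0.4),
                               x0, P0, times, ys)
  for (k in seq_along(times)) {
    expect_equal(traj$steps[[k]]$x_post, oracle[[k]]$x, tolerance = 1e-8)
    expect_equal(traj$steps[[k]]$P_post,
                 (oracle[[k]]$P + t(oracle[[k]]$P)) / 2, tolerance = 1e-8)
  }
})

test_that("filter invariants: covariance order, constraints, noise-free innovations", {
  e <- heat_shock_experiment(seed = 123)
  traj <- run_hekf(e$ext, e$data, e$cfg)
  expect_false(traj$diverged)
  for (s in traj$steps) {
    dP <- s$P_prior - s$P_post
    expect_gt(min(eigen((dP + t(dP)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-10)
    expect_true(constraints_satisfied(e$ext$constraints, s$x_constrained,
                                      tol = 1e-9))
  }

  # without constraints, x_constrained is bitwise x_post
  ext_u <- e$ext; ext_u$constraints <- NULL
  traj_u <- run_hekf(ext_u, e$data, e$cfg)
  for (s in traj_u$steps) expect_identical(s$x_constrained, s$x_post)

  # noise-free data from the true extension, true start: innovations vanish
  m <- heat_shock_model()
  data0 <- simulate_measurements(m, times = heat_shock_schedule(),
                                 observed = c(1, 2), R = c(0, 0))
  data0$R <- c(1e-4, 1e-4)  # filter needs positive R
  cfg0 <- filter_config(c(m$x0, 3, 3), R = data0$R,
                        rtol = 1e-8, atol = 1e-10)
  ext <- extend_state(m, c("k_syn", "k_seq"),
                      output = state_output_map(c(1, 2), 5),
                      Q = rep(0, 5))
  traj0 <- run_hekf(ext, data0, cfg0)
  expect_lt(max(abs(unlist(lapply(traj0$steps, `[[`, "innovation")))), 1e-4)
})

test_that("noise-free linear observable system: state recovered to 1e-3", {
  A <- matrix(c(-0.3, 0.1, 0.05, -0.2), 2)
  ext <- lti_ext(A, observed = 1:2, Q = 1e-10)
  x_true <- c(2, -1)
  times <- seq(0.5, 10, by = 0.5)
  f <- function(t, x) as.numeric(A %*% x)
  Y <- ode_at(f, x_true, 0, times)
  data <- measurement_series(times, Y, R = c(1e-10, 1e-10))
  cfg <- filter_config(c(0, 0), P0 = diag(2), R = c(1e-8, 1e-8),
                       rtol = 1e-10, atol = 1e-12, averaging_window = 1)
  traj <- run_hekf(ext, data, cfg)
  xT <- ode_at(f, x_true, 0, max(times))[1, ]
  expect_equal(traj$final_state, xT, tolerance = 1e-3)
})

test_that("final_estimate: averaging window semantics and errors", {
  e <- heat_shock_experiment(seed = 1)
  traj <- run_hekf(e$ext, e$data, e$cfg)
  # hand-build the expected averages from the stored steps
  idx <- 4:5
  tail10 <- vapply(traj$steps[13:22], function(s) s$x_constrained[idx],
                   numeric(2))
  expect_equal(unname(final_estimate(traj, 10)), rowMeans(tail10))
  all22 <- vapply(traj$steps, function(s) s$x_constrained[idx], numeric(2))
  expect_equal(unname(final_estimate(traj, 22)), rowMeans(all22))
  expect_error(final_estimate(traj, 23), "window")
  expect_error(final_estimate(traj, 0), "window")

  # constant parameter track: synthetic trajectory object
  fake <- structure(list(
    steps = lapply(1:20, function(k)
      list(x_constrained = c(0, k))),
    ext = list(n_states = 1, free_params = "a"),
    diverged = FALSE), class = "filter_trajectory")
  expect_equal(unname(final_estimate(fake, 10)), mean(11:20))  # 15.5
  expect_equal(unname(final_estimate(fake, 20)), mean(1:20))

  # averaging window larger than the series is rejected up front
  cfg_bad <- e$cfg; cfg_bad$averaging_window <- 23L
  expect_error(run_hekf(e$ext, e$data, cfg_bad), "averaging_window")
})

test_that("filter configuration validation", {
  expect_error(filter_config(c(0, 0), P0 = matrix(c(1, 0.2, 0, 1), 2)),
               "symmetric")
  expect_error(filter_config(c(0, 0), P0 = diag(c(1, -1))),
               "positive definite")
  expect_error(filter_config(0, R = 0), "strictly positive")
  e <- heat_shock_experiment(seed = 1)
  bad_data <- e$data
  bad_data$times[2] <- bad_data$times[1]  # force non-monotone
  expect_error(run_hekf(e$ext, bad_data, e$cfg), "strictly increasing")
})
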