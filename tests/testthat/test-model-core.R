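test_that("state extension zeroes parameter derivatives and preserves the base RHS", {
  # scalar: x' = -a x extended with a; at (x, a) = (2, 0.5) -> (-1, 0)
  ext <- scalar_decay_ext()
  expect_equal(ext$rhs_ext(0, c(2, 0.5)), c(-1, 0))

  # heat shock with two free parameters: 5 extended states, last 2 rates zero
  m <- heat_shock_model()
  ext <- extend_state(m, c("k_syn", "k_seq"),
                      output = state_output_map(c(1, 2), 5), Q = rep(0, 5))
  expect_equal(ext$n_ext, 5)
  set.seed(42)
  for (i in 1:20) {
    z <- c(runif(3, 0.1, 100), runif(2, 0.1, 5))
    d <- ext$rhs_ext(runif(1, 0, 100), z)
    expect_identical(d[4:5], c(0, 0))
    p <- m$params; p[c("k_syn", "k_seq")] <- z[4:5]
    expect_equal(d[1:3], m$rhs(z[1:3], 1, 1, p))
  }

  # empty extension: identical to the base RHS
  ext0 <- extend_state(m, character(0),
                       output = state_output_map(c(1, 2), 3), Q = rep(0, 3))
  z <- c(10, 1, 20)
  expect_equal(ext0$rhs_ext(1, z), m$rhs(z, 1, 1, m$params))
})

test_that("extension rejects bad configuration", {
  m <- heat_shock_model()
  om <- state_output_map(c(1, 2), 5)
  expect_error(extend_state(m, c("nope"), output = om, Q = rep(0, 4)),
               "unknown parameter")
  expect_error(extend_state(m, c("k_syn", "k_seq"), output = om,
                            Q = rep(0, 4)), "dimension mismatch")
  expect_error(extend_state(m, c("k_syn", "k_seq"), output = om,
                            Q = c(rep(0, 4), -1)), "nonnegative")
})

test_that("rhs_jacobian: hand cases and parameter-row structure", {
  ext <- scalar_decay_ext()
  expect_equal(rhs_jacobian(ext, c(2, 0.5), 0),
               matrix(c(-0.5, 0, -2, 0), 2), tolerance = 1e-8)

  # linear system with no free parameters: Jacobian = A everywhere (analytic
  # path) and by finite differences (FD path)
  A <- matrix(c(-1, 0.3, 0.2, -0.7), 2)
  ext <- lti_ext(A)
  expect_equal(rhs_jacobian(ext, c(3, -2), 1), A)
  ext_fd <- ext; ext_fd$jac_ext <- NULL
  expect_equal(rhs_jacobian(ext_fd, c(3, -2), 1), A, tolerance = 1e-7)
})

test_that("finite-difference and analytic Jacobians agree along fixture trajectories", {
  # the fixtures' hand-coded Jacobians serve as the independent symbolic oracle
  for (build in list(
    function() {
      m <- heat_shock_model()
      extend_state(m, c("k_syn", "k_dD", "k_seq", "K_u"),
                   output = state_output_map(c(1, 2), 7), Q = rep(0, 7))
    },
    function() {
      m <- repressilator_model()
      extend_state(m, names(m$params),
                   output = state_output_map(1:3, 24), Q = rep(0, 24))
    })) {
    ext <- build()
    nf <- length(ext$free_params)
    x0e <- c(ext$base$x0, unname(ext$base$params[ext$free_params]))
    sol <- simulate_model(ext, x0e, c(0, 40), rtol = 1e-8, atol = 1e-10)
    set.seed(7)
    tq <- sort(runif(100, 0.5, 40))
    Xq <- sol$interp(tq)
    ext_fd <- ext; ext_fd$jac_ext <- NULL
    for (i in seq(1, 100, by = 7)) {
      Ja <- rhs_jacobian(ext, Xq[i, ], tq[i])
      Jf <- rhs_jacobian(ext_fd, Xq[i, ], tq[i])
      expect_equal(Jf, Ja, tolerance = 1e-5)
      expect_true(all(Ja[(ext$n_states + 1):ext$n_ext, ] == 0))
    }
  }
})

test_that("output_jacobian: selection, summation and nonlinear readouts", {
  ext <- lti_ext(diag(-1, 2))
  # identity on the first 2 of 5 extended states
  m <- heat_shock_model()
  ext5 <- extend_state(m, c("k_syn", "k_seq"),
                       output = state_output_map(c(1, 2), 5), Q = rep(0, 5))
  H <- output_jacobian(ext5, 1, c(10, 1, 20, 3, 3))
  expect_equal(H, rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0)))

  # total-protein readout: sum of two states -> single row (1, 1, 0, ...)
  om_sum <- output_map(1, h = function(x, k) x[1] + x[2])
  ext_sum <- extend_state(m, c("k_syn", "k_seq"), output = om_sum,
                          Q = rep(0, 5))
  expect_equal(output_jacobian(ext_sum, 1, c(10, 1, 20, 3, 3)),
               matrix(c(1, 1, 0, 0, 0), 1), tolerance = 1e-7)

  # Hill-type readout: FD against the hand derivative
  om_hill <- output_map(1, h = function(x, k) x[1]^2 / (4 + x[1]^2))
  ext_h <- extend_state(m, character(0), output = om_hill, Q = rep(0, 3))
  x <- c(3, 1, 2)
  dh <- 2 * x[1] * 4 / (4 + x[1]^2)^2
  expect_equal(output_jacobian(ext_h, 1, x),
               matrix(c(dh, 0, 0), 1), tolerance = 1e-6)

  # masked-empty index is an error
  om_mask <- output_map(2, h = function(x, k) x[1:2],
                        mask = function(k) c(FALSE, FALSE))
  ext_m <- extend_state(m, character(0), output = om_mask, Q = rep(0, 3))
  expect_error(output_jacobian(ext_m, 1, c(1, 1, 1)), "no observed channel")
})

test_that("simulation: closed form, parameter constancy, extension idempotence", {
  ext <- scalar_decay_ext(a = 1)
  sol <- simulate_model(ext, c(1, 1), c(0, 1))
  expect_equal(sol$y1[1], exp(-1), tolerance = 1e-8)
  expect_lt(abs(sol$y1[2] - 1), 10 * 1e-10)  # zero-derivative component

  # extended vs base trajectories coincide when free params are at the truth
  m <- heat_shock_model()
  ext <- extend_state(m, c("k_syn", "k_seq"),
                      output = state_output_map(c(1, 2), 5), Q = rep(0, 5))
  sol_e <- simulate_model(ext, c(m$x0, 3, 3), c(0, 100))
  f_base <- function(t, x) m$rhs(x, m$input(t), t, m$params)
  sol_b <- ode_solve(f_base, m$x0, 0, 100, rtol = 1e-8, atol = 1e-10)
  tq <- seq(1, 100, by = 7)
  expect_equal(sol_e$interp(tq)[, 1:3], sol_b$interp(tq), tolerance = 1e-6)
})

test_that("linear constraint sets validate their inputs", {
  expect_error(linear_constraints(diag(2), c(0, 0, 0)), "nrow")
  expect_error(linear_constraints(matrix(c(1, -1), 2, 1), c(1, 1),
                                  c(">=", ">=")),
               "infeasible")  # x >= 1 and -x >= 1 (i.e. x <= -1)
  cs <- linear_constraints(rbind(c(1, 0), c(0, 1), c(1, 1)), c(0, 0, -1),
                           c(">=", ">=", ">="))
  expect_true(constraints_satisfied(cs, c(1, 1)))
  expect_false(constraints_satisfied(cs, c(-1, 1)))
})
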