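test_that("heat-shock fixture: defaults, settling, induction, decay limit", {
  m <- heat_shock_model()
  expect_equal(unname(m$params[c("k_syn", "k_seq")]), c(3, 3))
  expect_error(heat_shock_model(c(bogus = 1)), "unknown parameter")

  f <- function(t, x) m$rhs(x, m$input(t), t, m$params)
  X <- ode_at(f, m$x0, 0, c(25, 100, 375, 400))
  # settled by the horizon end: < 1% relative change per 25 time units
  expect_lt(max(abs(X[4, 1:2] - X[3, 1:2]) / abs(X[4, 1:2])), 0.01)
  # elevated new steady state (order-10x induction of both outputs)
  expect_gt(X[4, 1] / m$x0[1], 5)
  expect_gt(X[4, 2] / m$x0[2], 5)

  # with production off, states decay monotonically toward zero
  m0 <- heat_shock_model(c(eta_s0 = 0, eta_s1 = 0, eta_u0 = 0, eta_u1 = 0,
                           k_syn = 0))
  f0 <- function(t, x) m0$rhs(x, m0$input(t), t, m0$params)
  X0 <- ode_at(f0, c(10, 1, 10), 0, seq(0, 400, by = 10))
  expect_true(all(diff(X0[, 1]) < 1e-9))
  expect_true(all(diff(X0[, 2]) < 1e-9))
  expect_true(all(diff(X0[, 3]) < 1e-9))
  expect_lt(max(X0[nrow(X0), ]), 0.2)
})

test_that("no-spike variant: same steady state, different transient, same parameters", {
  m1 <- heat_shock_model()
  m2 <- heat_shock_nospike_model()
  expect_identical(m1$param_names, m2$param_names)
  expect_equal(m1$params, m2$params)

  f1 <- function(t, x) m1$rhs(x, m1$input(t), t, m1$params)
  f2 <- function(t, x) m2$rhs(x, m2$input(t), t, m2$params)
  tt <- seq(0.5, 400, by = 0.5)
  X1 <- ode_at(f1, m1$x0, 0, tt)
  X2 <- ode_at(f2, m1$x0, 0, tt)   # same start as the generating model
  end <- length(tt)
  expect_equal(X1[end, 1:2], X2[end, 1:2], tolerance = 0.02)

  # transient differs: the spike model's sigma-32 peak exceeds the no-spike
  # peak by well over 5 noise standard deviations (R2 = 0.02)
  expect_gt(max(X1[, 2]) - max(X2[, 2]), 5 * sqrt(0.02))
})

test_that("repressilator fixture: 18 parameters, periodic orbit, symmetry", {
  m <- repressilator_model()
  expect_length(m$params, 18)
  expect_error(repressilator_model(rep(1, 17)), "18 rates")
  expect_error(repressilator_model(c(rep(1, 17), -1)), "positive")

  f <- function(t, x) m$rhs(x, 0, t, m$params)
  sol <- ode_solve(f, m$x0, 0, 150, rtol = 1e-8, atol = 1e-10)
  tt <- seq(60, 150, by = 0.02)
  M <- sol$interp(tt)
  m1 <- M[, 1]
  pk <- which(diff(sign(diff(m1))) == -2) + 1
  peaks <- m1[pk]
  expect_gt(length(peaks), 4)
  # successive peak amplitudes differ by < 1% after the transient
  expect_lt(max(abs(diff(peaks))) / max(peaks), 0.01)

  # identical per-pair rates: the mRNAs are cyclic time-shifted copies,
  # m2(t) = m1(t + T/3) and m3(t) = m1(t + 2T/3)
  period <- median(diff(tt[pk]))
  amp <- max(m1) - min(m1)
  for (j in 2:3) {
    shift <- (j - 1) * period / 3
    keep <- tt + shift <= max(tt)
    m1_shift <- sol$interp(tt[keep] + shift)[, 1]
    expect_lt(max(abs(M[keep, j] - m1_shift)) / amp, 0.01)
  }
})

test_that("fixture trajectories stay in the nonnegative orthant", {
  for (nm in c("heat_shock", "heat_shock_nospike", "repressilator")) {
    fx <- fixture_model(nm)
    m <- fx$model
    f <- function(t, x) m$rhs(x, m$input(t), t, m$params)
    X <- ode_at(f, m$x0, 0, seq(1, 100, by = 1))
    expect_gt(min(X), -1e-8)
  }
})

test_that("sampling schedules", {
  s <- heat_shock_schedule()
  expect_length(s, 22)
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(s[8:22]) == 25))   # uniform 25-minute tail
  expect_true(all(s[1:7] < 50))           # dense transient portion

  u <- uniform_schedule(30, 30)
  expect_length(u, 30)
  expect_lt(max(abs(diff(u) - diff(u)[1])), 1e-12)
  expect_equal(uniform_schedule(2, 10), c(0, 10))
  expect_error(uniform_schedule(1, 10), "n >= 2")
})

test_that("synthetic measurement generator contract", {
  m <- heat_shock_model()
  times <- heat_shock_schedule()

  # R = 0: exact noise-free outputs
  d0 <- simulate_measurements(m, times = times, observed = c(1, 2),
                              R = c(0, 0))
  f <- function(t, x) m$rhs(x, m$input(t), t, m$params)
  X <- ode_at(f, m$x0, 0, times)
  expect_equal(unname(d0$values), X[, 1:2], tolerance = 1e-10)

  # seed reproducibility
  d1 <- simulate_measurements(m, times = times, observed = c(1, 2),
                              R = c(50, 0.02), seed = 7)
  d2 <- simulate_measurements(m, times = times, observed = c(1, 2),
                              R = c(50, 0.02), seed = 7)
  d3 <- simulate_measurements(m, times = times, observed = c(1, 2),
                              R = c(50, 0.02), seed = 8)
  expect_identical(d1$values, d2$values)
  expect_false(identical(d1$values, d3$values))
  expect_identical(d1$seed, 7)

  # empirical noise variance over 1e4 regenerated points within 5% of R
  flat <- ode_model(1, function(x, u, t, p) 0, "unused", c(unused = 0),
                    x0 = 2)
  big <- simulate_measurements(flat, times = seq_len(1e4), observed = 1,
                               R = 0.49, seed = 99)
  expect_lt(abs(mean((big$values - 2)^2) / 0.49 - 1), 0.05)

  # relative noise: variance = fraction x signal mean per channel
  dr <- simulate_measurements(m, times = times, observed = c(1, 2),
                              noise_frac = 0.05, seed = 1)
  expect_equal(dr$R, 0.05 * colMeans(abs(X[, 1:2])), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("fixture registry lookup", {
  fx <- fixture_model("heat_shock")
  expect_s3_class(fx$model, "ode_model")
  expect_equal(fx$observed, c(1L, 2L))
  expect_error(fixture_model("nonexistent"), "unknown model")
  register_model("tmp_test_model", function() scalar_decay_model(),
                 observed = 1L)
  expect_equal(fixture_model("tmp_test_model")$observed, 1L)
})
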