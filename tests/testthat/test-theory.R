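test_that("parameter validation rejects unstable or malformed models", {
  expect_error(feedback_params(tau = -1), "tau")
  expect_error(feedback_params(tau = 1.05, w = 2), "unstable")
  expect_error(feedback_params(tau = 1, dt = 0.1, duration = 0.01))
  p <- feedback_params(tau = 1.05, w = -0.5)
  expect_s3_class(p, "feedback_params")
  expect_error(simulate_replay(p, numeric(10), seed = 1), "length")
})

test_that("no drive and no noise gives an identically zero trace", {
  p <- feedback_params(tau = 1.05, sigma = 0, dt = 0.01, duration = 10)
  expect_true(all(simulate_open(p, seed = 1)$values == 0))
  pc <- feedback_params(tau = 1.05, w = -0.5, sigma = 0, dt = 0.01,
                        duration = 10)
  expect_true(all(simulate_closed(pc, seed = 1)$values == 0))
})

test_that("equilibrium response per unit static input matches the gains", {
  # Richardson check: the dt -> 0 limit of the Euler equilibrium equals the
  # closed forms Gain_o = tau and Gain_c = tau/(1 - w tau)
  run_gain <- function(w, dt) {
    p <- feedback_params(tau = 1.05, w = w, sigma = 0, dt = dt,
                         duration = 60,
                         input = data.frame(start = 0, stop = 60, amp = 2))
    sim <- if (w == 0) simulate_open(p) else simulate_closed(p)
    tail(sim$values, 1) / 2
  }
  s <- analytic_summary(feedback_params(tau = 1.05, w = -0.5))
  for (w in c(0, -0.5)) {
    g1 <- run_gain(w, 1e-3)
    g2 <- run_gain(w, 5e-4)
    extrap <- 2 * g2 - g1           # first-order Richardson extrapolation
    target <- if (w == 0) s$gain_open else s$gain_closed
    expect_equal(extrap, target, tolerance = 1e-6)
  }
})

test_that("analytic summary reproduces the closed-form values", {
  s <- analytic_summary(feedback_params(tau = 1.05, w = -0.5, sigma = 1))
  expect_equal(s$peak_open, 0.525)
  expect_equal(s$peak_closed, 0.525 / 1.525)
  expect_equal(s$peak_replay, 0.525 / 1.525 +
                 0.525 * 2 * (-0.525) / (-0.525 - 2))
  expect_equal(s$gain_open, 1.05)
  expect_equal(s$gain_closed, 1.05 / 1.525)
  expect_equal(s$tau_eff, 1.05 / 1.525)
  # w = 0 collapses closed onto open
  s0 <- analytic_summary(feedback_params(tau = 1.05, w = 0))
  expect_equal(s0$peak_closed, s0$peak_open)
  expect_equal(s0$gain_closed, s0$gain_open)
  expect_equal(s0$tau_eff, 1.05)
  # sigma = 0 zeroes the peaks but not the gains
  sz <- analytic_summary(feedback_params(tau = 1.05, w = -0.5, sigma = 0))
  expect_equal(sz$peak_open, 0)
  expect_equal(sz$gain_closed, s$gain_closed)
})

test_that("replay peak agrees with an independent spectral-integral oracle", {
  # S_Br(w) = sigma^2 [1 + w^2/(om^2 + (1/tau - w)^2)] / (om^2 + 1/tau^2);
  # its integral over frequencies is the stationary replay variance
  tau <- 1.05; w <- -0.5; sigma <- 1
  spec <- function(om) {
    sigma^2 * (1 + w^2 / (om^2 + (1 / tau - w)^2)) / (om^2 + 1 / tau^2)
  }
  oracle <- stats::integrate(spec, -Inf, Inf, rel.tol = 1e-10)$value / (2 * pi)
  s <- analytic_summary(feedback_params(tau = tau, w = w, sigma = sigma))
  expect_equal(oracle, s$peak_replay, tolerance = 1e-8)
})

test_that("empirical variances of all three conditions match theory", {
  p <- theory_params(duration = 5000, dt = 0.01)
  s <- analytic_summary(p)
  o <- simulate_open(p, seed = 11)
  cl <- simulate_closed(p, seed = 12)
  rp <- simulate_replay(p, cl, seed = 13)
  for (pair in list(list(o, s$peak_open), list(cl, s$peak_closed),
                    list(rp, s$peak_replay))) {
    v <- empirical_variance(pair[[1]])
    expect_lt(abs(v$estimate - pair[[2]]), 3 * v$se)
  }
})

test_that("trivial replay identities hold", {
  p <- theory_params(duration = 50)
  # w = 0 closed-loop equals open-loop exactly for the same seed
  p0 <- feedback_params(tau = 1.05, w = 0, sigma = 1, dt = 0.01,
                        duration = 50)
  expect_equal(simulate_closed(p0, seed = 5)$values,
               simulate_open(p0, seed = 5)$values)
  # replaying an identically zero input reproduces the open-loop trace
  rp <- simulate_replay(p, numeric(round(50 / 0.01)), seed = 5)
  expect_equal(rp$values, simulate_open(p, seed = 5)$values)
})

test_that("condition ordering holds for negative feedback, stochastic and analytic", {
  set.seed(99)
  for (k in 1:5) {
    tau <- runif(1, 0.5, 2)
    w <- -runif(1, 0.2, 1 / tau)
    p <- feedback_params(tau = tau, w = w, sigma = 1, dt = 0.01,
                         duration = 2000)
    s <- analytic_summary(p)
    expect_true(s$peak_closed < s$peak_open)
    expect_true(s$peak_open < s$peak_replay)
    cl <- simulate_closed(p, seed = k)
    vo <- empirical_variance(simulate_open(p, seed = k))
    vc <- empirical_variance(cl)
    vr <- empirical_variance(simulate_replay(p, cl, seed = k + 100))
    expect_lt(vc$estimate, vo$estimate)
    expect_lt(vo$estimate, vr$estimate)
  }
})

test_that("closed-loop autocorrelation decays with the effective time constant", {
  p <- theory_params(duration = 20000, dt = 0.02)
  s <- analytic_summary(p)
  cl <- simulate_closed(p, seed = 3)
  x <- cl$values[-(1:500)]
  lag_max <- round(2 * s$tau_eff / p$dt)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  lags_t <- (seq_along(ac) - 1) * p$dt
  keep <- ac > 0.05
  tau_hat <- -1 / stats::coef(stats::lm(log(ac[keep]) ~ lags_t[keep]))[2]
  expect_lt(abs(tau_hat - s$tau_eff) / s$tau_eff, 0.1)
})

test_that("empirical_variance handles trivial and degenerate inputs", {
  expect_equal(empirical_variance(rep(2, 500))$estimate, 0)
  set.seed(1)
  v <- empirical_variance(rnorm(20000))
  expect_lt(abs(v$estimate - 1), 3 * v$se)
  expect_error(empirical_variance(rnorm(50)), "too few")
})

test_that("replay requires the recorded feedback input and matching dt", {
  p <- theory_params(duration = 20)
  o <- simulate_open(p, seed = 1)
  expect_error(simulate_replay(p, o, seed = 2), "feedback_input")
  p2 <- feedback_params(tau = 1.05, w = -0.5, dt = 0.02, duration = 20)
  cl <- simulate_closed(p2, seed = 1)
  expect_error(simulate_replay(p, cl, seed = 2), "dt")
})
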