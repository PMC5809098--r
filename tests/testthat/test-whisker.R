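test_that("free whisker configuration equals the unconstrained minimum", {
  out <- whisker_solve(20 * pi / 180, whisker_params())
  expect_equal(out$theta_p, 20 * pi / 180)
  expect_equal(out$theta_h, 0)
  expect_false(out$in_contact)
  # negative angles never touch the overhead wall
  out2 <- whisker_solve(-0.8, whisker_params())
  expect_false(out2$in_contact)
})

test_that("rigid whisker clamps protraction at the wall angle", {
  out <- whisker_solve(45 * pi / 180, whisker_params(k2 = 1e7))
  expect_true(out$in_contact)
  expect_equal(out$theta_p, asin(0.5), tolerance = 1e-3)
  expect_lt(abs(out$theta_h), 1e-3)
})

test_that("stiff whiskers deflect protraction more than flexible ones", {
  # a flexible center spring lets theta_p track theta_eq while the tip
  # bends; a stiff one forces theta_p away from theta_eq toward the wall
  te <- 45 * pi / 180
  flex <- whisker_solve(te, whisker_params(k2 = 0.1))
  stiff <- whisker_solve(te, whisker_params(k2 = 10))
  expect_true(flex$in_contact && stiff$in_contact)
  expect_lt(abs(flex$theta_p - te), abs(stiff$theta_p - te))
  expect_gt(abs(flex$theta_h), abs(stiff$theta_h))
})

test_that("contact solutions satisfy the constraint to 1e-6", {
  set.seed(51)
  for (k in 1:25) {
    te <- runif(1, asin(0.5) + 0.01, pi / 2)
    k2 <- 10^runif(1, -1.3, 1.3)
    out <- whisker_solve(te, whisker_params(k2 = k2))
    expect_true(out$in_contact)
    expect_lt(abs(sin(out$theta_p) + sin(out$theta_p - out$theta_h) - 1),
              1e-6)
  }
})

test_that("constrained minimizer matches a dense 2-D grid search", {
  set.seed(52)
  tp_grid <- seq(asin(0.5) - 0.05, pi / 2, by = 0.002)
  for (k in 1:20) {
    te <- runif(1, 0.6, 1.5)
    k2 <- 10^runif(1, -1, 1)
    th_free <- tp_grid - asin(pmin(1, pmax(-1, 1 - sin(tp_grid))))
    en <- (tp_grid - te)^2 + k2 / 2 * th_free^2
    best <- which.min(en)
    out <- whisker_solve(te, whisker_params(k2 = k2))
    expect_lt(abs(out$theta_p - tp_grid[best]), 0.004)
  }
})

test_that("connectivity has the printed sign structure and sparsity", {
  net <- cached_network()
  N <- net$params$N
  W <- net$W
  expect_true(all(W[, 1:N] >= 0))
  expect_true(all(W[, (N + 1):(2 * N)] <= 0))
  dens <- mean(W[, (N + 1):(2 * N)] != 0)
  expect_lt(abs(dens - net$params$p), 3 * sqrt(0.1 * 0.9 / (2 * N * N)) + 0.01)
})

test_that("spectral calibration hits the target eigenvalue exactly by scaling", {
  net <- cached_network()
  expect_lt(abs(net$lead_eigenvalue - 0.975), 5e-3)
  # deterministic limit: g0 = 0 and p -> 1 make the eigenvalue equal b0
  p1 <- network_params(N = 20L, p = 0.999, g0 = 0)
  m <- loopgain:::assemble_connectivity(
    list(b = matrix(1, 40, 20), b_prime = matrix(1, 40, 20),
         b_dprime = matrix(1, 40, 20)), p1)
  b0 <- calibrate_b0(m, 0.975)
  expect_equal(b0 * max(Re(eigen(m)$values)), 0.975, tolerance = 1e-10)
  # doubling the target doubles b0 (linearity of the spectrum in b0)
  expect_equal(calibrate_b0(m, 1.95), 2 * b0, tolerance = 1e-10)
})

test_that("quiescent network decays to rest below the instability point", {
  net <- cached_network()
  p0 <- net$params
  p0$noise_sigma <- 0; p0$adapt_gain <- 0; p0$cpg_sigma <- 0
  net0 <- net; net0$params <- p0
  st <- list(x = rep(1, 200), a = numeric(200), theta_eq = 0, u = 0, v = 0)
  rec <- run_condition(net0, "open", duration = 2, seed = 1, burn_in = 0,
                       state = st)
  expect_lt(max(abs(rec$state$x)), 0.2)
  # the all-zero state is a fixed point
  rec0 <- run_condition(net0, "open", duration = 0.5, seed = 1, burn_in = 0)
  expect_equal(max(abs(rec0$state$x)), 0)
  expect_equal(var(rec0$theta_p), 0)
})

test_that("contact-detection input lasts min(contact duration, 25 ms)", {
  net <- cached_network()
  rec <- run_condition(net, "touch", duration = 20, seed = 7,
                       wp = whisker_params(k2 = 10))
  expect_gt(nrow(rec$contacts), 10)
  dur_steps <- round((rec$contacts$offset - rec$contacts$onset) /
                       net$params$dt)
  cap <- round(net$params$pulse_max_ms / 1e3 / net$params$dt)
  expected <- pmin(dur_steps, cap)
  expect_true(all(abs(rec$contacts$pulse_steps - expected) <= 1))
  expect_equal(sum(rec$contacts$pulse_steps), rec$total_pulse_steps)
})

test_that("whisking drives theta at the pattern-generator frequency", {
  net <- cached_network()
  rec <- run_condition(net, "closed", duration = 25, seed = 8)
  sp <- welch_psd(rec$theta_p, 1 / rec$dt_out, segment_length = 8192)
  expect_lt(abs(peak_frequency(sp, f_min = 1, f_max = 40) - 10), 0.5)
  # wall off means no contacts
  expect_equal(nrow(rec$contacts), 0L)
  expect_true(all(rec$theta_h == 0))
})

test_that("zero-amplitude deflection pulses evoke no mean response", {
  net <- cached_network()
  tr <- passive_deflection_trials(net, "closed", n_trials = 12, seed = 9,
                                  amp = 0, spacing = 1.2)
  post <- tr$times_ms > 0 & tr$times_ms < 500
  expect_lt(abs(mean(tr$mean_response[post])), 0.05)
})

test_that("evoked responses scale linearly with pulse amplitude", {
  # with a shared seed the noise realization is identical across runs, so
  # linearity of the network makes equal amplitude increments produce
  # exactly equal response increments
  net <- cached_network()
  r1 <- passive_deflection_trials(net, "open", n_trials = 10, seed = 10,
                                  amp = 0.035, spacing = 1.2)
  r2 <- passive_deflection_trials(net, "open", n_trials = 10, seed = 10,
                                  amp = 0.07, spacing = 1.2)
  r3 <- passive_deflection_trials(net, "open", n_trials = 10, seed = 10,
                                  amp = 0.105, spacing = 1.2)
  d21 <- r2$mean_response - r1$mean_response
  d32 <- r3$mean_response - r2$mean_response
  expect_equal(d32, d21, tolerance = 1e-8)
  expect_gt(max(d21), 0)      # the increment is a real evoked response
})

test_that("touch trials require contacts and align at onsets", {
  net <- cached_network()
  tr <- active_touch_trials(net, whisker_params(k2 = 10), n_trials = 25,
                            seed = 11, min_trials = 15)
  expect_gte(dim(tr$with_event)[1], 15)
  expect_equal(dim(tr$with_event)[2], 20)
  expect_true(all(diff(tr$onsets) >= 0.35 - 1e-9))
  # no wall, no contacts: the error advises stronger whisking
  p2 <- network_params(cpg_sigma = 1e-4)
  net2 <- build_network(p2, seed = 1)
  expect_error(active_touch_trials(net2, n_trials = 10, seed = 2),
               "contact")
})
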