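test_that("afferent fit and residual satisfy least-squares identities", {
  set.seed(41)
  ses <- simulate_session(make_ground_truth(
    single_cell_config(env_drive_sd = 0.5), seed = 1), seed = 2)
  E_c <- ses$E_c - mean(ses$E_c)
  B_r <- ses$B_r[, 1] - mean(ses$B_r[, 1])
  Ff <- fit_afferent(E_c, B_r, ses$fs)
  res <- compute_residual(B_r, Ff, E_c)
  D <- loopgain:::basis_design(E_c, Ff$basis)
  expect_lt(max(abs(crossprod(D, res))) / length(res), 1e-8)
  expect_equal(res, Ff$residuals, tolerance = 1e-10)
  # the generating afferent is net negative and so is the estimate
  expect_lt(filter_area(Ff), 0)
})

test_that("noise-free session is identified essentially exactly", {
  # broadband environment drive so the afferent kernel is identifiable at
  # every frequency; the neural noise is four orders below the signal
  cfg <- single_cell_config(noise_sd = 1e-3, env_drive_sd = 0.5,
                            duration = 720)
  gt <- make_ground_truth(cfg, seed = 3)
  ses <- simulate_session(gt, seed = 4)
  E_c <- ses$E_c - mean(ses$E_c)
  B_r <- ses$B_r[, 1] - mean(ses$B_r[, 1])
  Ff <- fit_afferent(E_c, B_r, ses$fs, scales = 0.6, n_lags = 15)
  tf <- gt$F_kernels[, 1]
  L <- min(length(Ff$kernel), length(tf))
  expect_lt(sqrt(sum((Ff$kernel[1:L] - tf[1:L])^2) / sum(tf^2)), 0.05)
  res <- compute_residual(B_r, Ff, E_c)
  expect_lt(sd(res), 0.02 * sd(B_r))
})

test_that("feedback combination obeys H = F*G and the convolution theorem", {
  set.seed(42)
  ses <- simulate_session(make_ground_truth(single_cell_config(), seed = 5),
                          seed = 6)
  E_c <- ses$E_c - mean(ses$E_c)
  Ff <- fit_afferent(E_c, ses$B_r[, 1] - mean(ses$B_r[, 1]), ses$fs)
  res <- compute_residual(ses$B_r[, 1] - mean(ses$B_r[, 1]), Ff, E_c)
  Gf <- fit_efferent(res, ses$E_r - mean(ses$E_r), ses$fs)
  fe <- combine_feedback(Ff, Gf)
  expect_equal(fe$H, fe$F * fe$G)     # exact identity on every frequency
  # time-domain convolution matches the frequency-domain product
  hw <- vapply(fe$freqs, function(f)
    sum(fe$kernel * exp(-2i * pi * f * fe$lags)), complex(1))
  expect_equal(hw, fe$H, tolerance = 1e-6)
})

test_that("power-ratio formulas give the printed special cases", {
  freqs <- c(0.05, 0.1)
  expect_equal(predicted_power_ratio(c(0i, 0i), freqs)$ratio, c(1, 1))
  expect_equal(predicted_power_ratio(c(-1 + 0i, -1 + 0i), freqs)$ratio,
               c(0.2, 0.2))
  expect_equal(predicted_power_ratio(c(0.5 + 0i, 0.5 + 0i), freqs)$ratio,
               c(2, 2))
  expect_equal(single_cycle_ratio(c(0i, 0i), freqs)$ratio, c(1, 1))
  # for small H the one-cycle and full ratios agree to second order
  for (h in c(0.05, 0.02, 0.01)) {
    full <- predicted_power_ratio(complex(real = -h), 0.1)$ratio
    one <- single_cycle_ratio(complex(real = -h), 0.1)$ratio
    expect_lt(abs(full - one), 4 * h^2)
  }
  # instability is flagged when |1 - H| collapses
  pr <- predicted_power_ratio(complex(real = 1 - 1e-5), 0.1)
  expect_true(pr$unstable)
})

test_that("zero efferent filter collapses the naive prediction onto F", {
  set.seed(43)
  ses <- simulate_session(make_ground_truth(single_cell_config(), seed = 7),
                          seed = 8)
  E_c <- ses$E_c - mean(ses$E_c)
  Ff <- fit_afferent(E_c, ses$B_r[, 1] - mean(ses$B_r[, 1]), ses$fs)
  S <- welch_psd(E_c, ses$fs, 64)
  zeroG <- list(freqs = S$freqs, F = freq_response(Ff, S$freqs),
                G = rep(0 + 0i, length(S$freqs)),
                H = rep(0 + 0i, length(S$freqs)), dt = Ff$dt)
  np <- predict_naive_afferent(zeroG, S, S)
  expect_equal(np$values, freq_response(Ff, S$freqs))
})

test_that("prediction error ratio has the right fixed points", {
  set.seed(44)
  ses <- simulate_session(make_ground_truth(single_cell_config(), seed = 9),
                          seed = 10)
  E_c <- ses$E_c - mean(ses$E_c)
  B_c <- ses$B_c[, 1] - mean(ses$B_c[, 1])
  naive <- fit_naive_afferent(E_c, B_c, ses$fs)
  Ff <- fit_afferent(E_c, ses$B_r[, 1] - mean(ses$B_r[, 1]), ses$fs)
  expect_equal(prediction_error_ratio(naive, naive$kernel, Ff)$ratio, 0)
  f_on_lags <- numeric(length(naive$lags))
  idx <- match(round(naive$lags * ses$fs), round(Ff$lags * ses$fs))
  f_on_lags[!is.na(idx)] <- Ff$kernel[idx[!is.na(idx)]]
  expect_equal(prediction_error_ratio(naive, f_on_lags, Ff)$ratio, 1)
})

test_that("the naive filter develops an acausal lobe under feedback", {
  cfg <- single_cell_config(noise_sd = 0.3, duration = 720)
  gt <- make_ground_truth(cfg, seed = 11)
  ses <- simulate_session(gt, seed = 12)
  E_c <- ses$E_c - mean(ses$E_c)
  naive <- fit_naive_afferent(E_c, ses$B_c[, 1] - mean(ses$B_c[, 1]), ses$fs)
  neg <- naive$lags < -1e-9
  pos <- naive$lags > 1e-9
  acausal_share <- sum(naive$kernel[neg]^2) / sum(naive$kernel^2)
  expect_gt(acausal_share, 0.1)
  # and it differs clearly from the replay afferent filter
  Ff <- fit_afferent(E_c, ses$B_r[, 1] - mean(ses$B_r[, 1]), ses$fs)
  f_on_lags <- numeric(length(naive$lags))
  idx <- match(round(naive$lags * ses$fs), round(Ff$lags * ses$fs))
  f_on_lags[!is.na(idx)] <- Ff$kernel[idx[!is.na(idx)]]
  expect_gt(sqrt(mean((f_on_lags - naive$kernel)^2)) /
              sqrt(mean(f_on_lags^2)), 0.2)
})

test_that("behavioural feedback is net negative for suppressive loops", {
  cfg <- session_config(fraction_feedback = 0.2, efferent_net = 0.15,
                        env_drive_sd = 0.5)
  nets <- vapply(1:4, function(s) {
    ses <- simulate_session(make_ground_truth(cfg, seed = s), seed = 50 + s)
    bf <- behavioural_feedback(block_demean(ses$E_r, ses$blocks),
                               block_demean(ses$E_c, ses$blocks), ses$fs)
    filter_area(bf)
  }, numeric(1))
  expect_lt(median(nets), 0)
  # without any feedback the behavioural filter is negligible
  cfg0 <- session_config(fraction_feedback = 0, env_drive_sd = 1)
  ses0 <- simulate_session(make_ground_truth(cfg0, seed = 1), seed = 2)
  bf0 <- behavioural_feedback(block_demean(ses0$E_r, ses0$blocks),
                              block_demean(ses0$E_c, ses0$blocks), ses0$fs)
  expect_lt(abs(filter_area(bf0)), 0.25)
})

test_that("session analysis returns a complete per-cell report", {
  gt <- make_ground_truth(session_config(n_cells = 6L), seed = 13)
  ses <- simulate_session(gt, seed = 14)
  an <- analyze_session(ses)
  expect_equal(nrow(an$report), 6)
  expect_true(all(c("net_F", "net_G", "net_H", "observed_ratio",
                    "predicted_ratio", "single_cycle_ratio",
                    "prediction_error_ratio") %in% names(an$report)))
  expect_true(all(an$report$observed_ratio > 0))
  expect_true(all(an$report$predicted_ratio > 0, na.rm = TRUE))
  rr <- recovery_report(gt, an)
  expect_equal(nrow(rr$cells), 6)
  expect_gte(rr$summary$sign_F_rate, 0.5)
})

test_that("recovery sharpens and rank agreement is positive with longer sessions", {
  # consistency of the least-squares identification: quadrupling the
  # session length shrinks the afferent kernel error, and across the
  # pooled long-session population the predicted and realized log power
  # ratios agree in rank
  pool <- NULL
  improved <- logical(4)
  for (s in 1:4) {
    gt_s <- make_ground_truth(session_config(duration = 180),
                              seed = 600 + s, retries = 5L)
    gt_l <- make_ground_truth(session_config(duration = 720),
                              seed = 600 + s, retries = 5L)
    an_s <- analyze_session(simulate_session(gt_s, seed = 700 + s))
    an_l <- analyze_session(simulate_session(gt_l, seed = 700 + s))
    improved[s] <- recovery_report(gt_l, an_l)$summary$median_err_F <
      recovery_report(gt_s, an_s)$summary$median_err_F
    pool <- rbind(pool, an_l$report[, c("predicted_ratio",
                                        "observed_ratio")])
  }
  expect_gte(sum(improved), 3)
  expect_gt(cor(log(pool$predicted_ratio), log(pool$observed_ratio),
                method = "spearman"), 0)
})
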