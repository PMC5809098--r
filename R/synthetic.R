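#' Configuration of a synthetic closed-loop/replay session
#'
#' Describes the ground truth of a simulated virtual-reality session: a
#' population of cells, each with a causal afferent kernel (swim power to
#' cell, net negative by default) and — for a configurable fraction — a
#' causal efferent kernel (cell to swim power, net positive), embedded in a
#' shared environment loop with 30-s alternating visual-gain blocks. The
#' defaults emulate the fictive-swimming sessions the pipeline is designed
#' for: calcium-rate sampling at 2.5 Hz, 3 minutes per condition, and
#' suppressive (negative) round-trip feedback whose population total stays
#' well inside the stability margin.
#'
#' @param n_cells Number of cells (default 30).
#' @param fs Sampling rate in Hz (default 2.5).
#' @param duration Seconds per condition (default 180).
#' @param block_len Gain-block length in seconds (default 30).
#' @param gain_levels High/low visual gain factors (default \code{c(1.2,
#'   0.8)}), applied multiplicatively to the afferent pathway in alternating
#'   blocks (the visual gain scales the stimulus the afferent pathway sees,
#'   identically in the closed-loop recording and its replay).
#' @param fraction_feedback Fraction of cells with a nonzero efferent kernel
#'   (default 0.1, a minority of strongly loop-coupled cells as in the
#'   cerebellar population the analysis highlights).
#' @param afferent_net Mean net area of the afferent kernels (default
#'   \code{-0.65}; negative = suppressive visual drive).
#' @param efferent_net Mean net area of the efferent kernels of feedback
#'   cells (default \code{0.3}; positive = swim-promoting). With the default
#'   cell count and feedback fraction the population round-trip gain stays
#'   near \code{-0.6}: clearly suppressive yet stable, and dominated by few
#'   enough cells that per-cell closed-loop corrections remain informative.
#' @param amp_spread Log-normal spread (sdlog) of kernel amplitudes across
#'   cells (default 0.3).
#' @param tau_f,tau_g Afferent/efferent kernel time constants in seconds
#'   (alpha-function shapes; defaults 0.6 and 0.5 give a round-trip kernel
#'   peaking near 1 s).
#' @param kernel_support Kernel support in seconds (default 6).
#' @param noise_sd Neural residual noise s.d. (default 1; the environment
#'   carries no noise of its own).
#' @param env_drive_sd S.d. of the efferent drive contributed by the
#'   unrecorded population (default 1): swimming is driven by the whole
#'   brain, of which the recorded cells are a small subset, so the
#'   environment receives an additional broadband neural drive inside the
#'   loop (fresh realization in the replay condition). Setting it to 0
#'   recovers a loop closed exclusively by the recorded cells. Default 1.
#' @param env_baseline Gain-dependent swim-power baseline scale (default
#'   0.2): each block adds \code{env_baseline * (2 - gain)} to E, so blocks
#'   have different mean activity levels until block demeaning.
#' @param noise_ar1 Optional AR(1) coefficient of the neural noise (default
#'   0, white) for stress testing the equal-residual-spectra assumption.
#' @param calcium_tau Optional exponential smoothing time constant in
#'   seconds applied to B traces (default 0, off) for indicator-kinetics
#'   realism tests.
#' @param stability_margin Minimum allowed \eqn{|1 - H_{tot}(\omega)|}
#'   (default 0.1); configurations with \eqn{\max_\omega |H_{tot}| \ge 1}
#'   are always rejected (the delayed loop recursion diverges).
#' @return An object of class \code{"session_config"}.
#' @export
session_config <- function(n_cells = 30L, fs = 2.5, duration = 180,
                           block_len = 30, gain_levels = c(1.2, 0.8),
                           fraction_feedback = 0.1, afferent_net = -0.65,
                           efferent_net = 0.3, amp_spread = 0.3,
                           tau_f = 0.6, tau_g = 0.5, kernel_support = 6,
                           noise_sd = 1, env_drive_sd = 1, env_baseline = 0.2,
                           noise_ar1 = 0, calcium_tau = 0,
                           stability_margin = 0.1) {
  stopifnot(n_cells >= 1L, fs > 0, duration > 0, block_len > 0,
            length(gain_levels) == 2L, all(gain_levels > 0),
            fraction_feedback >= 0, fraction_feedback <= 1,
            tau_f > 0, tau_g > 0, kernel_support > 1 / fs, noise_sd >= 0,
            env_drive_sd >= 0,
            abs(noise_ar1) < 1, calcium_tau >= 0, stability_margin > 0)
  structure(as.list(environment()), class = "session_config")
}

# unit-area alpha-function kernel on a lag grid (seconds)
alpha_kernel <- function(lags_s, tau) {
  k <- (lags_s / tau) * exp(1 - lags_s / tau)
  k[lags_s < 0] <- 0
  if (sum(k) <= 0) stop("degenerate kernel", call. = FALSE)
  k / sum(k)
}

#' Draw the ground truth of a synthetic session
#'
#' Samples per-cell afferent and efferent kernels (alpha-function shapes
#' with log-normal amplitude spread), assigns the feedback cells, builds the
#' gain-block schedule and verifies loop stability: the population
#' round-trip transfer \eqn{H_{tot}(\omega) = \sum_i F_i(\omega)G_i(\omega)}
#' (including the one-sample loop closure delay carried by the efferent
#' kernels) must keep \eqn{|1 - H_{tot}|} above the configured margin at the
#' highest gain.
#'
#' @param config A \code{\link{session_config}}.
#' @param seed Integer seed.
#' @param retries Number of deterministic redraws (derived seeds) allowed
#'   when a drawn kernel set violates the stability requirements (default
#'   0: fail immediately).
#' @return Object of class \code{"session_ground_truth"}: kernel matrices
#'   \code{F_kernels} (lags 0..K-1) and \code{G_kernels} (lags 1..K),
#'   \code{is_feedback}, \code{noise_sd}, gain \code{schedule} and
#'   \code{blocks}, \code{fs}, \code{n_samples}, \code{config}, \code{seed}.
#' @export
make_ground_truth <- function(config = session_config(), seed = NULL,
                              retries = 0L) {
  stopifnot(inherits(config, "session_config"))
  if (retries > 0L) {
    for (k in 0:retries) {
      sk <- if (is.null(seed)) NULL else seed + k * 797L
      gt <- tryCatch(make_ground_truth(config, sk, retries = 0L),
                     error = function(e) e)
      if (!inherits(gt, "error")) return(gt)
    }
    stop(gt)
  }
  with_seed(seed, {
    nc <- config$n_cells
    dt <- 1 / config$fs
    K <- round(config$kernel_support * config$fs)
    lags_f <- (0:(K - 1L)) * dt
    lags_g <- (1:K) * dt
    n_fb <- round(config$fraction_feedback * nc)
    is_fb <- rep(FALSE, nc)
    if (n_fb > 0) is_fb[sample.int(nc, n_fb)] <- TRUE
    amp_f <- config$afferent_net *
      stats::rlnorm(nc, -config$amp_spread^2 / 2, config$amp_spread)
    amp_g <- ifelse(is_fb, config$efferent_net *
                      stats::rlnorm(nc, -config$amp_spread^2 / 2,
                                    config$amp_spread), 0)
    Fk <- vapply(seq_len(nc), function(i)
      amp_f[i] * alpha_kernel(lags_f, config$tau_f), numeric(K))
    Gk <- vapply(seq_len(nc), function(i)
      if (amp_g[i] == 0) numeric(K) else
        amp_g[i] * alpha_kernel(lags_g, config$tau_g), numeric(K))
    # unrecorded-population drive enters white (swim power is broadband:
    # discrete bouts), keeping the environment spectrum bounded away from
    # zero at all frequencies
    bg_kernel <- c(1, numeric(K - 1L))
    n <- round(config$duration * config$fs)
    block_starts <- seq(1L, n, by = round(config$block_len * config$fs))
    gain_of_block <- rep(config$gain_levels,
                         length.out = length(block_starts))
    schedule <- rep(gain_of_block,
                    times = diff(c(block_starts, n + 1L)))
    gt <- structure(list(F_kernels = Fk, G_kernels = Gk,
                         bg_kernel = bg_kernel,
                         is_feedback = is_fb,
                         noise_sd = rep(config$noise_sd, nc),
                         schedule = schedule, blocks = block_starts,
                         fs = config$fs, n_samples = n,
                         config = config, seed = seed),
                    class = "session_ground_truth")
    Ht <- ground_truth_H(gt, total = TRUE, gain = max(config$gain_levels))
    if (max(Mod(Ht)) >= 1) {
      stop("unstable configuration: max |H_tot| = ", format(max(Mod(Ht))),
           " is not below 1", call. = FALSE)
    }
    margin <- min(Mod(1 - Ht))
    if (margin < config$stability_margin) {
      stop("unstable configuration: min |1 - H_tot| = ", format(margin),
           " below margin ", config$stability_margin, call. = FALSE)
    }
    gt
  })
}

#' @export
print.session_ground_truth <- function(x, ...) {
  cat(sprintf("<session_ground_truth> %d cells (%d feedback), %g s at %g Hz, %d gain blocks\n",
              ncol(x$F_kernels), sum(x$is_feedback),
              x$n_samples / x$fs, x$fs, length(x$blocks)))
  invisible(x)
}

#' Ground-truth round-trip transfer function
#'
#' Evaluates the true per-cell (or population-total) feedback transfer
#' \eqn{H_i(\omega) = F_i(\omega) G_i(\omega)} on a frequency grid,
#' including the one-sample loop delay built into the efferent kernels.
#'
#' @param gt A \code{session_ground_truth}.
#' @param freqs Frequencies in Hz; default a 257-point grid to Nyquist.
#' @param cell Cell index (ignored when \code{total = TRUE}).
#' @param total Sum over all cells?
#' @param gain Multiplies the afferent transfer (visual gain).
#' @return Complex vector over \code{freqs}.
#' @export
ground_truth_H <- function(gt, freqs = NULL, cell = 1L, total = FALSE,
                           gain = 1) {
  dt <- 1 / gt$fs
  if (is.null(freqs)) freqs <- seq(0, gt$fs / 2, length.out = 257L)
  K <- nrow(gt$F_kernels)
  lags_f <- (0:(K - 1L)) * dt
  lags_g <- (1:K) * dt
  one <- function(i) {
    Fw <- vapply(freqs, function(f)
      sum(gt$F_kernels[, i] * exp(-2i * pi * f * lags_f)), complex(1))
    Gw <- vapply(freqs, function(f)
      sum(gt$G_kernels[, i] * exp(-2i * pi * f * lags_g)), complex(1))
    gain * Fw * Gw
  }
  if (total) {
    Reduce(`+`, lapply(seq_len(ncol(gt$F_kernels)), one))
  } else one(cell)
}

# discrete convolution of past values: sum_k kernel[k] * x[t - lag_k]
conv_causal <- function(x, kernel, lag0) {
  n <- length(x)
  out <- numeric(n)
  for (j in seq_along(kernel)) {
    l <- lag0 + j - 1L
    if (kernel[j] == 0 || l >= n) next
    if (l == 0L) out <- out + kernel[j] * x
    else out[(l + 1L):n] <- out[(l + 1L):n] + kernel[j] * x[1:(n - l)]
  }
  out
}

make_noise <- function(n, nc, sd_vec, ar1) {
  eps <- matrix(stats::rnorm(n * nc), n, nc)
  if (ar1 != 0) {
    eps <- apply(eps, 2L, function(e)
      as.numeric(stats::filter(e, ar1, method = "recursive"))) *
      sqrt(1 - ar1^2)
  }
  sweep(eps, 2L, sd_vec, `*`)
}

apply_calcium <- function(B, fs, tau) {
  if (tau <= 0) return(B)
  a <- exp(-1 / (fs * tau))
  apply(B, 2L, function(b)
    as.numeric(stats::filter((1 - a) * b, a, method = "recursive")))
}

#' Simulate the closed-loop half of a session
#'
#' Discrete-time co-simulation of the population loop: at each step the swim
#' power is assembled from the cells' past activity through the efferent
#' kernels (one-sample loop closure delay) plus the gain-dependent baseline,
#' and each cell responds to the swim power through its gain-scaled afferent
#' kernel plus fresh neural noise. The environment carries no noise of its
#' own.
#'
#' @param gt A \code{\link{make_ground_truth}} result.
#' @param seed Integer seed for the neural noise.
#' @return List with \code{B_c} (time x cell) and \code{E_c}.
#' @export
simulate_closed_session <- function(gt, seed = NULL) {
  stopifnot(inherits(gt, "session_ground_truth"))
  n <- gt$n_samples
  nc <- ncol(gt$F_kernels)
  K <- nrow(gt$F_kernels)
  cfg <- gt$config
  with_seed(seed, {
    noise <- make_noise(n, nc, gt$noise_sd, cfg$noise_ar1)
    bg <- cfg$env_drive_sd *
      conv_causal(stats::rnorm(n), gt$bg_kernel, 1L)
    B <- matrix(0, n, nc)
    E <- numeric(n)
    base <- cfg$env_baseline * (2 - gt$schedule) + bg
    Gk <- gt$G_kernels  # lag 1..K
    Fk <- gt$F_kernels  # lag 0..K-1
    for (t in seq_len(n)) {
      # environment from past neural activity (lags 1..K)
      e <- base[t]
      kmax <- min(K, t - 1L)
      if (kmax >= 1L) {
        rows <- t - seq_len(kmax)
        e <- e + sum(Gk[seq_len(kmax), , drop = FALSE] *
                       B[rows, , drop = FALSE])
      }
      E[t] <- e
      # cells from the swim power (lags 0..K-1), gain on the afferent path
      lmax <- min(K - 1L, t - 1L)
      ev <- E[t - (0:lmax)]
      B[t, ] <- gt$schedule[t] *
        crossprod(Fk[seq_len(lmax + 1L), , drop = FALSE], ev)[, 1L] +
        noise[t, ]
    }
    if (any(!is.finite(B))) {
      bad <- which(colSums(!is.finite(B)) > 0)
      stop("closed-loop simulation diverged (cells ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
    list(B_c = apply_calcium(B, gt$fs, cfg$calcium_tau), E_c = E)
  })
}

#' Simulate the replay half of a session
#'
#' Each cell is driven by the recorded closed-loop swim power through the
#' same gain-scaled afferent kernel but with a fresh noise realization; the
#' replay swim power is then generated from the replay neural activity
#' through the efferent kernels, with no loop closure.
#'
#' @param gt A \code{\link{make_ground_truth}} result.
#' @param E_c The closed-loop swim power (bit-identical replay stimulus).
#' @param seed Integer seed for the fresh neural noise.
#' @return List with \code{B_r} (time x cell) and \code{E_r}.
#' @export
simulate_replay_session <- function(gt, E_c, seed = NULL) {
  stopifnot(inherits(gt, "session_ground_truth"))
  n <- gt$n_samples
  if (length(E_c) != n) stop("E_c length mismatch", call. = FALSE)
  nc <- ncol(gt$F_kernels)
  cfg <- gt$config
  with_seed(seed, {
    noise <- make_noise(n, nc, gt$noise_sd, cfg$noise_ar1)
    bg <- cfg$env_drive_sd *
      conv_causal(stats::rnorm(n), gt$bg_kernel, 1L)
    B <- vapply(seq_len(nc), function(i)
      gt$schedule * conv_causal(E_c, gt$F_kernels[, i], 0L) + noise[, i],
      numeric(n))
    E_r <- Reduce(`+`, lapply(seq_len(nc), function(i)
      conv_causal(B[, i], gt$G_kernels[, i], 1L))) + bg
    list(B_r = apply_calcium(B, gt$fs, cfg$calcium_tau), E_r = E_r)
  })
}

#' Generate a complete paired closed-loop/replay session
#'
#' @param gt A \code{\link{make_ground_truth}} result (or a
#'   \code{session_config}, in which case the ground truth is drawn first
#'   with the same seed).
#' @param seed Integer root seed; condition-specific seeds are derived from
#'   it deterministically.
#' @return Object of class \code{"session_recording"}: \code{B_c},
#'   \code{B_r} (time x cell), \code{E_c}, \code{E_r}, \code{fs},
#'   \code{blocks} (gain-block start indices), \code{ground_truth},
#'   \code{seed}.
#' @export
simulate_session <- function(gt, seed = NULL) {
  if (inherits(gt, "session_config")) gt <- make_ground_truth(gt, seed)
  stopifnot(inherits(gt, "session_ground_truth"))
  s1 <- if (is.null(seed)) NULL else seed + 11L
  s2 <- if (is.null(seed)) NULL else seed + 23L
  cl <- simulate_closed_session(gt, s1)
  rp <- simulate_replay_session(gt, cl$E_c, s2)
  structure(list(B_c = cl$B_c, B_r = rp$B_r, E_c = cl$E_c, E_r = rp$E_r,
                 fs = gt$fs, blocks = gt$blocks, ground_truth = gt,
                 seed = seed),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %d cells, %d samples per condition at %g Hz, %d gain blocks\n",
              ncol(x$B_c), nrow(x$B_c), x$fs, length(x$blocks)))
  invisible(x)
}

#' Parameter-recovery report against the ground truth
#'
#' Compares the fitted filters of a \code{\link{analyze_session}} run with
#' the generating kernels: relative L2 kernel errors, sign agreement of the
#' net afferent/efferent/round-trip transfers, and the rank correlation
#' between the theoretically predicted and realized per-cell log power
#' ratios.
#'
#' @param gt The generating \code{session_ground_truth}.
#' @param analysis A \code{session_analysis} of a session from \code{gt}.
#' @return A list with per-cell data frame \code{cells} and summary list
#'   \code{summary} (median errors, sign agreement rates, rank correlation).
#' @export
recovery_report <- function(gt, analysis) {
  stopifnot(inherits(gt, "session_ground_truth"),
            inherits(analysis, "session_analysis"))
  rep_df <- analysis$report
  nc <- nrow(rep_df)
  dt <- 1 / gt$fs
  rows <- lapply(seq_len(nc), function(r) {
    ci <- rep_df$cell[r]
    fit <- analysis$fits[[as.character(ci)]]
    tf <- gt$F_kernels[, ci]
    tg <- gt$G_kernels[, ci]
    ef <- fit$F$kernel
    L <- min(length(ef), length(tf))
    err_f <- sqrt(sum((ef[1:L] - tf[1:L])^2) / max(sum(tf[1:L]^2), 1e-12))
    eg <- fit$G$kernel[-1L]           # truth has no lag-0 tap
    Lg <- min(length(eg), length(tg))
    err_g <- if (any(tg != 0)) {
      sqrt(sum((eg[1:Lg] - tg[1:Lg])^2) / sum(tg[1:Lg]^2))
    } else NA_real_
    true_H0 <- Re(ground_truth_H(gt, freqs = 0, cell = ci))
    data.frame(cell = ci,
               true_net_F = sum(tf), true_net_G = sum(tg),
               true_net_H = true_H0,
               est_net_F = sum(ef), est_net_G = sum(fit$G$kernel),
               est_net_H = rep_df$net_H[r],
               err_F = err_f, err_G = err_g,
               sign_F_ok = sign(sum(ef)) == sign(sum(tf)),
               sign_H_ok = if (true_H0 == 0) NA else
                 sign(rep_df$net_H[r]) == sign(true_H0),
               is_feedback = gt$is_feedback[ci])
  })
  cells <- do.call(rbind, rows)
  fb <- gt$is_feedback[rep_df$cell]
  rank_cor <- if (nc >= 5L)
    stats::cor(log(rep_df$predicted_ratio), log(rep_df$observed_ratio),
               method = "spearman") else NA_real_
  list(cells = cells,
       summary = list(
         median_err_F = stats::median(cells$err_F),
         median_err_G = stats::median(cells$err_G, na.rm = TRUE),
         sign_F_rate = mean(cells$sign_F_ok),
         sign_H_rate = mean(cells$sign_H_ok[fb], na.rm = TRUE),
         rank_correlation = rank_cor))
}
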