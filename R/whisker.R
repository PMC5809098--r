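#' Parameters of the cortex-vibrissa network model
#'
#' Defaults follow the published model definition: 2N rate neurons (N
#' excitatory, N inhibitory) with sparse random connectivity calibrated to a
#' leading eigenvalue just below one, spike-frequency adaptation producing a
#' slow (about 1 Hz) coherent oscillation, a whisker driven by the excitatory
#' population and a stochastic 10 Hz pattern generator, and brief
#' contact-detection input pulses.
#'
#' The printed rate constants of the cortical equations are expressed on an
#' internal "network" clock; \code{time_unit_scale} (seconds per network time
#' unit) maps that clock onto wall-clock seconds. Its default was calibrated
#' once so that the quiet-state population spectrum peaks at about 1 Hz
#' (see the methods vignette for the procedure and implied biophysical time
#' constants). The whisking oscillator runs directly on the wall clock so
#' that \code{f_whisk} is in Hz.
#'
#' @param N Neurons per population (default 100, i.e. 200 total).
#' @param p Connection probability (default 0.1).
#' @param g0 Scale of the balanced random connectivity component (0.05).
#' @param target_eigenvalue Spectral calibration target for the leading
#'   eigenvalue (0.975).
#' @param w_x_theta Whisker-to-neuron feedback weight (0.002, applied to the
#'   protraction angle in degrees).
#' @param w_theta_x Neuron-to-whisker drive weight (0.085, applied to the
#'   excitatory population mean).
#' @param adapt_decay,adapt_gain Adaptation current constants (0.07, 0.008).
#' @param input_amp Sensory input amplitude I (0.035).
#' @param pulse_max_ms Cap on the contact-detection input per event (25 ms).
#' @param theta_decay Base-spring equilibrium decay rate (0.93).
#' @param whisk_setpoint Whisking set point in radians (default 25 degrees):
#'   the mean protraction angle about which the whisker oscillates while the
#'   pattern generator is on, placing the whisk field against the wall so
#'   that touch epochs are sustained rather than grazing.
#' @param f_whisk Whisking frequency in Hz (10).
#' @param cpg_damp Damping rate of the whisking oscillator (0.98 per second).
#' @param cpg_sigma Oscillator noise amplitude (per sqrt(second)); the default
#'   gives a whisking amplitude of roughly 25 degrees (s.d.), comparable to
#'   free whisking.
#' @param noise_sigma Neural noise amplitude per sqrt(network time unit);
#'   the default 1/sqrt(2) reproduces unit-variance noise per printed Euler
#'   step.
#' @param dt Euler step in seconds (5e-4, i.e. 0.5 ms).
#' @param time_unit_scale Seconds per network time unit (calibration
#'   constant).
#' @return An object of class \code{"network_params"}.
#' @export
network_params <- function(N = 100L, p = 0.1, g0 = 0.05,
                           target_eigenvalue = 0.975,
                           w_x_theta = 0.002, w_theta_x = 0.085,
                           adapt_decay = 0.07, adapt_gain = 0.008,
                           input_amp = 0.035, pulse_max_ms = 25,
                           theta_decay = 0.93, whisk_setpoint = 25 * pi / 180,
                           f_whisk = 10,
                           cpg_damp = 0.98, cpg_sigma = 0.8,
                           noise_sigma = 1 / sqrt(2), dt = 5e-4,
                           time_unit_scale = 0.0126) {
  stopifnot(N >= 2L, p > 0, p < 1, dt > 0, time_unit_scale > 0,
            adapt_decay > 0, theta_decay > 0, cpg_damp > 0, f_whisk > 0,
            pulse_max_ms > 0, g0 >= 0, target_eigenvalue > 0)
  structure(as.list(environment()), class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("Cortex-vibrissa network parameters: 2N = %d neurons, p = %g, g0 = %g\n",
              2L * x$N, x$p, x$g0))
  cat(sprintf("  target eigenvalue %g, whisking %g Hz, dt = %g ms, time unit = %g ms\n",
              x$target_eigenvalue, x$f_whisk, x$dt * 1e3,
              x$time_unit_scale * 1e3))
  invisible(x)
}

# assemble the connectivity from binary masks with unit b0:
# excitatory columns b*J + b'*g, inhibitory columns -b''*g, J = 1/(pN).
# The balanced-component scale g is normalised so the random part of the
# spectrum forms a disc of radius b0*g0 regardless of N and p:
# g = g0 / sqrt(2*N*p*(1-p)).
assemble_connectivity <- function(masks, params) {
  N <- params$N
  J <- 1 / (params$p * N)
  g <- params$g0 / sqrt(2 * N * params$p * (1 - params$p))
  exc <- masks$b * J + masks$b_prime * g
  inh <- -masks$b_dprime * g
  cbind(exc, inh)
}

#' Calibrate the connectivity scale to the target leading eigenvalue
#'
#' The assembled connectivity is linear in the mask value \code{b0}, so its
#' spectrum scales exactly with \code{b0}; the calibrated scale is the target
#' eigenvalue divided by the largest real part of the unit-scale spectrum.
#' The result is verified by re-solving the eigenproblem.
#'
#' @param unit_matrix Connectivity assembled with \code{b0 = 1}.
#' @param target Target leading eigenvalue (largest real part).
#' @param tol Verification tolerance (default 5e-3).
#' @return The calibrated scale \code{b0}.
#' @export
calibrate_b0 <- function(unit_matrix, target, tol = 5e-3) {
  lead <- max(Re(eigen(unit_matrix, only.values = TRUE)$values))
  if (lead <= 0) stop("unit-scale matrix has no positive leading eigenvalue",
                      call. = FALSE)
  b0 <- target / lead
  check <- max(Re(eigen(b0 * unit_matrix, only.values = TRUE)$values))
  if (abs(check - target) > tol) {
    stop("calibration failed: achieved ", format(check), " vs target ",
         target, call. = FALSE)
  }
  b0
}

#' Build a calibrated cortical network
#'
#' Draws independent binary connection masks with probability \code{p},
#' assembles excitatory columns as \code{b0*(J + g)} masks and inhibitory
#' columns as \code{-b0*g} masks, and calibrates \code{b0} so the leading
#' eigenvalue equals \code{target_eigenvalue}.
#'
#' @param params A \code{\link{network_params}} object.
#' @param seed Integer seed for the mask draw.
#' @return An object of class \code{"cortical_network"} with elements
#'   \code{W} (2N x 2N weights), \code{b0}, \code{lead_eigenvalue},
#'   \code{params}, \code{seed}.
#' @export
build_network <- function(params = network_params(), seed = NULL) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N
  masks <- with_seed(seed, list(
    b = matrix(stats::rbinom(N * 2 * N, 1L, params$p), 2 * N, N),
    b_prime = matrix(stats::rbinom(N * 2 * N, 1L, params$p), 2 * N, N),
    b_dprime = matrix(stats::rbinom(N * 2 * N, 1L, params$p), 2 * N, N)))
  unit <- assemble_connectivity(masks, params)
  b0 <- calibrate_b0(unit, params$target_eigenvalue)
  W <- b0 * unit
  structure(list(W = W, b0 = b0,
                 lead_eigenvalue = max(Re(eigen(W, only.values = TRUE)$values)),
                 params = params, seed = seed),
            class = "cortical_network")
}

#' @export
print.cortical_network <- function(x, ...) {
  cat(sprintf("<cortical_network> %d neurons, b0 = %.4g, leading eigenvalue %.4f\n",
              nrow(x$W), x$b0, x$lead_eigenvalue))
  invisible(x)
}

#' Whisker mechanical parameters
#'
#' Two massless hinged sections of unit length: a base torsion spring of
#' constant \code{k1} drives the protraction angle toward its equilibrium and
#' a center spring of constant \code{k2} aligns the two sections. Only the
#' ratio \code{k2/k1} matters; a horizontal frictionless wall of height
#' \code{wall_height} section lengths constrains the tip.
#'
#' @param k1 Base spring constant (default 1).
#' @param k2 Center (bending) spring constant; \code{k2/k1} of 0.1, 1 and 10
#'   span flexible to stiff whiskers.
#' @param wall_height Wall height in section lengths (default 1).
#' @return An object of class \code{"whisker_params"}.
#' @export
whisker_params <- function(k1 = 1, k2 = 1, wall_height = 1) {
  stopifnot(k1 > 0, k2 > 0, wall_height > 0, wall_height <= 2)
  structure(list(k1 = k1, k2 = k2, wall_height = wall_height),
            class = "whisker_params")
}

#' Solve the whisker configuration
#'
#' Minimizes the whisker energy \eqn{E = k_1(\theta_p - \theta_{eq})^2 +
#' (k_2/2)\theta_h^2} subject to the wall constraint
#' \eqn{\sin\theta_p + \sin(\theta_p - \theta_h) \le wall\_height}. When the
#' unconstrained minimum \eqn{(\theta_{eq}, 0)} satisfies the constraint it
#' is returned with \code{in_contact = FALSE}; otherwise the constrained
#' minimizer (constraint active) is found by a one-dimensional search along
#' the contact manifold.
#'
#' @param theta_eq Base-spring equilibrium angle (radians).
#' @param wp A \code{\link{whisker_params}} object.
#' @return List with \code{theta_p}, \code{theta_h} (radians) and
#'   \code{in_contact}.
#' @export
whisker_solve <- function(theta_eq, wp = whisker_params()) {
  stopifnot(is.finite(theta_eq))
  out <- .whisker_solve_cpp(theta_eq, wp$k1, wp$k2, wp$wall_height, TRUE)
  list(theta_p = unname(out[1L]), theta_h = unname(out[2L]),
       in_contact = out[3L] > 0)
}

condition_flags <- function(condition) {
  switch(condition,
         open = list(cpg_on = FALSE, feedback_on = FALSE, wall_on = FALSE),
         closed = list(cpg_on = TRUE, feedback_on = TRUE, wall_on = FALSE),
         touch = list(cpg_on = TRUE, feedback_on = TRUE, wall_on = TRUE),
         stop("unknown condition: ", condition, call. = FALSE))
}

#' Run the cortex-vibrissa model in a behavioural condition
#'
#' Conditions: \code{"open"} (quiet attentive: pattern generator off and
#' whisker feedback removed by setting the whisker-to-neuron weight to zero),
#' \code{"closed"} (free whisking: pattern generator and feedback on, no
#' wall) and \code{"touch"} (whisking against the wall: as closed plus the
#' wall constraint and contact-detection input).
#'
#' @param network A \code{\link{build_network}} result.
#' @param condition One of \code{"open"}, \code{"closed"}, \code{"touch"}.
#' @param duration Simulated time in seconds.
#' @param seed Integer seed for all noise sources.
#' @param wp \code{\link{whisker_params}}; the stiffness ratio
#'   \code{k2/k1} controls how strongly contact clamps protraction.
#' @param ext_input Optional per-step external input vector (length
#'   \code{duration/dt}) added to every neuron, for passive-deflection
#'   protocols.
#' @param out_dt Output sampling interval in seconds (default 1 ms).
#' @param n_keep Number of individual neuron traces to store (default 20,
#'   the first \code{n_keep/2} excitatory and inhibitory neurons).
#' @param burn_in Seconds simulated and discarded before recording starts
#'   (default 5).
#' @param flags Optional named list overriding the condition flag mapping
#'   (\code{cpg_on}, \code{feedback_on}, \code{wall_on}).
#' @param state Optional initial state (as returned in a recording's
#'   \code{state}); defaults to rest.
#' @return An object of class \code{"sim_recording"}: subsampled traces
#'   (\code{pop_mean}, \code{x_keep}, \code{theta_p}, \code{theta_h},
#'   \code{theta_eq}, \code{contact_input}), contact-event table
#'   \code{contacts} (seconds, relative to recording start), \code{dt_out},
#'   condition label, parameters and final \code{state}.
#' @export
run_condition <- function(network, condition = c("open", "closed", "touch"),
                          duration = 50, seed = NULL,
                          wp = whisker_params(), ext_input = NULL,
                          out_dt = 1e-3, n_keep = 20L, burn_in = 5,
                          flags = list(), state = NULL) {
  stopifnot(inherits(network, "cortical_network"))
  condition <- match.arg(condition)
  p <- network$params
  fl <- utils::modifyList(condition_flags(condition), flags)
  n2 <- 2L * p$N
  n_burn <- round(burn_in / p$dt)
  n_rec <- round(duration / p$dt)
  out_every <- max(1L, round(out_dt / p$dt))
  if (is.null(ext_input)) ext_input <- numeric(n_rec)
  stopifnot(length(ext_input) == n_rec)
  keep_idx <- c(seq_len(min(n_keep %/% 2L + n_keep %% 2L, p$N)),
                p$N + seq_len(min(n_keep %/% 2L, p$N)))
  if (is.null(state)) {
    state <- list(x = numeric(n2), a = numeric(n2), theta_eq = 0,
                  u = 0, v = 0)
  }
  run <- with_seed(seed, {
    if (n_burn > 0L) {
      warm <- .sim_run_cpp(network$W, p$N, state$x, state$a, state$theta_eq,
                           state$u, state$v, n_burn, p$dt, p$time_unit_scale,
                           p$w_x_theta, p$w_theta_x, p$adapt_decay,
                           p$adapt_gain, p$input_amp, p$pulse_max_ms,
                           p$theta_decay, p$whisk_setpoint, p$f_whisk,
                           p$cpg_damp, p$cpg_sigma,
                           p$noise_sigma, 180 / pi, wp$k1, wp$k2,
                           wp$wall_height, fl$cpg_on, fl$feedback_on,
                           fl$wall_on, numeric(n_burn), n_burn, keep_idx)
      state <- warm$state
    }
    .sim_run_cpp(network$W, p$N, state$x, state$a, state$theta_eq,
                 state$u, state$v, n_rec, p$dt, p$time_unit_scale,
                 p$w_x_theta, p$w_theta_x, p$adapt_decay, p$adapt_gain,
                 p$input_amp, p$pulse_max_ms, p$theta_decay, p$whisk_setpoint, p$f_whisk,
                 p$cpg_damp, p$cpg_sigma, p$noise_sigma, 180 / pi,
                 wp$k1, wp$k2, wp$wall_height, fl$cpg_on, fl$feedback_on,
                 fl$wall_on, ext_input, out_every, keep_idx)
  })
  contacts <- data.frame(
    onset = run$contact_onsets * p$dt,
    offset = run$contact_offsets * p$dt,
    pulse_steps = run$contact_pulse_steps)
  structure(list(pop_mean = as.numeric(run$pop_mean), x_keep = run$x_keep,
                 theta_p = as.numeric(run$theta_p),
                 theta_h = as.numeric(run$theta_h),
                 theta_eq = as.numeric(run$theta_eq), u = as.numeric(run$u),
                 contact_input = as.numeric(run$contact_input),
                 contacts = contacts,
                 total_pulse_steps = run$total_pulse_steps,
                 dt_out = out_every * p$dt, condition = condition,
                 duration = duration, params = p, wp = wp, seed = seed,
                 flags = fl, state = run$state),
            class = "sim_recording")
}

#' @export
print.sim_recording <- function(x, ...) {
  cat(sprintf("<sim_recording> %s condition, %.3g s at %g ms resolution, %d contact event(s)\n",
              x$condition, x$duration, x$dt_out * 1e3, nrow(x$contacts)))
  invisible(x)
}

# extract event-aligned windows (trial x neuron x time) from a recording
aligned_windows <- function(rec, onsets_s, pre_s, post_s) {
  dt <- rec$dt_out
  i_pre <- round(pre_s / dt); i_post <- round(post_s / dt)
  n <- length(rec$pop_mean)
  keep <- onsets_s / dt > i_pre + 1 & onsets_s / dt + i_post <= n
  onsets_s <- onsets_s[keep]
  if (!length(onsets_s)) stop("no usable event windows", call. = FALSE)
  arr <- array(NA_real_, c(length(onsets_s), ncol(rec$x_keep),
                           i_pre + i_post + 1L))
  for (k in seq_along(onsets_s)) {
    i0 <- round(onsets_s[k] / dt)
    arr[k, , ] <- t(rec$x_keep[(i0 - i_pre):(i0 + i_post), , drop = FALSE])
  }
  attr(arr, "times_ms") <- seq(-i_pre, i_post) * dt * 1e3
  arr
}

#' Passive whisker-deflection trials
#'
#' Injects brief square input pulses (amplitude \code{input_amp}, duration
#' \code{pulse_ms}) into all neurons at regularly spaced, phase-randomized
#' times during an open- or closed-loop run, and returns event-aligned
#' membrane responses together with matched no-event windows from a separate
#' run of the same condition.
#'
#' @param network A \code{\link{build_network}} result.
#' @param condition \code{"open"} or \code{"closed"}.
#' @param n_trials Number of pulses (default 50).
#' @param seed Integer seed.
#' @param amp Pulse amplitude; defaults to the network's \code{input_amp}.
#' @param pulse_ms Pulse duration in ms (default 25).
#' @param spacing Mean inter-pulse interval in seconds (default 1.6).
#' @param pre,post Aligned window before/after onset in seconds.
#' @param wp,n_keep Passed to \code{\link{run_condition}}.
#' @return List of class \code{"aligned_trials"}: arrays \code{with_event}
#'   and \code{without_event} (trial x neuron x time), \code{times_ms},
#'   \code{mean_response} (event-mean of the neuron-average deviation from
#'   pre-onset baseline), \code{onsets}.
#' @export
passive_deflection_trials <- function(network, condition = c("closed", "open"),
                                      n_trials = 50L, seed = NULL,
                                      amp = NULL, pulse_ms = 25,
                                      spacing = 1.6, pre = 0.2, post = 1,
                                      wp = whisker_params(), n_keep = 20L) {
  condition <- match.arg(condition)
  p <- network$params
  if (is.null(amp)) amp <- p$input_amp
  dur <- (n_trials + 1) * spacing
  n_steps <- round(dur / p$dt)
  jitter <- with_seed(seed, stats::runif(n_trials, 0, spacing / 2))
  onsets <- pre + 0.1 + (seq_len(n_trials) - 1) * spacing + jitter
  ext <- numeric(n_steps)
  pl <- round(pulse_ms / 1e3 / p$dt)
  for (o in onsets) {
    i0 <- round(o / p$dt)
    ext[i0:min(i0 + pl - 1L, n_steps)] <- amp
  }
  seed2 <- if (is.null(seed)) NULL else seed + 1000003L
  rec1 <- run_condition(network, condition, duration = dur, seed = seed,
                        wp = wp, ext_input = ext, n_keep = n_keep)
  rec0 <- run_condition(network, condition, duration = dur, seed = seed2,
                        wp = wp, n_keep = n_keep)
  w1 <- aligned_windows(rec1, onsets, pre, post)
  w0 <- aligned_windows(rec0, onsets, pre, post)
  times <- attr(w1, "times_ms")
  base <- apply(w1[, , times < 0, drop = FALSE], 1L, mean)
  resp <- sweep(apply(w1, c(1L, 3L), mean), 1L, base)
  structure(list(with_event = w1, without_event = w0, times_ms = times,
                 mean_response = colMeans(resp), onsets = onsets,
                 condition = condition),
            class = "aligned_trials")
}

#' Active-touch trials
#'
#' Runs the touch condition (whisking against the wall) and aligns membrane
#' responses at contact onsets; matched no-event windows are taken from a
#' closed-loop run (wall removed) at the same times. Contact onsets closer
#' than \code{refractory} seconds to the previous one are skipped.
#'
#' @inheritParams passive_deflection_trials
#' @param min_trials Error if fewer usable contact events than this.
#' @param refractory Minimum separation between used onsets (seconds).
#' @return An \code{"aligned_trials"} list as in
#'   \code{\link{passive_deflection_trials}}, plus \code{contacts}.
#' @export
active_touch_trials <- function(network, wp = whisker_params(k2 = 10),
                                n_trials = 50L, seed = NULL,
                                pre = 0.2, post = 1, min_trials = 20L,
                                refractory = 0.35, n_keep = 20L) {
  p <- network$params
  dur <- max(30, n_trials * 0.8)
  rec1 <- run_condition(network, "touch", duration = dur, seed = seed,
                        wp = wp, n_keep = n_keep)
  if (nrow(rec1$contacts) == 0L) {
    stop("no contact events detected; increase whisking drive (cpg_sigma) ",
         "or run duration", call. = FALSE)
  }
  on <- rec1$contacts$onset
  on <- on[on > pre + 0.05 & on < dur - post - 0.05]
  if (length(on) > 1L) {        # greedy thinning: next onset >= refractory
    kept <- on[1L]              # after the last kept one
    for (o in on[-1L]) if (o - kept[length(kept)] >= refractory) {
      kept <- c(kept, o)
    }
    on <- kept
  }
  if (length(on) < min_trials) {
    stop("only ", length(on), " usable contact events (need >= ", min_trials,
         "); increase duration or whisking drive", call. = FALSE)
  }
  on <- on[seq_len(min(length(on), n_trials))]
  seed2 <- if (is.null(seed)) NULL else seed + 2000003L
  rec0 <- run_condition(network, "closed", duration = dur, seed = seed2,
                        wp = wp, n_keep = n_keep)
  w1 <- aligned_windows(rec1, on, pre, post)
  w0 <- aligned_windows(rec0, on, pre, post)
  times <- attr(w1, "times_ms")
  base <- apply(w1[, , times < 0, drop = FALSE], 1L, mean)
  resp <- sweep(apply(w1, c(1L, 3L), mean), 1L, base)
  structure(list(with_event = w1, without_event = w0, times_ms = times,
                 mean_response = colMeans(resp), onsets = on,
                 contacts = rec1$contacts, condition = "touch"),
            class = "aligned_trials")
}

#' Condition summary metrics of a recording
#'
#' Low-frequency band power of the population mean, mean pairwise
#' inter-neuron correlation of the coherent slow component, and the
#' protraction-angle variance. Before computing correlations each neuron
#' trace is averaged over one whisk cycle (boxcar of width
#' \code{1/f_whisk}, a zero of the boxcar response), so the correlation
#' measures coherent low-frequency fluctuations rather than common locking
#' to the whisking cycle.
#'
#' @param rec A \code{\link{run_condition}} recording.
#' @param band Frequency band in Hz (default 1-5 Hz).
#' @param segment_s Welch segment length in seconds (default 8).
#' @return List with \code{band_power}, \code{mean_correlation},
#'   \code{theta_p_var}, \code{contact_fraction}.
#' @export
recording_metrics <- function(rec, band = c(1, 5), segment_s = 8) {
  fs <- 1 / rec$dt_out
  spec <- welch_psd(rec$pop_mean, fs,
                    segment_length = min(length(rec$pop_mean) %/% 2L,
                                         round(segment_s * fs)))
  w <- max(1L, round(fs / rec$params$f_whisk))
  sm <- apply(rec$x_keep, 2L, function(z)
    stats::filter(z, rep(1 / w, w), sides = 2L))
  sm <- sm[stats::complete.cases(sm), , drop = FALSE]
  cm <- correlation_matrix(sm)
  list(band_power = band_power(spec, band),
       mean_correlation = mean(cm[upper.tri(cm)]),
       theta_p_var = stats::var(rec$theta_p),
       contact_fraction = mean(rec$theta_h != 0))
}
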