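#' Parameters of the minimal brain-environment feedback model
#'
#' Bundles the parameters of the first-order linear stochastic model of
#' collective neural activity \eqn{B(t)}: a leaky integrator with leak time
#' constant \code{tau}, optional instantaneous self-feedback of strength
#' \code{w} mediated by the environment, endogenous white noise of
#' instantaneous variance \code{sigma^2}, and a schedule of exafferent input
#' pulses \eqn{I(t)}.
#'
#' The closed-loop model is stable only when \eqn{1 - w\tau > 0}; unstable
#' parameter sets are rejected at construction.
#'
#' @param tau Leak time constant (time units, > 0).
#' @param w Feedback strength (1/time units; negative values give suppressive
#'   reafferent feedback). Default 0 (open loop).
#' @param sigma Noise amplitude: the endogenous noise has instantaneous
#'   variance \code{sigma^2}. Default 1.
#' @param dt Euler integration step (time units). Default 0.01.
#' @param duration Total simulated time (>= \code{dt}). Default 100.
#' @param input Optional input schedule: a data frame with columns
#'   \code{start}, \code{stop}, \code{amp}; \eqn{I(t)} is the sum of the
#'   amplitudes of all pulses with \code{start <= t < stop}.
#' @return An object of class \code{"feedback_params"}.
#' @examples
#' p <- feedback_params(tau = 1.05, w = -0.5, sigma = 1)
#' analytic_summary(p)
#' @export
feedback_params <- function(tau, w = 0, sigma = 1, dt = 0.01,
                            duration = 100, input = NULL) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0)
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w))
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma), sigma >= 0)
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration >= dt)
  if (1 - w * tau <= 0) {
    stop("unstable feedback parameters: 1 - w*tau = ", format(1 - w * tau),
         " must be > 0", call. = FALSE)
  }
  if (!is.null(input)) {
    stopifnot(is.data.frame(input),
              all(c("start", "stop", "amp") %in% names(input)))
    stopifnot(all(input$stop >= input$start))
  }
  structure(list(tau = tau, w = w, sigma = sigma, dt = dt,
                 duration = duration, input = input),
            class = "feedback_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat("Feedback model parameters\n")
  cat(sprintf("  tau = %g, w = %g, sigma = %g (1 - w*tau = %g)\n",
              x$tau, x$w, x$sigma, 1 - x$w * x$tau))
  cat(sprintf("  dt = %g, duration = %g, %d input pulse(s)\n",
              x$dt, x$duration,
              if (is.null(x$input)) 0L else nrow(x$input)))
  invisible(x)
}

# exafferent input I(t) evaluated on a time grid
input_drive <- function(params, times) {
  drive <- numeric(length(times))
  if (!is.null(params$input)) {
    for (k in seq_len(nrow(params$input))) {
      on <- times >= params$input$start[k] & times < params$input$stop[k]
      drive[on] <- drive[on] + params$input$amp[k]
    }
  }
  drive
}

new_loop_ts <- function(values, dt, t0, label, ...) {
  out <- structure(list(values = values, dt = dt, t0 = t0, label = label),
                   class = "loop_ts")
  extras <- list(...)
  for (nm in names(extras)) attr(out, nm) <- extras[[nm]]
  out
}

#' @export
print.loop_ts <- function(x, ...) {
  cat(sprintf("<loop_ts> %s condition: %d samples, dt = %g (%.6g .. %.6g)\n",
              x$label, length(x$values), x$dt, x$t0,
              x$t0 + (length(x$values) - 1) * x$dt))
  invisible(x)
}

#' Time axis of a model trace
#' @param ts A \code{loop_ts} object.
#' @return Numeric vector of sample times.
#' @export
ts_times <- function(ts) ts$t0 + (seq_along(ts$values) - 1) * ts$dt

# run a seeded expression without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# first-order Euler recursion B[k+1] = a*B[k] + drive[k], vectorized
euler_recursion <- function(a, drive, b0 = 0) {
  n <- length(drive) + 1L
  out <- c(b0, as.numeric(stats::filter(drive, a, method = "recursive",
                                        init = b0)))
  bad <- which(!is.finite(out))
  if (length(bad)) {
    stop("simulation diverged: non-finite value at step ", bad[1L],
         " of ", n, call. = FALSE)
  }
  out
}

#' Simulate the open-loop condition
#'
#' Euler-forward integration of the leaky-integrator model
#' \eqn{dB = (-B/\tau + I(t))\,dt + \sigma\sqrt{dt}\,\xi},
#' with \eqn{\xi \sim N(0,1)} drawn independently at each step.
#'
#' @param params A \code{\link{feedback_params}} object.
#' @param seed Integer seed for the noise realization (NULL to use the current
#'   RNG state).
#' @param b0 Initial condition, default 0.
#' @return A \code{loop_ts} with label \code{"open"}.
#' @export
simulate_open <- function(params, seed = NULL, b0 = 0) {
  stopifnot(inherits(params, "feedback_params"))
  n <- round(params$duration / params$dt)
  times <- (seq_len(n) - 1) * params$dt
  drive <- params$dt * input_drive(params, times[-n]) +
    with_seed(seed, params$sigma * sqrt(params$dt) * stats::rnorm(n - 1L))
  vals <- euler_recursion(1 - params$dt / params$tau, drive, b0)
  new_loop_ts(vals, params$dt, 0, "open", params = params, seed = seed)
}

#' Simulate the closed-loop condition
#'
#' As \code{\link{simulate_open}} but with the reafferent self-feedback term
#' \eqn{+wB} added to the drift. The realized feedback input \eqn{wB_c(t)} is
#' stored in the \code{"feedback_input"} attribute so that it can later be
#' played back by \code{\link{simulate_replay}} without any re-derivation from
#' the trace.
#'
#' @inheritParams simulate_open
#' @return A \code{loop_ts} with label \code{"closed"} carrying the
#'   \code{feedback_input} attribute.
#' @export
simulate_closed <- function(params, seed = NULL, b0 = 0) {
  stopifnot(inherits(params, "feedback_params"))
  if (1 - params$w * params$tau <= 0) {
    stop("unstable feedback parameters", call. = FALSE)
  }
  n <- round(params$duration / params$dt)
  times <- (seq_len(n) - 1) * params$dt
  drive <- params$dt * input_drive(params, times[-n]) +
    with_seed(seed, params$sigma * sqrt(params$dt) * stats::rnorm(n - 1L))
  a <- 1 - params$dt * (1 / params$tau - params$w)
  vals <- euler_recursion(a, drive, b0)
  new_loop_ts(vals, params$dt, 0, "closed", params = params, seed = seed,
              feedback_input = params$w * vals)
}

#' Simulate the replay condition
#'
#' The feedback input recorded during a closed-loop run is replayed as
#' exafferent input to an identical model with a fresh realization of the
#' endogenous noise:
#' \eqn{dB_r = (-B_r/\tau + u(t) + I(t))\,dt + \sigma\sqrt{dt}\,\xi},
#' where \eqn{u(t)} is the recorded \eqn{wB_c(t)}.
#'
#' @inheritParams simulate_open
#' @param recorded_input Either a closed-loop \code{loop_ts} produced by
#'   \code{\link{simulate_closed}} (its stored feedback input is used) or a
#'   numeric vector of the recorded feedback term, one value per sample.
#' @return A \code{loop_ts} with label \code{"replay"}.
#' @export
simulate_replay <- function(params, recorded_input, seed = NULL, b0 = 0) {
  stopifnot(inherits(params, "feedback_params"))
  if (inherits(recorded_input, "loop_ts")) {
    if (!isTRUE(all.equal(recorded_input$dt, params$dt))) {
      stop("recorded_input dt (", recorded_input$dt,
           ") does not match params dt (", params$dt, ")", call. = FALSE)
    }
    rec <- attr(recorded_input, "feedback_input")
    if (is.null(rec)) {
      stop("recorded_input carries no feedback_input attribute; ",
           "pass a trace from simulate_closed()", call. = FALSE)
    }
  } else {
    rec <- as.numeric(recorded_input)
  }
  n <- round(params$duration / params$dt)
  if (length(rec) != n) {
    stop("recorded_input length (", length(rec),
         ") does not match round(duration/dt) = ", n, call. = FALSE)
  }
  times <- (seq_len(n) - 1) * params$dt
  drive <- params$dt * (input_drive(params, times[-n]) + rec[-n]) +
    with_seed(seed, params$sigma * sqrt(params$dt) * stats::rnorm(n - 1L))
  vals <- euler_recursion(1 - params$dt / params$tau, drive, b0)
  new_loop_ts(vals, params$dt, 0, "replay", params = params, seed = seed)
}

#' Closed-form stationary variances, gains and effective time constant
#'
#' Evaluates the analytic predictions of the minimal feedback model:
#' \deqn{Peak_o = \sigma^2\tau/2, \quad Peak_c = Peak_o/(1 - w\tau),}
#' \deqn{Peak_r = Peak_c + Peak_o \cdot 2w\tau/(w\tau - 2),}
#' \deqn{Gain_o = \tau, \quad Gain_c = \tau/(1 - w\tau), \quad
#'       \tau_{eff} = \tau/(1 - w\tau).}
#' The peaks are the stationary instantaneous variances (zero-lag
#' autocovariances) of the three conditions; the gains are the equilibrium
#' response per unit static input. For negative feedback (\eqn{w < 0}) the
#' ordering \eqn{Peak_c < Peak_o < Peak_r} always holds.
#'
#' @param params A \code{\link{feedback_params}} object.
#' @return A list of class \code{"theory_summary"} with elements
#'   \code{peak_open}, \code{peak_closed}, \code{peak_replay},
#'   \code{gain_open}, \code{gain_closed}, \code{tau_eff}.
#' @export
analytic_summary <- function(params) {
  stopifnot(inherits(params, "feedback_params"))
  tau <- params$tau; w <- params$w; s2 <- params$sigma^2
  if (1 - w * tau <= 0) stop("unstable feedback parameters", call. = FALSE)
  peak_o <- s2 * tau / 2
  peak_c <- peak_o / (1 - w * tau)
  peak_r <- peak_c + peak_o * 2 * w * tau / (w * tau - 2)
  structure(list(peak_open = peak_o, peak_closed = peak_c,
                 peak_replay = peak_r, gain_open = tau,
                 gain_closed = tau / (1 - w * tau),
                 tau_eff = tau / (1 - w * tau)),
            class = "theory_summary")
}

#' @export
print.theory_summary <- function(x, ...) {
  cat("Analytic summary of the minimal feedback model\n")
  cat(sprintf("  Peak (variance): open %.4g, closed %.4g, replay %.4g\n",
              x$peak_open, x$peak_closed, x$peak_replay))
  cat(sprintf("  Gain: open %.4g, closed %.4g;  tau_eff = %.4g\n",
              x$gain_open, x$gain_closed, x$tau_eff))
  invisible(x)
}

#' Stationary variance of a trace with a batch-means standard error
#'
#' Discards an initial burn-in and estimates the instantaneous variance of the
#' remaining samples. The standard error is obtained by batch means: the
#' post-burn-in stretch is split into contiguous batches, the sample variance
#' is computed within each batch, and the SE is the standard deviation of the
#' batch variances divided by \code{sqrt(n_batches)}.
#'
#' @param ts A \code{loop_ts} or numeric vector.
#' @param burn_in Time to discard from the start (same units as \code{dt}).
#'   Defaults to \code{10 * tau_eff} when the trace carries its generating
#'   parameters, otherwise 0.
#' @param n_batches Number of batches for the standard error (default 30).
#' @return A list with \code{estimate}, \code{se}, \code{n_used}.
#' @export
empirical_variance <- function(ts, burn_in = NULL, n_batches = 30L) {
  if (inherits(ts, "loop_ts")) {
    vals <- ts$values
    dt <- ts$dt
    if (is.null(burn_in)) {
      p <- attr(ts, "params")
      burn_in <- if (!is.null(p)) 10 * p$tau / (1 - p$w * p$tau) else 0
    }
    drop <- min(length(vals) - 1L, floor(burn_in / dt))
  } else {
    vals <- as.numeric(ts)
    drop <- if (is.null(burn_in)) 0L else as.integer(burn_in)
  }
  x <- vals[(drop + 1L):length(vals)]
  if (length(x) < 100L) {
    stop("too few samples after burn-in (", length(x), " < 100)",
         call. = FALSE)
  }
  n_batches <- max(2L, min(as.integer(n_batches), length(x) %/% 50L))
  batch <- cut(seq_along(x), n_batches, labels = FALSE)
  bvar <- tapply(x, batch, stats::var)
  list(estimate = stats::var(x),
       se = stats::sd(bvar) / sqrt(n_batches),
       n_used = length(x))
}
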