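#' Fit the afferent filter F (environment to brain, replay condition)
#'
#' Causal Laguerre-basis regression of the replay neural trace \code{B_r} on
#' the closed-loop swim power \code{E_c}: in the replay condition the neuron
#' is driven by the recorded stimulus with no loop closure, so ordinary least
#' squares identifies the afferent pathway without closed-loop bias.
#'
#' @param E_c Closed-loop swim-power series (replayed stimulus drive).
#' @param B_r Replay neural activity of one cell (same length).
#' @param fs Sampling rate in Hz.
#' @param ... Passed to \code{\link{fit_filter}} (e.g. \code{scales},
#'   \code{max_order}, \code{n_lags}).
#' @return A \code{basis_filter} (the afferent filter F).
#' @export
fit_afferent <- function(E_c, B_r, fs, ...) {
  fit_filter(E_c, B_r, family = "laguerre", dt = 1 / fs, ...)
}

#' Residual neural variability in the replay condition
#'
#' \eqn{R_{Br} = B_r - F * E_c}: the part of replay activity not driven by
#' the replayed stimulus. By the least-squares normal equations it is
#' orthogonal to every basis-convolved regressor used in the fit.
#'
#' @param B_r Replay neural trace.
#' @param F_filt The fitted afferent \code{basis_filter}.
#' @param E_c The stimulus series used in the fit.
#' @return Numeric residual series (full length).
#' @export
compute_residual <- function(B_r, F_filt, E_c) {
  stopifnot(inherits(F_filt, "basis_filter"), length(B_r) == length(E_c))
  B_r - as.numeric(basis_design(E_c, F_filt$basis) %*% F_filt$coefficients)
}

#' Fit the efferent filter G (brain to environment, replay condition)
#'
#' Causal Laguerre-basis regression of the replay swim power \code{E_r} on
#' the residual neural variability \code{R_Br}. Using the residual (rather
#' than \code{B_r} itself) removes the stimulus-driven component shared with
#' the environment, isolating how the cell's intrinsic activity drives
#' behaviour.
#'
#' @param R_Br Residual series from \code{\link{compute_residual}}.
#' @param E_r Replay swim-power series.
#' @param fs Sampling rate in Hz.
#' @param ... Passed to \code{\link{fit_filter}}.
#' @return A \code{basis_filter} (the efferent filter G).
#' @export
fit_efferent <- function(R_Br, E_r, fs, ...) {
  fit_filter(R_Br, E_r, family = "laguerre", dt = 1 / fs, ...)
}

#' Combine afferent and efferent filters into the feedback filter H
#'
#' \eqn{H(\omega) = F(\omega) G(\omega)} on a common frequency grid; the
#' time-domain kernel is the discrete convolution of the two kernels.
#'
#' @param F_filt,G_filt Fitted \code{basis_filter}s sharing \code{dt}.
#' @param freqs Frequency grid in Hz; default a uniform grid of
#'   \code{n_freq} points from 0 to Nyquist.
#' @param n_freq Number of grid points when \code{freqs} is NULL.
#' @return Object of class \code{"feedback_estimate"}: \code{freqs},
#'   complex \code{F}, \code{G}, \code{H}, \code{kernel} (of H),
#'   \code{lags}, \code{dt}.
#' @export
combine_feedback <- function(F_filt, G_filt, freqs = NULL, n_freq = 256L) {
  stopifnot(inherits(F_filt, "basis_filter"), inherits(G_filt, "basis_filter"))
  if (!isTRUE(all.equal(F_filt$dt, G_filt$dt))) {
    stop("filters have different sampling intervals", call. = FALSE)
  }
  dt <- F_filt$dt
  if (is.null(freqs)) freqs <- seq(0, 1 / (2 * dt), length.out = n_freq)
  Fw <- freq_response(F_filt, freqs)
  Gw <- freq_response(G_filt, freqs)
  kern <- stats::convolve(F_filt$kernel, rev(G_filt$kernel), type = "open")
  lags <- (seq_along(kern) - 1L) * dt + F_filt$lags[1L] + G_filt$lags[1L]
  structure(list(freqs = freqs, F = Fw, G = Gw, H = Fw * Gw,
                 kernel = kern, lags = lags, dt = dt),
            class = "feedback_estimate")
}

#' @export
print.feedback_estimate <- function(x, ...) {
  cat(sprintf("<feedback_estimate> H on %d frequencies 0..%.4g Hz, net H(0) = %.4g\n",
              length(x$freqs), max(x$freqs), Re(x$H[1L])))
  invisible(x)
}

resolve_H <- function(H, freqs) {
  if (inherits(H, "feedback_estimate")) list(H = H$H, freqs = H$freqs)
  else {
    stopifnot(!is.null(freqs), length(H) == length(freqs))
    list(H = as.complex(H), freqs = freqs)
  }
}

#' Predicted closed/replay power ratio from the feedback filter
#'
#' Under the closed-loop model \eqn{B_c = (1-H)^{-1} R_{Bc}} and the replay
#' model \eqn{B_r = H B_c + R_{Br}}, with equal residual spectra in the two
#' conditions, the power ratio is
#' \deqn{\frac{|B_c|^2}{|B_r|^2} = \frac{1}{|H|^2 + |1-H|^2}.}
#' Negative (suppressive) feedback gives ratios below one.
#'
#' @param H A \code{feedback_estimate} or complex vector.
#' @param freqs Frequency grid (Hz) when \code{H} is a vector.
#' @param band Optional band \code{c(f_lo, f_hi)} over which to average.
#' @param weights Optional spectral weights on the grid (e.g. the replay
#'   power spectrum): an observed ratio of band powers is the
#'   denominator-spectrum-weighted mean of the pointwise ratio, so weighted
#'   band means are the quantity comparable to data.
#' @return List with \code{freqs}, \code{ratio} (pointwise), \code{band_mean}
#'   (NULL without a band) and \code{unstable} (TRUE when \eqn{|1-H|}
#'   approaches zero anywhere on the grid, or in the band if given).
#' @export
predicted_power_ratio <- function(H, freqs = NULL, band = NULL,
                                  weights = NULL) {
  hh <- resolve_H(H, freqs)
  denom <- Mod(hh$H)^2 + Mod(1 - hh$H)^2
  ratio <- 1 / denom
  out <- list(freqs = hh$freqs, ratio = ratio, band_mean = NULL,
              unstable = any(Mod(1 - hh$H) < 1e-3))
  if (!is.null(band)) {
    keep <- hh$freqs >= band[1L] & hh$freqs <= band[2L]
    if (!any(keep)) stop("band contains no grid frequencies", call. = FALSE)
    w <- if (is.null(weights)) rep(1, sum(keep)) else weights[keep]
    out$band_mean <- sum(ratio[keep] * w) / sum(w)
    out$unstable <- any(Mod(1 - hh$H[keep]) < 1e-3)
  }
  out
}

#' Single-cycle approximation of the power ratio
#'
#' Truncating the geometric expansion \eqn{B_c = (1 + H + H^2 + \dots)R_{Bc}}
#' after one cycle of feedback gives \eqn{B_1 = (1+H) R_{Bc}} and the
#' one-cycle ratio (default variant)
#' \deqn{\frac{|B_1|^2}{|B_r|^2} = \frac{1}{|H|^2 + |1+H|^{-2}},}
#' obtained by substituting \eqn{B_1} for \eqn{B_c} in the replay drive.
#' The alternative \code{"numerator"} variant substitutes \eqn{B_1} only in
#' the numerator: \eqn{|1+H|^2 |1-H|^2 / (|H|^2 + |1-H|^2)}. Comparing either
#' against the full prediction quantifies the contribution of repeated
#' cycles of feedback.
#'
#' @inheritParams predicted_power_ratio
#' @param variant \code{"direct"} (default) or \code{"numerator"}.
#' @return As \code{\link{predicted_power_ratio}}.
#' @export
single_cycle_ratio <- function(H, freqs = NULL, band = NULL,
                               weights = NULL,
                               variant = c("direct", "numerator")) {
  variant <- match.arg(variant)
  hh <- resolve_H(H, freqs)
  ratio <- if (variant == "direct") {
    1 / (Mod(hh$H)^2 + Mod(1 + hh$H)^-2)
  } else {
    Mod(1 + hh$H)^2 * Mod(1 - hh$H)^2 / (Mod(hh$H)^2 + Mod(1 - hh$H)^2)
  }
  out <- list(freqs = hh$freqs, ratio = ratio, band_mean = NULL,
              unstable = any(Mod(1 + hh$H) < 1e-3))
  if (!is.null(band)) {
    keep <- hh$freqs >= band[1L] & hh$freqs <= band[2L]
    if (!any(keep)) stop("band contains no grid frequencies", call. = FALSE)
    w <- if (is.null(weights)) rep(1, sum(keep)) else weights[keep]
    out$band_mean <- sum(ratio[keep] * w) / sum(w)
  }
  out
}

#' Fit the naive afferent filter (closed-loop condition, two-sided)
#'
#' Hermite-basis regression of the closed-loop neural trace \code{B_c} on
#' the closed-loop swim power \code{E_c}, ignoring the loop. Because brain
#' and environment interact mutually in the closed loop, this filter
#' generally has an acausal (negative-lag) component and differs from the
#' true afferent filter.
#'
#' @param E_c Closed-loop swim power.
#' @param B_c Closed-loop neural activity of one cell.
#' @param fs Sampling rate in Hz.
#' @param ... Passed to \code{\link{fit_filter}}.
#' @return A two-sided \code{basis_filter}.
#' @export
fit_naive_afferent <- function(E_c, B_c, fs, ...) {
  fit_filter(E_c, B_c, family = "hermite", dt = 1 / fs, ...)
}

#' Theoretical prediction of the naive afferent filter
#'
#' From the closed-loop relations, the naive environment-to-brain filter is
#' \deqn{F(\omega) + \left(\frac{G(\omega)}{1-H(\omega)}\right)^{\!*}
#' \frac{|R_{Bc}(\omega)|^2}{|E_c(\omega)|^2},}
#' where the unobservable closed-loop residual spectrum is approximated by
#' the replay residual spectrum \eqn{|R_{Br}|^2}.
#'
#' @param fe A \code{\link{combine_feedback}} estimate, evaluated on the
#'   spectra's frequency grid (pass \code{freqs = spec$freqs} when building
#'   it), or a list with complex \code{F}, \code{G}, \code{H}, \code{freqs}.
#' @param S_RBr Spectrum of the replay residual (\code{spectrum_estimate} or
#'   numeric power on the same grid).
#' @param S_Ec Spectrum of the closed-loop swim power (same grid).
#' @param mask_rel Bins with \code{S_Ec} below \code{mask_rel * max(S_Ec)}
#'   are masked (NA) and reported in the \code{"masked_bins"} attribute.
#' @return List with \code{freqs}, complex \code{values} and a
#'   \code{kernel_fun(lags)} closure performing the inverse transform.
#' @export
predict_naive_afferent <- function(fe, S_RBr, S_Ec, mask_rel = 1e-8) {
  sr <- if (inherits(S_RBr, "spectrum_estimate")) S_RBr$power else
    as.numeric(S_RBr)
  se <- if (inherits(S_Ec, "spectrum_estimate")) S_Ec$power else
    as.numeric(S_Ec)
  stopifnot(length(sr) == length(se), length(se) == length(fe$freqs))
  vals <- fe$F + Conj(fe$G / (1 - fe$H)) * sr / se
  masked <- which(se < mask_rel * max(se))
  vals[masked] <- NA_complex_
  out <- list(freqs = fe$freqs, values = vals, dt = fe$dt)
  attr(out, "masked_bins") <- masked
  out$kernel_fun <- function(lags) {
    ok <- !is.na(vals)
    freq_to_kernel(fe$freqs[ok], vals[ok], lags, fe$dt)
  }
  out
}

#' Prediction error ratio for the naive afferent filter
#'
#' Compares, on a common lag grid, the mean square error between the
#' theoretical prediction and the fitted naive filter
#' (\eqn{R_{prediction}}) with the mean square error between the replay
#' afferent filter and the naive filter (\eqn{R_{naive}}). Ratios below one
#' indicate that accounting for the closed loop explains the naive filter
#' better than the afferent filter alone.
#'
#' @param naive_fit The fitted two-sided \code{basis_filter}.
#' @param prediction Result of \code{\link{predict_naive_afferent}} (or a
#'   numeric kernel on the naive filter's lags).
#' @param F_filt The causal afferent \code{basis_filter}.
#' @param project Compare within the naive fit's own basis (default TRUE):
#'   both candidates are projected onto the basis functions the naive
#'   estimate was allowed to use, so the comparison is not confounded by
#'   structure that estimate could never express. Set FALSE for raw
#'   kernel-grid mean square errors.
#' @return List with \code{ratio}, \code{R_prediction}, \code{R_naive}.
#' @export
prediction_error_ratio <- function(naive_fit, prediction, F_filt,
                                   project = TRUE) {
  lags <- naive_fit$lags
  pred_k <- if (is.numeric(prediction)) prediction else
    prediction$kernel_fun(lags)
  f_k <- numeric(length(lags))
  idx <- match(round(lags / F_filt$dt), round(F_filt$lags / F_filt$dt))
  f_k[!is.na(idx)] <- F_filt$kernel[idx[!is.na(idx)]]
  if (project && naive_fit$order > 0L) {
    B <- naive_fit$basis    # orthonormal columns on the lag grid
    pred_k <- as.numeric(B %*% crossprod(B, pred_k))
    f_k <- as.numeric(B %*% crossprod(B, f_k))
  }
  r_pred <- mean((pred_k - naive_fit$kernel)^2)
  r_naive <- mean((f_k - naive_fit$kernel)^2)
  if (r_naive == 0) {
    stop("R_naive is zero: naive and afferent filters coincide",
         call. = FALSE)
  }
  list(ratio = r_pred / r_naive, R_prediction = r_pred, R_naive = r_naive)
}

#' Behavioural feedback filter between replay and closed-loop swim power
#'
#' Fits a two-sided filter describing how fluctuations of one condition's
#' swim power map onto the other's; with suppressive sensorimotor feedback
#' its kernel is net negative. The default regresses \code{E_c} on
#' \code{E_r}.
#'
#' @param E_r,E_c Replay and closed-loop swim-power series.
#' @param fs Sampling rate in Hz.
#' @param direction \code{"r_to_c"} (default: \code{E_r} drives the
#'   regression of \code{E_c}) or \code{"c_to_r"}.
#' @param ... Passed to \code{\link{fit_filter}}.
#' @return A two-sided \code{basis_filter}.
#' @export
behavioural_feedback <- function(E_r, E_c, fs,
                                 direction = c("r_to_c", "c_to_r"), ...) {
  direction <- match.arg(direction)
  if (direction == "r_to_c") {
    fit_filter(E_r, E_c, family = "hermite", dt = 1 / fs, ...)
  } else {
    fit_filter(E_c, E_r, family = "hermite", dt = 1 / fs, ...)
  }
}

#' Full closed-loop filter analysis of a paired session
#'
#' Runs the whole identification pipeline for every cell of a paired
#' closed-loop/replay session: gain-block mean subtraction, afferent fit
#' (\code{E_c} to \code{B_r}), residual, efferent fit (residual to
#' \code{E_r}), feedback filter \code{H = F G}, observed and predicted
#' closed/replay low-frequency power ratios (full and single-cycle), naive
#' afferent fit and its theoretical prediction, and the prediction error
#' ratio.
#'
#' @param session A \code{session_recording} (see
#'   \code{\link{simulate_session}}) or a list with matrices \code{B_c},
#'   \code{B_r} (time x cell), vectors \code{E_c}, \code{E_r}, sampling rate
#'   \code{fs} and gain-block start indices \code{blocks}.
#' @param band Low-frequency band in Hz (default \code{c(0.01, 0.15)}).
#' @param segment_length Welch segment length (samples) for the band-power
#'   ratios; default the longest power of two not exceeding half the
#'   series, so that the low-frequency band is resolved.
#' @param spectra_segment Shorter Welch segment length used for the spectra
#'   entering the naive-filter prediction (default 32 samples): the
#'   prediction divides two spectral estimates, so bias-variance favours
#'   heavier averaging there.
#' @param max_order Maximum basis order for all fits.
#' @param n_lags Kernel support in lag samples for all fits (per side for
#'   the two-sided naive fit); defaults to about 6 s of lags, the scale on
#'   which the estimated sensorimotor kernels live.
#' @param cells Optional subset of cell indices.
#' @return A list of class \code{"session_analysis"}: \code{report} (one row
#'   per cell: net filter areas, observed/predicted/single-cycle band
#'   ratios, prediction error ratio, AIC orders) and \code{fits} (per-cell
#'   list of filter objects).
#' @export
analyze_session <- function(session, band = c(0.01, 0.15),
                            segment_length = NULL, spectra_segment = 32L,
                            max_order = 15L, n_lags = NULL,
                            cells = NULL) {
  fs <- session$fs
  B_c <- block_demean(as.matrix(session$B_c), session$blocks)
  B_r <- block_demean(as.matrix(session$B_r), session$blocks)
  E_c <- block_demean(as.numeric(session$E_c), session$blocks)
  E_r <- block_demean(as.numeric(session$E_r), session$blocks)
  n <- length(E_c)
  if (is.null(segment_length)) {
    segment_length <- 2^floor(log2(n / 2))
  }
  if (is.null(n_lags)) n_lags <- max(8L, round(6 * fs))
  if (is.null(cells)) cells <- seq_len(ncol(B_c))
  S_Ec <- welch_psd(E_c, fs, spectra_segment)
  rows <- list(); fits <- list()
  for (ci in cells) {
    Ff <- fit_afferent(E_c, B_r[, ci], fs, max_order = max_order,
                       n_lags = n_lags)
    R_Br <- compute_residual(B_r[, ci], Ff, E_c)
    Gf <- fit_efferent(R_Br, E_r, fs, max_order = max_order,
                       n_lags = n_lags)
    fe <- combine_feedback(Ff, Gf, freqs = S_Ec$freqs)
    sp_c <- welch_psd(B_c[, ci], fs, segment_length)
    sp_r <- welch_psd(B_r[, ci], fs, segment_length)
    w_r <- stats::approx(sp_r$freqs, sp_r$power, xout = S_Ec$freqs,
                         rule = 2)$y
    pred <- predicted_power_ratio(fe, band = band, weights = w_r)
    one <- single_cycle_ratio(fe, band = band, weights = w_r)
    obs_ratio <- band_power(sp_c, band) / band_power(sp_r, band)
    S_RBr <- welch_psd(R_Br, fs, spectra_segment)
    naive <- fit_naive_afferent(E_c, B_c[, ci], fs, max_order = max_order,
                                n_lags = n_lags)
    naive_pred <- predict_naive_afferent(fe, S_RBr, S_Ec)
    per <- tryCatch(prediction_error_ratio(naive, naive_pred, Ff),
                    error = function(e) list(ratio = NA_real_))
    rows[[length(rows) + 1L]] <- data.frame(
      cell = ci,
      net_F = filter_area(Ff), net_G = filter_area(Gf),
      net_F_se = Ff$net_area_se * Ff$dt,
      net_G_se = Gf$net_area_se * Gf$dt,
      net_H = Re(fe$H[1L]),
      order_F = Ff$order, order_G = Gf$order, order_naive = naive$order,
      observed_ratio = obs_ratio,
      predicted_ratio = pred$band_mean,
      single_cycle_ratio = one$band_mean,
      prediction_error_ratio = per$ratio,
      unstable = pred$unstable)
    fits[[as.character(ci)]] <- list(F = Ff, G = Gf, feedback = fe,
                                     naive = naive, naive_pred = naive_pred,
                                     R_Br = R_Br)
  }
  structure(list(report = do.call(rbind, rows), fits = fits,
                 band = band, fs = fs),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  r <- x$report
  cat(sprintf("<session_analysis> %d cells, band %g-%g Hz\n",
              nrow(r), x$band[1L], x$band[2L]))
  cat(sprintf("  median observed ratio %.3f, predicted %.3f, error ratio %.3f\n",
              stats::median(r$observed_ratio),
              stats::median(r$predicted_ratio),
              stats::median(r$prediction_error_ratio)))
  invisible(x)
}
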