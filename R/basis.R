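#' Discrete Laguerre basis
#'
#' Orthonormal discrete Laguerre functions with pole \code{alpha}, generated
#' by the standard cascade: the first function is the impulse response of
#' \eqn{\sqrt{1-\alpha^2}/(1-\alpha z^{-1})} and each subsequent one is the
#' previous filtered by the all-pass \eqn{(z^{-1}-\alpha)/(1-\alpha z^{-1})}.
#' The functions are causal (zero for negative lags) and orthonormal on an
#' infinite lag grid; truncation to \code{n_lags} samples leaves them
#' orthonormal to high accuracy when \code{n_lags} is large compared with the
#' memory \eqn{1/(1-\alpha)}.
#'
#' @param order Number of basis functions (1..15).
#' @param alpha Pole of the generating filter, in (0, 1); larger values give
#'   slower kernels.
#' @param n_lags Number of lag samples (support of the kernel).
#' @param dt Sample interval in seconds (metadata only).
#' @return An \code{n_lags x order} matrix with attributes \code{lags}
#'   (seconds), \code{family}, \code{scale}, \code{dt}.
#' @export
laguerre_basis <- function(order, alpha, n_lags, dt = 1) {
  stopifnot(order >= 1L, order <= 15L, alpha > 0, alpha < 1, n_lags >= order)
  B <- matrix(0, n_lags, order)
  B[, 1L] <- sqrt(1 - alpha^2) * alpha^(0:(n_lags - 1L))
  if (order > 1L) {
    for (j in 2:order) {
      x <- B[, j - 1L]
      u <- c(0, x[-n_lags]) - alpha * x       # (z^-1 - alpha) x
      B[, j] <- as.numeric(stats::filter(u, alpha, method = "recursive"))
    }
  }
  structure(B, lags = (0:(n_lags - 1L)) * dt, family = "laguerre",
            scale = alpha, dt = dt)
}

#' Hermite-function basis on a two-sided lag grid
#'
#' Gaussian-weighted Hermite polynomials
#' \eqn{h_k(t) \propto H_k(t/w)\,e^{-t^2/(2w^2)}} sampled on lags
#' \code{-n_lags_each_side..n_lags_each_side}, then orthonormalized on the
#' grid (QR with sign fixing, which preserves the even/odd parity structure
#' of the functions). Suited to acausal filters: the first (even) function
#' is symmetric about lag zero.
#'
#' @param order Number of basis functions (1..15).
#' @param width Gaussian width w in seconds.
#' @param n_lags_each_side Lags on each side of zero.
#' @param dt Sample interval in seconds.
#' @return A \code{(2*n_lags_each_side+1) x order} matrix with attributes as
#'   in \code{\link{laguerre_basis}}.
#' @export
hermite_basis <- function(order, width, n_lags_each_side, dt = 1) {
  stopifnot(order >= 1L, order <= 15L, width > 0, n_lags_each_side >= order)
  t <- (-n_lags_each_side:n_lags_each_side) * dt
  z <- t / width
  H <- matrix(0, length(z), order)
  H[, 1L] <- 1
  if (order > 1L) H[, 2L] <- 2 * z
  if (order > 2L) {
    for (k in 3:order) {
      H[, k] <- 2 * z * H[, k - 1L] - 2 * (k - 2) * H[, k - 2L]
    }
  }
  B <- H * exp(-z^2 / 2)
  qr_d <- qr(B)
  Q <- qr.Q(qr_d)
  sgn <- sign(diag(qr.R(qr_d)))
  sgn[sgn == 0] <- 1
  B <- sweep(Q, 2L, sgn, `*`)
  structure(B, lags = t, family = "hermite", scale = width, dt = dt)
}

# design matrix of basis-convolved regressors, zero-padded at the edges.
# For a causal basis (lags >= 0) column k at time t is
# sum_l B[l,k] x[t-l]; for a two-sided basis lags run negative..positive.
basis_design <- function(x, basis) {
  n <- length(x)
  lags_idx <- round(attr(basis, "lags") / attr(basis, "dt"))
  D <- matrix(0, n, ncol(basis))
  for (k in seq_len(ncol(basis))) {
    col <- numeric(n)
    for (j in seq_along(lags_idx)) {
      l <- lags_idx[j]
      w <- basis[j, k]
      if (w == 0) next
      if (l >= 0) {
        if (l < n) col[(l + 1L):n] <- col[(l + 1L):n] + w * x[1:(n - l)]
      } else {
        m <- -l
        if (m < n) col[1:(n - m)] <- col[1:(n - m)] + w * x[(m + 1L):n]
      }
    }
    D[, k] <- col
  }
  D
}

#' Fit a linear filter in a Laguerre or Hermite basis with AIC selection
#'
#' Regresses \code{y} on convolutions of \code{x} with the basis functions
#' (ordinary least squares, series assumed demeaned), selecting the basis
#' order — and the basis time scale when several are offered — by the Akaike
#' information criterion \eqn{AIC = n\log(RSS/n) + 2k} over orders
#' \code{0..max_order}. Order 0 is the empty model (identically zero
#' kernel), selected when no order explains enough variance to justify its
#' parameters — the natural outcome for an input that does not drive the
#' output.
#'
#' @param x Input series.
#' @param y Output series (same length).
#' @param family \code{"laguerre"} (causal) or \code{"hermite"} (two-sided).
#' @param dt Sample interval in seconds.
#' @param scales Candidate basis scales: Laguerre poles (default
#'   \code{c(0.6, 0.8, 0.9)}) or Hermite widths in seconds (default
#'   \code{c(1, 2, 4)}).
#' @param max_order Maximum basis order (default 15).
#' @param n_lags Kernel support: lag samples (causal) or samples per side
#'   (two-sided). Default about 10 s of lags, capped at a quarter of the
#'   series.
#' @return An object of class \code{"basis_filter"}: \code{kernel} (sampled
#'   impulse response, exactly basis times coefficients), \code{lags}
#'   (seconds), \code{coefficients}, \code{family}, \code{order},
#'   \code{scale}, \code{aic}, \code{aic_table}, \code{residuals},
#'   \code{fitted}, \code{dt}.
#' @export
fit_filter <- function(x, y, family = c("laguerre", "hermite"), dt = 1,
                       scales = NULL, max_order = 15L, n_lags = NULL) {
  family <- match.arg(family)
  stopifnot(length(x) == length(y))
  n <- length(y)
  if (is.null(scales)) {
    scales <- if (family == "laguerre") c(0.6, 0.8, 0.9) else c(1, 2, 4)
  }
  if (is.null(n_lags)) {
    n_lags <- max(max_order + 1L, min(round(10 / dt), n %/% 4L))
  }
  if (n <= max_order * 3L) stop("series too short for max_order = ",
                                max_order, call. = FALSE)
  yss <- sum(y^2)
  # order 0: the empty model
  best <- list(aic = n * log(yss / n), order = 0L, scale = scales[1L],
               coefficients = numeric(0), basis = NULL,
               fitted = numeric(n))
  tab <- data.frame(scale = NA_real_, order = 0L, aic = best$aic)
  for (sc in scales) {
    basis <- if (family == "laguerre") {
      laguerre_basis(max_order, sc, n_lags, dt)
    } else {
      hermite_basis(max_order, sc, n_lags, dt)
    }
    D <- basis_design(x, basis)
    qr_d <- qr(D)
    # orders are nested in the columns; usable orders stop where the
    # truncated basis convolutions become numerically collinear
    rdiag <- abs(diag(qr.R(qr_d)))
    good <- rdiag > 1e-7 * max(rdiag)
    k_max <- sum(cumprod(good))   # leading run of well-conditioned columns
    if (k_max < 1L) {
      stop("rank-deficient design: basis convolutions are collinear ",
           "(constant or degenerate input?)", call. = FALSE)
    }
    qty <- qr.qty(qr_d, y)[seq_len(k_max)]
    rss_k <- yss - cumsum(qty^2)
    rss_k <- pmax(rss_k, 1e-300)
    aic_k <- n * log(rss_k / n) + 2 * seq_len(k_max)
    tab <- rbind(tab, data.frame(scale = sc, order = seq_len(k_max),
                                 aic = aic_k))
    k_best <- which.min(aic_k)
    if (is.null(best) || aic_k[k_best] < best$aic) {
      R <- qr.R(qr_d)[seq_len(k_best), seq_len(k_best), drop = FALSE]
      coef <- backsolve(R, qty[seq_len(k_best)])
      fitted <- D[, seq_len(k_best), drop = FALSE] %*% coef
      bsub <- structure(basis[, seq_len(k_best), drop = FALSE],
                        lags = attr(basis, "lags"),
                        family = attr(basis, "family"),
                        scale = attr(basis, "scale"), dt = attr(basis, "dt"))
      # standard error of the kernel's net area: a' (X'X)^-1 a * sigma2
      # with a = column sums of the basis
      sig2 <- rss_k[k_best] / max(n - k_best, 1L)
      a_net <- colSums(bsub)
      ra <- backsolve(R, a_net, transpose = TRUE)
      best <- list(aic = aic_k[k_best], order = k_best, scale = sc,
                   coefficients = as.numeric(coef), basis = bsub,
                   fitted = as.numeric(fitted),
                   net_area_se = sqrt(sum(ra^2) * sig2))
    }
  }
  if (best$order == 0L) {
    ref <- if (family == "laguerre") {
      laguerre_basis(1L, scales[1L], n_lags, dt)
    } else hermite_basis(1L, scales[1L], n_lags, dt)
    best$basis <- structure(matrix(0, nrow(ref), 0L),
                            lags = attr(ref, "lags"), family = family,
                            scale = scales[1L], dt = dt)
    best$net_area_se <- 0
    kernel <- numeric(nrow(ref))
  } else {
    kernel <- as.numeric(best$basis %*% best$coefficients)
  }
  structure(list(family = family, order = best$order, scale = best$scale,
                 coefficients = best$coefficients,
                 kernel = kernel, lags = attr(best$basis, "lags"),
                 dt = dt, aic = best$aic, aic_table = tab,
                 net_area_se = best$net_area_se,
                 fitted = best$fitted, residuals = y - best$fitted,
                 basis = best$basis, n = n),
            class = "basis_filter")
}

#' @export
print.basis_filter <- function(x, ...) {
  cat(sprintf("<basis_filter> %s, order %d (scale %g), net area %.4g, AIC %.2f\n",
              x$family, x$order, x$scale, filter_area(x), x$aic))
  invisible(x)
}

#' Net area (integral) of a filter kernel
#'
#' \code{sum(kernel) * dt}: the kernel's response to a sustained unit input,
#' whose sign classifies a filter as net excitatory or net suppressive.
#'
#' @param filt A \code{basis_filter} (or numeric kernel with \code{dt}
#'   attribute).
#' @return Scalar net area.
#' @export
filter_area <- function(filt) {
  if (inherits(filt, "basis_filter")) sum(filt$kernel) * filt$dt
  else sum(filt) * attr(filt, "dt")
}

#' Frequency response of a filter kernel
#'
#' Evaluates the discrete-time transfer function
#' \eqn{F(\omega) = \sum_l k_l e^{-2\pi i f \, l\, dt}} of a sampled kernel
#' on a grid of frequencies. Conjugate symmetry for real kernels holds by
#' construction.
#'
#' @param filt A \code{basis_filter}, or a numeric kernel.
#' @param freqs Frequencies in Hz.
#' @param lags Lag times in seconds (required when \code{filt} is a bare
#'   kernel).
#' @return Complex vector of the same length as \code{freqs}.
#' @export
freq_response <- function(filt, freqs, lags = NULL) {
  if (inherits(filt, "basis_filter")) {
    kernel <- filt$kernel
    lags <- filt$lags
  } else {
    kernel <- as.numeric(filt)
    stopifnot(!is.null(lags), length(lags) == length(kernel))
  }
  vapply(freqs, function(f) sum(kernel * exp(-2i * pi * f * lags)),
         complex(1))
}

#' Reconstruct a lag-domain kernel from a one-sided frequency response
#'
#' Inverse discrete-time Fourier transform of a transfer function given on a
#' uniform one-sided frequency grid (0..Nyquist), assuming conjugate
#' symmetry: \eqn{k_l = dt\,\Delta f\,[V_0 + 2\sum_j \mathrm{Re}(V_j
#' e^{2\pi i f_j l dt}) + \mathrm{Re}(V_{Nyq} e^{2\pi i f_{Nyq} l dt})]}.
#'
#' @param freqs One-sided frequency grid in Hz (uniform, starting at 0).
#' @param values Complex response on \code{freqs}.
#' @param lags Lag times (seconds) at which to evaluate the kernel.
#' @param dt Sample interval of the target kernel (seconds).
#' @return Numeric kernel over \code{lags}.
#' @export
freq_to_kernel <- function(freqs, values, lags, dt) {
  stopifnot(length(freqs) == length(values), length(freqs) >= 2L)
  df <- freqs[2L] - freqs[1L]
  nyq <- abs(freqs[length(freqs)] - 1 / (2 * dt)) < df / 2
  wts <- rep(2, length(freqs))
  wts[1L] <- 1
  if (nyq) wts[length(freqs)] <- 1
  vapply(lags, function(l)
    dt * df * sum(wts * Re(values * exp(2i * pi * freqs * l))),
    numeric(1))
}
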