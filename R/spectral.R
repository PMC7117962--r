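# Taper-based spectral estimation, amplifier roll-off correction, noise
# masking and sliding-window power-law slope fitting.

# cache for computed taper families, keyed by "n|nw|k"
.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` Slepian sequences of length `n_samples` with
#' time-bandwidth product `time_bandwidth` (half-bandwidth W =
#' time_bandwidth / n_samples in cycles/sample) via the standard symmetric
#' tridiagonal eigenproblem.  Tapers are orthonormal (unit energy); sign is
#' fixed so each taper is positive at its largest-magnitude sample.
#' The default single lowest-order taper maximises frequency resolution.
#'
#' @param n_samples sequence length (>= 8).
#' @param time_bandwidth time-bandwidth product NW (default 1).
#' @param k number of tapers (default 1).  A warning is issued when k
#'   exceeds 2 NW - 1, beyond which concentration degrades.
#' @return `n_samples x k` matrix, one taper per column.
#' @export
slepian_taper <- function(n_samples, time_bandwidth = 1, k = 1) {
  stopifnot(n_samples >= 8, k >= 1, time_bandwidth > 0)
  if (k > max(1, 2 * time_bandwidth - 1)) {
    warning("k = ", k, " tapers with NW = ", time_bandwidth,
            ": concentration is poor beyond 2*NW - 1 tapers")
  }
  key <- paste(n_samples, time_bandwidth, k, sep = "|")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- n_samples
  W <- time_bandwidth / n
  t <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  diag_off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  A <- diag(diag_main)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- diag_off
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (tap[which.max(abs(tap[, j])), j] < 0) tap[, j] <- -tap[, j]
  }
  .taper_cache[[key]] <- tap
  tap
}

#' Tapered Fourier coefficients of an epoched recording
#'
#' For each electrode, trial and taper, computes `fft(taper * x) / sqrt(n)`
#' over the analysis window, retaining frequencies 0..Nyquist.  With this
#' scaling the one-sided per-bin power (see [power_spectrum()]) satisfies
#' Parseval's identity against the tapered time series.  Frequency
#' resolution is 1 / window duration (0.5 s at 2 kHz -> 2 Hz bins; 0.2 s ->
#' 5 Hz).
#'
#' @param rec an `epoched_recording`.
#' @param window `c(t0, t1)` in seconds relative to epoch start (default:
#'   whole epoch).
#' @param time_bandwidth,k taper family parameters (defaults: single Slepian
#'   taper with NW = 1).
#' @return object of class `spectral_coefficients`: complex array `coef`
#'   indexed (electrode, trial, taper, frequency), `frequencies` (Hz),
#'   `sampling_rate`, `grid`, `scheme`, taper spec.
#' @export
spectral_coefficients <- function(rec, window = NULL, time_bandwidth = 1, k = 1) {
  stopifnot(inherits(rec, "epoched_recording"))
  fs <- rec$sampling_rate
  nt <- n_samples(rec)
  if (is.null(window)) window <- c(0, nt / fs)
  i0 <- round(window[1] * fs) + 1L
  i1 <- round(window[2] * fs)
  if (i0 < 1 || i1 > nt || i1 <= i0) {
    stop("analysis window [", window[1], ", ", window[2],
         "] s falls outside the epoch (", nt / fs, " s)")
  }
  n <- i1 - i0 + 1L
  tap <- slepian_taper(n, time_bandwidth, k)
  nE <- dim(rec$samples)[1]
  nTr <- dim(rec$samples)[2]
  nF <- n %/% 2 + 1L
  freqs <- (seq_len(nF) - 1) * fs / n
  coef <- array(complex(1), dim = c(nE, nTr, k, nF))
  for (e in seq_len(nE)) {
    x <- matrix(rec$samples[e, , i0:i1], nTr, n)    # trial x time
    for (j in seq_len(k)) {
      y <- t(x) * tap[, j]                          # time x trial
      cf <- stats::mvfft(y) / sqrt(n)
      coef[e, , j, ] <- t(cf[seq_len(nF), , drop = FALSE])
    }
  }
  out <- list(coef = coef, frequencies = freqs, sampling_rate = fs,
              grid = rec$grid, scheme = rec$scheme,
              time_bandwidth = time_bandwidth, k = k, n = n,
              window = c((i0 - 1) / fs, i1 / fs))
  class(out) <- "spectral_coefficients"
  out
}

#' @export
print.spectral_coefficients <- function(x, ...) {
  d <- dim(x$coef)
  cat(sprintf("<spectral_coefficients> %d electrodes x %d trials x %d taper(s) x %d freqs (df = %g Hz), scheme=%s\n",
              d[1], d[2], d[3], d[4], x$frequencies[2], x$scheme))
  invisible(x)
}

#' Power spectrum from tapered coefficients
#'
#' One-sided per-bin power `2 |c(f)|^2` (DC and Nyquist not doubled)
#' averaged over trials and tapers.  Units: uV^2 per frequency bin.
#'
#' @param coeffs a `spectral_coefficients` object.
#' @return object of class `power_spectrum`: `power` matrix (electrode x
#'   frequency), `frequencies`, `masked` logical vector, `rolloff_corrected`.
#' @export
power_spectrum <- function(coeffs) {
  stopifnot(inherits(coeffs, "spectral_coefficients"))
  d <- dim(coeffs$coef)
  pw <- matrix(0, d[1], d[4])
  for (e in seq_len(d[1])) {
    p <- abs(matrix(coeffs$coef[e, , , ], d[2] * d[3], d[4]))^2
    pw[e, ] <- colMeans(p)
  }
  w <- rep(2, d[4])
  w[coeffs$frequencies == 0] <- 1
  if (abs(coeffs$frequencies[d[4]] - coeffs$sampling_rate / 2) < 1e-9) {
    w[d[4]] <- 1
  }
  pw <- sweep(pw, 2, w, `*`)
  out <- list(power = pw, frequencies = coeffs$frequencies,
              masked = rep(FALSE, d[4]), rolloff_corrected = FALSE,
              grid = coeffs$grid, scheme = coeffs$scheme,
              sampling_rate = coeffs$sampling_rate)
  class(out) <- "power_spectrum"
  out
}

#' Butterworth amplifier roll-off correction
#'
#' Divides the PSD by the squared magnitude response of the acquisition
#' chain: first-order analog high-pass at `highpass` Hz times fourth-order
#' low-pass at `lowpass` Hz (|H_hp|^2 = (f/fc)^2 / (1 + (f/fc)^2),
#' |H_lp|^2 = 1 / (1 + (f/fc)^(2*order))).  At the low-pass cutoff the
#' correction doubles the power.  DC (where the high-pass gain vanishes) is
#' masked.  Slope analyses should stay below ~400 Hz where the analytic and
#' measured responses agree.
#'
#' @param psd a `power_spectrum` not yet corrected.
#' @param highpass,hp_order high-pass cutoff (Hz) and order (defaults 0.3, 1).
#' @param lowpass,lp_order low-pass cutoff (Hz) and order (defaults 500, 4).
#' @return corrected `power_spectrum` (`rolloff_corrected = TRUE`).
#' @export
rolloff_correction <- function(psd, highpass = 0.3, hp_order = 1,
                               lowpass = 500, lp_order = 4) {
  stopifnot(inherits(psd, "power_spectrum"))
  if (psd$rolloff_corrected) {
    stop("PSD is already roll-off corrected; refusing to correct twice")
  }
  f <- psd$frequencies
  h2 <- butterworth_gain2(f, highpass, hp_order, lowpass, lp_order)
  zero <- h2 <= 0
  h2[zero] <- 1
  psd$power <- sweep(psd$power, 2, h2, `/`)
  psd$power[, zero] <- NA_real_
  psd$masked <- psd$masked | zero
  psd$rolloff_corrected <- TRUE
  psd
}

#' Squared magnitude response of the acquisition filter chain
#'
#' @param f frequencies in Hz.
#' @inheritParams rolloff_correction
#' @return numeric vector of |H(f)|^2.
#' @export
butterworth_gain2 <- function(f, highpass = 0.3, hp_order = 1,
                              lowpass = 500, lp_order = 4) {
  hp <- (f / highpass)^(2 * hp_order) / (1 + (f / highpass)^(2 * hp_order))
  hp[f == 0] <- 0
  lp <- 1 / (1 + (f / lowpass)^(2 * lp_order))
  hp * lp
}

#' Mask noise-contaminated frequencies
#'
#' Marks bins within `half_width` Hz of each listed frequency (monitor
#' refresh, line noise and harmonics) as missing; downstream fits skip them.
#' Masked bins are NA, never zero.
#'
#' @param psd a `power_spectrum`.
#' @param freqs frequencies to mask, Hz (default 100, 120, 240, 360: refresh
#'   rate plus line-noise harmonics).
#' @param half_width mask half-width in Hz; default two frequency bins.
#' @return the masked `power_spectrum`.
#' @export
mask_frequencies <- function(psd, freqs = c(100, 120, 240, 360),
                             half_width = NULL) {
  stopifnot(inherits(psd, "power_spectrum"))
  if (length(freqs) == 0) return(psd)
  df <- psd$frequencies[2] - psd$frequencies[1]
  if (is.null(half_width)) half_width <- 2 * df
  if (any(freqs < 0 | freqs > max(psd$frequencies))) {
    stop("masked frequencies outside the spectral grid")
  }
  bad <- rep(FALSE, length(psd$frequencies))
  for (f0 in freqs) {
    bad <- bad | abs(psd$frequencies - f0) <= half_width + 1e-9
  }
  psd$power[, bad] <- NA_real_
  psd$masked <- psd$masked | bad
  psd
}

#' Fit a power law plus noise floor to a PSD segment
#'
#' Fits P(f) = A f^(-alpha) + B by least squares on log10 power (default) or
#' linear power, using Nelder-Mead simplex search over (log A, alpha, log B);
#' the log parameterisation enforces A, B >= 0.  Initialisation: alpha and A
#' from a straight-line log-log fit over the window, B from half the minimum
#' power; one restart from perturbed values if the first search fails.
#'
#' @param psd a `power_spectrum`, or a numeric vector of powers (then
#'   `frequencies` must be given).
#' @param electrode electrode index (row of the power matrix); ignored for
#'   vector input.
#' @param f_range `c(f_lo, f_hi)` in Hz.
#' @param frequencies frequency grid for vector input.
#' @param log_space fit residuals on log10 power (default TRUE).
#' @return list with `A`, `B`, `alpha`, `residual` (objective at optimum),
#'   `converged`, `n_bins`.
#' @export
fit_power_law <- function(psd, electrode = 1, f_range = c(20, 400),
                          frequencies = NULL, log_space = TRUE) {
  if (inherits(psd, "power_spectrum")) {
    p <- psd$power[electrode, ]
    f <- psd$frequencies
  } else {
    p <- as.numeric(psd)
    f <- frequencies
    if (is.null(f)) stop("frequencies must be supplied for vector input")
  }
  use <- is.finite(p) & p > 0 & f >= f_range[1] - 1e-9 & f <= f_range[2] + 1e-9 & f > 0
  if (sum(use) < 4) {
    return(list(A = NA_real_, B = NA_real_, alpha = NA_real_,
                residual = NA_real_, converged = FALSE, n_bins = sum(use)))
  }
  f <- f[use]; p <- p[use]
  obj <- if (log_space) {
    function(par) {
      m <- exp(par[1]) * f^(-par[2]) + exp(par[3])
      mean((log10(p) - log10(m))^2)
    }
  } else {
    function(par) {
      m <- exp(par[1]) * f^(-par[2]) + exp(par[3])
      mean((p - m)^2)
    }
  }
  lf <- log(f); lp <- log(p)
  sl <- stats::cov(lf, lp) / stats::var(lf)
  a0 <- mean(lp) - sl * mean(lf)
  start <- c(a0, -sl, log(min(p) / 2))
  ctl <- list(maxit = 5000, reltol = 1e-10)
  fit <- stats::optim(start, obj, method = "Nelder-Mead", control = ctl)
  # fminsearch-style restarts: a fresh simplex at the incumbent escapes the
  # stalls Nelder-Mead is prone to on the nearly degenerate (A, B, alpha)
  # family over narrow windows; stop once restarts no longer pay
  for (restart in 1:15) {
    from <- if (fit$convergence == 0) fit$par else fit$par * 0.95 + 0.05
    nxt <- stats::optim(from, obj, method = "Nelder-Mead", control = ctl)
    improved <- (fit$value - nxt$value) > 1e-6 * max(fit$value, 1e-15)
    if (nxt$value <= fit$value) fit <- nxt
    if (!improved && fit$convergence == 0) break
  }
  list(A = exp(fit$par[1]), B = exp(fit$par[3]), alpha = fit$par[2],
       residual = fit$value, converged = fit$convergence == 0,
       n_bins = length(p))
}

#' Sliding-window PSD slope profile
#'
#' Fits P = A f^(-alpha) + B on segments of `half_width` Hz either side of
#' each centre frequency (defaults: centres 20..400 Hz in 10 Hz steps,
#' +/- 15 Hz segments).  Larger half-widths smooth the profile.
#'
#' @param psd a `power_spectrum`.
#' @param electrode electrode index.
#' @param f_centers centre frequencies, Hz.
#' @param half_width segment half-width, Hz.
#' @param log_space passed to [fit_power_law()].
#' @return `data.frame` with one row per centre: `f_center`, `A`, `B`,
#'   `alpha`, `residual`, `converged`, `n_bins`, `half_width`.
#' @export
slope_profile <- function(psd, electrode = 1,
                          f_centers = seq(20, 400, by = 10),
                          half_width = 15, log_space = TRUE) {
  rows <- lapply(f_centers, function(fc) {
    fit <- fit_power_law(psd, electrode,
                         f_range = c(fc - half_width, fc + half_width),
                         log_space = log_space)
    data.frame(f_center = fc, A = fit$A, B = fit$B, alpha = fit$alpha,
               residual = fit$residual, converged = fit$converged,
               n_bins = fit$n_bins, half_width = half_width)
  })
  do.call(rbind, rows)
}
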