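# Synthetic epoched LFP with the statistical structure the mechanistic
# analyses assume: per-frequency complex Gaussian spectral coefficients
# (Rayleigh amplitudes, exponential single-taper power) split between one
# globally shared source and per-electrode independent noise.

#' Default shared-component fraction profile
#'
#' Logistic decay of the fraction of power carried by the global source:
#' about 0.6 near DC, midpoint 80 Hz, width 20 Hz, approaching 0 above
#' ~100 Hz.  This is what makes inter-electrode coherence high at low
#' frequencies and drives it to the estimator's bias floor at high ones.
#'
#' @param c0 low-frequency plateau (default 0.6).
#' @param midpoint,width logistic midpoint and width in Hz.
#' @return function of frequency (Hz) returning the fraction in [0, 1].
#' @export
default_common_fraction <- function(c0 = 0.6, midpoint = 80, width = 20) {
  force(c0); force(midpoint); force(width)
  function(f) c0 * stats::plogis(-(f - midpoint) / width)
}

#' Synthetic recording configuration
#'
#' Describes the generative model: per-electrode background power
#' `background_scale * f^(-background_exponent)` plus `noise_floor` plus
#' optional Gaussian alpha/gamma bumps and line components; at every
#' frequency a fraction `common_fraction(f)` of the power is carried by a
#' single source shared by all electrodes (volume conduction), the rest by
#' independent noise.  `reference_pickup` adds a further component,
#' identical on all electrodes, with amplitude `reference_pickup` times the
#' background amplitude, emulating neural activity on the reference wire.
#'
#' @param n_rows,n_cols,pitch,good_mask grid specification, see
#'   [build_grid()].
#' @param n_trials number of epochs (default 200).
#' @param epoch_duration seconds (default 0.5).
#' @param sampling_rate Hz (default 2000).
#' @param background_exponent 1/f exponent of the background (default 2,
#'   Brownian-like).
#' @param background_scale power at 1 Hz, uV^2 per bin (default 1000).
#' @param noise_floor flat floor, uV^2 per bin (default 1e-3).
#' @param common_fraction function of frequency returning the shared-power
#'   fraction in [0, 1] (default [default_common_fraction()]).
#' @param alpha_bump,gamma_bump optional lists `list(center, bandwidth,
#'   amplitude)` adding Gaussian power bumps (bandwidth = 2 SD, Hz).
#' @param line_components optional list of `list(frequency, amplitude)`
#'   adding narrow deterministic-power contaminants (power added at the
#'   nearest bin, shared across electrodes like true pickup).
#' @param reference_pickup relative amplitude of the reference-wire
#'   component (default 0).
#' @param seed default RNG seed used by [generate_recording()].
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 10, n_cols = 10, pitch = 0.4,
                             good_mask = NULL, n_trials = 200,
                             epoch_duration = 0.5, sampling_rate = 2000,
                             background_exponent = 2,
                             background_scale = 1000, noise_floor = 1e-3,
                             common_fraction = default_common_fraction(),
                             alpha_bump = NULL, gamma_bump = NULL,
                             line_components = NULL,
                             reference_pickup = 0, seed = 1L) {
  nt <- epoch_duration * sampling_rate
  if (abs(nt - round(nt)) > 1e-9) {
    stop("epoch_duration x sampling_rate must be an integer sample count")
  }
  for (bump in list(alpha_bump, gamma_bump)) {
    if (!is.null(bump) && bump$center > sampling_rate / 2) {
      stop("configured component at ", bump$center, " Hz exceeds Nyquist")
    }
  }
  for (lc in line_components) {
    if (lc$frequency > sampling_rate / 2) {
      stop("line component at ", lc$frequency, " Hz exceeds Nyquist")
    }
  }
  cfg <- list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
              good_mask = good_mask, n_trials = n_trials,
              epoch_duration = epoch_duration, sampling_rate = sampling_rate,
              background_exponent = background_exponent,
              background_scale = background_scale, noise_floor = noise_floor,
              common_fraction = common_fraction, alpha_bump = alpha_bump,
              gamma_bump = gamma_bump, line_components = line_components,
              reference_pickup = reference_pickup, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

# total expected per-bin power at frequencies f (one-sided, uV^2 per bin)
synthetic_power_profile <- function(cfg, f) {
  p <- ifelse(f > 0, cfg$background_scale * f^(-cfg$background_exponent), 0) +
    cfg$noise_floor
  for (bump in list(cfg$alpha_bump, cfg$gamma_bump)) {
    if (!is.null(bump)) {
      sd <- bump$bandwidth / 2
      p <- p + bump$amplitude * exp(-(f - bump$center)^2 / (2 * sd^2))
    }
  }
  p
}

#' Expected inter-electrode coherence of the generative model
#'
#' For equal-power electrodes sharing fraction c(f) of their power, the
#' population coherence at frequency f is exactly c(f); this is the oracle
#' the empirical phase-coherence estimates converge to as trials grow
#' (up to estimator bias).
#'
#' @param config a `synthetic_config`.
#' @param f frequency (Hz), at or below Nyquist.
#' @export
expected_coherence <- function(config, f) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(f > config$sampling_rate / 2)) {
    stop("frequency above Nyquist (", config$sampling_rate / 2, " Hz)")
  }
  pmin(pmax(config$common_fraction(f), 0), 1)
}

#' Generate a synthetic epoched recording
#'
#' Coefficients are drawn directly in the frequency domain: for each trial
#' and positive FFT bin, a shared circularly-symmetric complex Gaussian
#' G(f) and per-electrode independent draws N_e(f) are combined as
#' V_e(f) = sqrt(c(f) P(f) / 2) G(f) + sqrt((1 - c(f)) P(f) / 2) N_e(f),
#' giving single-taper power that is exponential across trials (amplitude
#' Rayleigh) with expectation P(f) per one-sided bin, and expected
#' inter-electrode coherence c(f).  Time series are obtained by inverse FFT
#' of the conjugate-symmetric spectrum; DC and Nyquist bins are zero.
#' Line components are added as fixed-amplitude, random-phase (per trial)
#' phasors shared across electrodes; the reference-wire pickup as one more
#' shared Gaussian component scaled by `reference_pickup`.
#'
#' @param config a `synthetic_config`.
#' @param seed RNG seed; defaults to `config$seed`.  One sequential RNG
#'   stream per recording; trials consume it in order, so identical seeds
#'   give bit-identical recordings.
#' @return an `epoched_recording` (scheme `"single-wire"`) with a
#'   `ground_truth` element recording `frequencies`, `power` P(f),
#'   `common_fraction` c(f) and the seed.
#' @export
generate_recording <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  grid <- build_grid(config$n_rows, config$n_cols, config$pitch,
                     config$good_mask)
  nE <- length(grid$ids)
  nt <- as.integer(round(config$epoch_duration * config$sampling_rate))
  nF <- nt %/% 2 + 1L
  f <- (seq_len(nF) - 1) * config$sampling_rate / nt
  pos <- 2:(nF - 1L)                     # positive bins, excluding DC/Nyquist
  P <- synthetic_power_profile(config, f)
  cf <- pmin(pmax(config$common_fraction(f), 0), 1)
  # scaling: with x = Re(ifft(X)) / sqrt(nt) and the estimator convention
  # c = fft(taper * x) / sqrt(n), a bin with E|X|^2 = nt * P / 2 yields
  # one-sided per-bin power with expectation P
  amp_shared <- sqrt(nt * cf[pos] * P[pos] / 2)
  amp_indep <- sqrt(nt * (1 - cf[pos]) * P[pos] / 2)
  amp_pickup <- config$reference_pickup * sqrt(nt * P[pos] / 2)
  line_amp <- rep(0, length(pos))
  for (lc in config$line_components) {
    k <- which.min(abs(f[pos] - lc$frequency))
    line_amp[k] <- line_amp[k] + sqrt(nt) * lc$amplitude
  }
  nPos <- length(pos)
  samples <- array(0, dim = c(nE, config$n_trials, nt))
  cnorm <- function(n) complex(real = stats::rnorm(n, sd = sqrt(0.5)),
                               imaginary = stats::rnorm(n, sd = sqrt(0.5)))
  for (tr in seq_len(config$n_trials)) {
    G <- cnorm(nPos)
    W <- cnorm(nPos)
    phi <- stats::runif(nPos, -pi, pi)
    shared <- amp_shared * G + amp_pickup * W + line_amp * exp(1i * phi)
    Ne <- matrix(cnorm(nE * nPos), nE, nPos)
    X <- matrix(shared, nE, nPos, byrow = TRUE) +
      Ne * matrix(amp_indep, nE, nPos, byrow = TRUE)
    full <- matrix(0 + 0i, nt, nE)
    full[pos, ] <- t(X)
    full[nt + 2L - pos, ] <- Conj(t(X))
    samples[, tr, ] <- t(Re(stats::mvfft(full, inverse = TRUE)) / sqrt(nt))
  }
  rec <- epoched_recording(samples, config$sampling_rate, grid,
                           scheme = "single-wire",
                           lineage = sprintf("synthetic(seed=%d)", seed))
  rec$ground_truth <- list(frequencies = f, power = P, common_fraction = cf,
                           seed = seed)
  rec
}
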