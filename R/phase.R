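# Circular statistics: phase coherence, mean phase differences by distance,
# pairwise phase consistency, and the shared-component artifact profiles.

#' Wrap angles to (-pi, pi]
#' @param theta angles in radians.
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Phase coherence (phase-locking value) between two coefficient sets
#'
#' C_phase(f) = |mean_k exp(j (phi_k(f) - theta_k(f)))| over trials k.  Lies
#' in [0, 1]; 1 means a perfectly consistent phase difference across trials
#' (including a constant difference of pi).  Positively biased for finite N
#' (about sqrt(pi) / (2 sqrt(N)) for independent phases); see
#' [pairwise_phase_consistency()] for an unbiased alternative.
#'
#' @param coef_a,coef_b complex vectors (one frequency, trials along the
#'   vector) or trial x frequency matrices of single-taper coefficients.
#' @return numeric: one coherence per frequency (scalar for vector input).
#' @export
phase_coherence <- function(coef_a, coef_b) {
  a <- as.matrix(coef_a); b <- as.matrix(coef_b)
  if (!identical(dim(a), dim(b))) stop("coefficient sets differ in shape")
  if (nrow(a) < 2) stop("need at least 2 trials")
  za <- abs(a) == 0
  zb <- abs(b) == 0
  if (any(za) || any(zb)) {
    tr <- which(apply(za | zb, 1, any))[1]
    stop("zero-amplitude coefficient (undefined phase) at trial ", tr)
  }
  u <- (a * Conj(b)) / (abs(a) * abs(b))
  drop(abs(colMeans(u)))
}

#' Amplitude-weighted spectral coherence
#'
#' Magnitude of the coherency |mean_k(a_k conj(b_k))| /
#' sqrt(mean|a|^2 mean|b|^2) across trials.  For the shared-component
#' generative model this converges to the shared-power fraction c(f)
#' exactly, whereas the amplitude-discarding phase coherence
#' ([phase_coherence()]) converges to a smaller value for partially
#' coherent Gaussian signals.
#'
#' @inheritParams phase_coherence
#' @return numeric, one value per frequency.
#' @export
coherence <- function(coef_a, coef_b) {
  a <- as.matrix(coef_a); b <- as.matrix(coef_b)
  if (!identical(dim(a), dim(b))) stop("coefficient sets differ in shape")
  cross <- abs(colMeans(a * Conj(b)))
  drop(cross / sqrt(colMeans(abs(a)^2) * colMeans(abs(b)^2)))
}

#' Circular mean and resultant length
#'
#' Mean direction (wrapped to (-pi, pi]) and mean resultant length R of a
#' set of angles.  When R is numerically zero (antipodal cancellation) the
#' mean direction is undefined and reported as NA with `defined = FALSE`.
#'
#' @param angles radians.
#' @return list with `mean`, `R`, `defined`.
#' @export
circular_mean <- function(angles) {
  if (length(angles) < 1) stop("need at least one angle")
  z <- mean(exp(1i * angles))
  R <- abs(z)
  if (R < 1e-6) {
    list(mean = NA_real_, R = R, defined = FALSE)
  } else {
    list(mean = wrap_angle(Arg(z)), R = R, defined = TRUE)
  }
}

#' Angular deviation
#'
#' sigma_phase = sqrt(2 (1 - R)), a circular spread bounded on [0, sqrt(2)]
#' (unlike the circular standard deviation, which is unbounded).
#'
#' @param R mean resultant length in [0, 1].
#' @export
angular_deviation <- function(R) {
  if (any(R < -1e-12 | R > 1 + 1e-12)) stop("R must lie in [0, 1]")
  sqrt(2 * (1 - pmin(pmax(R, 0), 1)))
}

#' Pairwise phase consistency
#'
#' Mean over all unordered trial pairs (j, k) of cos(delta_j - delta_k),
#' where delta are per-trial phase differences.  Unbiased: expectation 0 for
#' uniform phases at any trial count, unlike the phase-locking value.
#'
#' @param delta per-trial phase differences, radians (length >= 2).
#' @return PPC estimate in [-1/(N-1), 1].
#' @export
pairwise_phase_consistency <- function(delta) {
  n <- length(delta)
  if (n < 2) stop("PPC needs at least 2 trials")
  cm <- cos(outer(delta, delta, "-"))
  (sum(cm) - n) / (n * (n - 1))
}

#' Amplitude of a sum of two equal-frequency sinusoids
#'
#' For amplitudes A1, A2 and phases theta1, theta2 the sum is a sinusoid of
#' amplitude sqrt(A1^2 + A2^2 + 2 A1 A2 cos(theta1 - theta2)).  With random
#' relative phase the expected squared amplitude is A1^2 + A2^2, hence the
#' ~sqrt(2) RMS amplitude (factor two in power) of a sum or difference of
#' equal-power independent signals.
#'
#' @param A1,A2 non-negative amplitudes.
#' @param theta1,theta2 phases in radians.
#' @export
amplitude_of_sum <- function(A1, theta1, A2, theta2) {
  if (any(A1 < 0) || any(A2 < 0)) stop("amplitudes must be non-negative")
  sqrt(A1^2 + A2^2 + 2 * A1 * A2 * cos(theta1 - theta2))
}

#' Pairwise phase statistics aggregated by distance bin and frequency
#'
#' For every pair in `pairs`, computes per-frequency phase coherence, mean
#' phase difference (orientation: phase of id_a minus phase of id_b, the
#' stored pair order) and angular deviation across trials, then aggregates
#' within distance bin x frequency x shared-component class: circular mean
#' of the pair-level mean phase differences, mean coherence, mean angular
#' deviation.  Shared-component pairs are never pooled with artifact-free
#' pairs.
#'
#' @param coeffs `spectral_coefficients` over the pairs' electrodes (single
#'   taper; the first taper is used).
#' @param pairs a `pair_table` whose ids exist in `coeffs$grid`.
#' @param frequencies optional frequency subset, Hz (nearest bins used).
#' @param return_pairs also return the per-pair table.
#' @return list with `by_bin` (aggregated `data.frame`: `bin`, `shared`,
#'   `frequency`, `mean_phase_diff`, `mean_coherence`, `mean_ang_dev`,
#'   `n_pairs`) and, optionally, `pairs` (per-pair long `data.frame`).
#'   Empty bins are simply absent.
#' @export
pair_profiles <- function(coeffs, pairs, frequencies = NULL,
                          return_pairs = FALSE) {
  stopifnot(inherits(coeffs, "spectral_coefficients"),
            inherits(pairs, "pair_table"))
  fsel <- if (is.null(frequencies)) {
    seq_along(coeffs$frequencies)
  } else {
    unique(vapply(frequencies, function(f)
      which.min(abs(coeffs$frequencies - f)), integer(1)))
  }
  fr <- coeffs$frequencies[fsel]
  ia <- match(pairs$id_a, coeffs$grid$ids)
  ib <- match(pairs$id_b, coeffs$grid$ids)
  if (anyNA(ia) || anyNA(ib)) stop("pair table ids missing from coefficients")
  nP <- nrow(pairs)
  nF <- length(fsel)
  C <- matrix(0, nP, nF)
  mu <- matrix(0, nP, nF)
  for (p in seq_len(nP)) {
    a <- coeffs$coef[ia[p], , 1, fsel]
    b <- coeffs$coef[ib[p], , 1, fsel]
    u <- (a * Conj(b)) / (abs(a) * abs(b))
    z <- colMeans(as.matrix(u))
    C[p, ] <- abs(z)
    mu[p, ] <- Arg(z)
  }
  sig <- matrix(angular_deviation(C), nP, nF)
  key <- interaction(pairs$bin, pairs$shared_component, drop = TRUE)
  agg <- do.call(rbind, lapply(levels(key), function(kl) {
    rows <- which(key == kl)
    zf <- colMeans(matrix(exp(1i * mu[rows, , drop = FALSE]),
                          length(rows), nF))
    data.frame(
      bin = pairs$bin[rows[1]],
      shared = pairs$shared_component[rows[1]],
      frequency = fr,
      mean_phase_diff = wrap_angle(Arg(zf)),
      mean_coherence = colMeans(C[rows, , drop = FALSE]),
      mean_ang_dev = colMeans(sig[rows, , drop = FALSE]),
      n_pairs = length(rows),
      stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  out <- list(by_bin = agg)
  if (return_pairs) {
    out$pairs <- data.frame(
      id_a = rep(pairs$id_a, each = nF),
      id_b = rep(pairs$id_b, each = nF),
      distance_mm = rep(pairs$distance_mm, each = nF),
      bin = rep(pairs$bin, each = nF),
      shared = rep(pairs$shared_component, each = nF),
      frequency = rep(fr, nP),
      coherence = as.vector(t(C)),
      mean_phase_diff = as.vector(t(mu)),
      ang_dev = as.vector(t(sig)),
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Fraction of trials with amplitude below the reference amplitude
#'
#' Per electrode and frequency: fraction of trials where the signal
#' coefficient amplitude is strictly below the average-reference coefficient
#' amplitude (ties count as not-below).  With a single-taper estimator,
#' amplitudes are Rayleigh across trials, so this fraction stays well above
#' zero even when the mean reference amplitude is far below the mean signal
#' amplitude; for n independent equal-power electrodes referenced to their
#' mean it approaches 1/(n+1).
#'
#' @param coeffs `spectral_coefficients` (first taper used).
#' @param ref_coef complex trial x frequency matrix of reference
#'   coefficients (e.g. the subset mean of per-electrode coefficients).
#' @return matrix electrode x frequency of fractions in [0, 1].
#' @export
fraction_below_reference <- function(coeffs, ref_coef) {
  stopifnot(inherits(coeffs, "spectral_coefficients"))
  d <- dim(coeffs$coef)
  ref_coef <- as.matrix(ref_coef)
  if (!identical(dim(ref_coef), c(d[2], d[4]))) {
    stop("reference coefficients must be trials x frequencies, aligned")
  }
  ra <- abs(ref_coef)
  out <- matrix(0, d[1], d[4])
  for (e in seq_len(d[1])) {
    out[e, ] <- colMeans(abs(matrix(coeffs$coef[e, , 1, ], d[2], d[4])) < ra)
  }
  out
}

#' Average-reference coefficient series
#'
#' Convenience helper: the per-trial mean coefficient over a subset of
#' electrodes (the spectral-domain image of the average-reference signal).
#'
#' @param coeffs `spectral_coefficients` of a single-wire recording.
#' @param subset electrode ids (default all).
#' @return complex trial x frequency matrix.
#' @export
reference_coefficients <- function(coeffs, subset = NULL) {
  stopifnot(inherits(coeffs, "spectral_coefficients"))
  if (is.null(subset)) subset <- coeffs$grid$ids
  idx <- match(subset, coeffs$grid$ids)
  if (anyNA(idx)) stop("subset ids missing from coefficients")
  d <- dim(coeffs$coef)
  acc <- matrix(0 + 0i, d[2], d[4])
  for (e in idx) acc <- acc + matrix(coeffs$coef[e, , 1, ], d[2], d[4])
  acc / length(idx)
}
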