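test_that("phase coherence hits 1 for constant phase differences", {
  set.seed(1)
  ph <- runif(100, -pi, pi)
  a <- exp(1i * ph)
  expect_equal(phase_coherence(a, a), 1)
  # constant pi offset: perfectly out of phase still means coherence 1
  expect_equal(phase_coherence(a, exp(1i * (ph + pi))), 1)
  # invariant under a common phase rotation of one electrode
  b <- exp(1i * runif(100, -pi, pi))
  expect_equal(phase_coherence(a * exp(1i * 0.77), b),
               phase_coherence(a, b), tolerance = 1e-12)
  expect_error(phase_coherence(a[1], a[1]), "at least 2")
  a0 <- a; a0[17] <- 0
  expect_error(phase_coherence(a0, b), "trial 17")
})

test_that("coherence estimator bias follows sqrt(pi)/(2 sqrt(N))", {
  set.seed(2)
  Ns <- c(25, 100, 400)
  bias <- vapply(Ns, function(N) {
    mean(replicate(600, abs(mean(exp(1i * runif(N, -pi, pi))))))
  }, numeric(1))
  # N = 100: expected resultant sqrt(pi/(4*100)) ~ 0.0886
  expect_equal(bias[2], sqrt(pi / 400), tolerance = 0.05)
  # 1/sqrt(N) scaling with coefficient sqrt(pi)/2, within 5%
  cc <- bias * sqrt(Ns)
  expect_true(all(abs(cc - sqrt(pi) / 2) / (sqrt(pi) / 2) < 0.05))
})

test_that("circular mean handles the antipodal degenerate case", {
  cm <- circular_mean(rep(1.1, 5))
  expect_equal(cm$mean, 1.1)
  expect_equal(cm$R, 1)
  cm2 <- circular_mean(c(0, pi))
  expect_false(cm2$defined)
  expect_true(is.na(cm2$mean))
  cm3 <- circular_mean(c(0, pi / 2))
  expect_equal(cm3$mean, pi / 4)
  expect_equal(cm3$R, cos(pi / 4))
})

test_that("angular deviation maps R to [0, sqrt(2)]", {
  expect_equal(angular_deviation(1), 0)
  expect_equal(angular_deviation(0), sqrt(2))
  expect_equal(angular_deviation(cos(pi / 4)), 0.7654, tolerance = 1e-4)
  expect_true(all(diff(angular_deviation(seq(0, 1, 0.1))) < 0))
  expect_error(angular_deviation(1.2), "0, 1")
  # identity on phase-difference samples by construction
  set.seed(4)
  d <- runif(50, -pi, pi)
  C <- abs(mean(exp(1i * d)))
  expect_equal(angular_deviation(C), sqrt(2 * (1 - C)))
})

test_that("PPC is unbiased and algebraically tied to the PLV", {
  expect_equal(pairwise_phase_consistency(rep(0.3, 10)), 1)
  expect_error(pairwise_phase_consistency(0.3), "at least 2")
  set.seed(5)
  # unbiasedness: mean over replicates within 3 SE of zero
  reps <- 2000; N <- 50
  est <- replicate(reps, pairwise_phase_consistency(runif(N, -pi, pi)))
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est)), 3 * se)
  # identity PPC = (N C^2 - 1)/(N - 1) on arbitrary samples
  for (i in 1:5) {
    d <- runif(30, -pi, pi)
    C <- abs(mean(exp(1i * d)))
    expect_equal(pairwise_phase_consistency(d), (30 * C^2 - 1) / 29,
                 tolerance = 1e-12)
  }
})

test_that("amplitude_of_sum reproduces vector addition", {
  expect_equal(amplitude_of_sum(1, 0.3, 1, 0.3), 2)
  expect_equal(amplitude_of_sum(1, 0, 1, pi), 0)
  expect_equal(amplitude_of_sum(2, 0.1, 3, -0.4),
               Mod(2 * exp(0.1i) + 3 * exp(-0.4i)))
  expect_error(amplitude_of_sum(-1, 0, 1, 0), "non-negative")
})

test_that("fraction below reference matches the correlated-Rayleigh law", {
  # reference identically zero -> never below; signal == reference -> ties
  # count as not-below
  cfg <- flat_config(n_rows = 1, n_cols = 2, n_trials = 50,
                     epoch_duration = 0.25)
  r <- generate_recording(cfg, seed = 6)
  co <- spectral_coefficients(r)
  d <- dim(co$coef)
  zero_ref <- matrix(0 + 0i, d[2], d[4])
  expect_equal(max(fraction_below_reference(co, zero_ref)), 0)
  self_ref <- matrix(co$coef[1, , 1, ], d[2], d[4])
  expect_equal(max(fraction_below_reference(co, self_ref)[1, ]), 0)

  # n equal-power independent electrodes vs their own mean
  cfg9 <- flat_config(n_rows = 3, n_cols = 3, n_trials = 3000,
                      epoch_duration = 0.1)
  r9 <- generate_recording(cfg9, seed = 7)
  co9 <- spectral_coefficients(r9)
  fr <- fraction_below_reference(co9, reference_coefficients(co9))
  sel <- co9$frequencies >= 50 & co9$frequencies <= 900
  expect_equal(mean(fr[, sel]), fraction_below_mean_exact(9),
               tolerance = 0.01)
  # and the independence approximation 1/(n+1) is close but not exact
  expect_lt(abs(mean(fr[, sel]) - 1 / 10), 0.02)
})

test_that("flip analysis separates the three amplitude categories", {
  set.seed(8)
  n <- 4000
  freqs <- c(10, 20)
  # aligned phases: everything real positive -> flips are exact
  A <- matrix(sqrt(-2 * log(runif(n * 2))), n, 2)   # Rayleigh-ish draws
  B <- matrix(sqrt(-2 * log(runif(n * 2))), n, 2)
  R <- matrix(1, n, 2)                              # fixed reference amplitude
  fa <- flip_analysis(A * (1 + 0i), B * (1 + 0i), R * (1 + 0i),
                      band = c(5, 25), frequencies = freqs)
  s <- fa$samples
  expect_setequal(unique(s$category), c("both", "exactly-one", "neither"))
  expect_equal(sum(fa$summary$fraction), 1)
  expect_equal(s$before, rep(0, nrow(s)))
  expect_equal(abs(s$change[s$category == "exactly-one"]),
               rep(pi, sum(s$category == "exactly-one")))
  expect_equal(max(abs(s$change[s$category != "exactly-one"])), 0)
  expect_equal(fa$summary$mean_abs_change[fa$summary$category == "exactly-one"],
               pi, tolerance = 1e-9)

  # all-zero reference: all trials 'both', after == before
  set.seed(9)
  Z <- matrix(complex(real = rnorm(n * 2), imaginary = rnorm(n * 2)), n, 2)
  W <- matrix(complex(real = rnorm(n * 2), imaginary = rnorm(n * 2)), n, 2)
  f0 <- flip_analysis(Z, W, matrix(0 + 0i, n, 2), c(5, 25), freqs)
  expect_equal(unique(f0$samples$category), "both")
  expect_equal(f0$samples$after, f0$samples$before)

  expect_error(flip_analysis(Z, W[1:10, ], matrix(0 + 0i, n, 2), c(5, 25),
                             freqs), "misaligned")
  expect_error(flip_analysis(Z, W, matrix(0 + 0i, n, 2), c(500, 600), freqs),
               "no frequency bins")
})

test_that("phase-shift surface is pi in the mixed quadrants", {
  set.seed(10)
  n <- 20000
  A <- matrix(sqrt(-2 * log(runif(n))), n, 1)
  B <- matrix(sqrt(-2 * log(runif(n))), n, 1)
  R <- matrix(1, n, 1)
  fa <- flip_analysis(A * (1 + 0i), B * (1 + 0i), R * (1 + 0i),
                      band = c(10, 10), frequencies = 10)
  ss <- phase_shift_surface(fa, n_bins = 8)
  mids_a <- (head(ss$breaks_a, -1) + tail(ss$breaks_a, -1)) / 2
  mids_b <- (head(ss$breaks_b, -1) + tail(ss$breaks_b, -1)) / 2
  q1 <- ss$surface[mids_a > 0, mids_b > 0]
  q3 <- ss$surface[mids_a < 0, mids_b < 0]
  q2 <- ss$surface[mids_a < 0, mids_b > 0]
  q4 <- ss$surface[mids_a > 0, mids_b < 0]
  expect_equal(max(abs(c(q1, q3)), na.rm = TRUE), 0)
  expect_equal(min(c(q2, q4), na.rm = TRUE), pi, tolerance = 1e-9)
})

test_that("pair profiles track frequency-dependent shared power", {
  cfg <- synthetic_config(n_rows = 4, n_cols = 4, n_trials = 150,
                          epoch_duration = 0.25)
  r <- generate_recording(cfg, seed = 11)
  co <- spectral_coefficients(r)
  pairs <- unique_pairs(r$grid, 4)
  pp <- pair_profiles(co, pairs, frequencies = c(20, 400),
                      return_pairs = TRUE)
  lo <- pp$by_bin[pp$by_bin$frequency == 20, ]
  hi <- pp$by_bin[pp$by_bin$frequency == 400, ]
  # strong shared component at 20 Hz: phases near zero at every distance
  expect_true(all(abs(lo$mean_phase_diff) < 0.2))
  # spread grows with frequency as the shared fraction decays
  expect_true(all(hi$mean_ang_dev > lo$mean_ang_dev))
  # per-pair long table has one row per pair x frequency
  expect_equal(nrow(pp$pairs), nrow(pairs) * 2)
})
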