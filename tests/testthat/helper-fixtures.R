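# Shared fixtures and independent oracles used across the suite.

deg <- function(rad) rad * 180 / pi

# circular mean (degrees) of a vector of angles in radians
circ_mean_deg <- function(angles) deg(Arg(mean(exp(1i * angles))))

# compact 27-electrode mask on a 10x10 lattice (a dense block with three
# corner sites dropped), mimicking an array where one region yielded no
# usable signals; all pairwise distances stay below 4 mm
mask_27 <- function() {
  m <- matrix(FALSE, 10, 10)
  m[1:6, 1:5] <- TRUE
  m[6, 4:5] <- FALSE
  m[5, 5] <- FALSE
  m
}

# small fast synthetic configs (dots override the quick defaults)
quick_config <- function(...) {
  args <- list(n_rows = 2, n_cols = 2, n_trials = 100, epoch_duration = 0.25)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

flat_config <- function(...) {
  # flat spectrum, no shared component: clean iid complex-Gaussian bins
  args <- list(background_exponent = 0, background_scale = 1,
               noise_floor = 0, common_fraction = function(f) 0 * f)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# analytic population phase-locking value for two unit-variance complex
# Gaussians with coherency rho: (pi/4) rho 2F1(1/2, 1/2; 2; rho^2)
plv_gaussian <- function(rho) {
  z <- rho^2
  s <- 1; term <- 1
  for (k in 0:60) {
    term <- term * (0.5 + k) * (0.5 + k) / ((2 + k) * (k + 1)) * z
    s <- s + term
  }
  pi / 4 * rho * s
}

# exact probability that one of n iid complex-Gaussian electrodes has
# amplitude below the amplitude of their mean (signal included in the mean);
# indefinite-quadratic-form eigenvalue result.  The independence
# approximation is 1/(n+1).
fraction_below_mean_exact <- function(n) {
  a <- 1 - 1 / n
  D <- sqrt(a^2 + 4 * (n - 1) / n^2)
  (D - a) / (2 * D)
}

# brute-force unordered pair enumeration with a distance cutoff
brute_force_pairs <- function(grid, max_distance) {
  n <- length(grid$ids)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((grid$pos[i, ] - grid$pos[j, ])^2))
      if (d <= max_distance + 1e-6) cnt <- cnt + 1L
    }
  }
  cnt
}

# symbolic CSD expansion: map each eligible electrode to the set of real
# electrode ids appearing in its CSD signal (itself + its four neighbours)
csd_term_sets <- function(grid) {
  elig <- csd_eligible(grid)
  lapply(elig, function(id) {
    r <- (id - 1) %/% grid$n_cols + 1
    c <- (id - 1) %% grid$n_cols + 1
    nb <- c((r - 2) * grid$n_cols + c, r * grid$n_cols + c,
            (r - 1) * grid$n_cols + c - 1, (r - 1) * grid$n_cols + c + 1)
    c(id, nb)
  })
}
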