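# The average-reference phase-flip mechanism: trial categorisation by
# amplitude relative to the reference, before/after phase differences, and
# the 2D phase-shift surface.

#' Trial-level flip analysis for one electrode pair
#'
#' For a pair of electrodes and the average-reference coefficient series,
#' pools the bins of a frequency band as samples and, per sample, records
#' the three amplitudes, the phase difference before referencing
#' (Arg a - Arg b) and after (Arg(a - ref) - Arg(b - ref)), and the wrapped
#' change.  Samples are classified by whether both, exactly one, or neither
#' signal amplitude exceeds the reference amplitude (ties count as
#' not-larger): with phases aligned across electrodes, the "exactly one"
#' category is the one whose phase difference flips by pi under average
#' referencing.
#'
#' @param coef_a,coef_b complex trial x frequency matrices of single-taper
#'   coefficients for the two electrodes.
#' @param ref_coef complex trial x frequency matrix of average-reference
#'   coefficients, trial-aligned.
#' @param band `c(f_lo, f_hi)` in Hz selecting bins of `frequencies`.
#' @param frequencies frequency grid (Hz) for the matrices' columns.
#' @return object of class `flip_analysis`: `samples` data.frame (`trial`,
#'   `frequency`, `A1`, `A2`, `A_ref`, `category`, `before`, `after`,
#'   `change`, `abs_change`) and `summary` (per category: fraction of
#'   samples, circular mean of absolute phase-difference change).
#' @export
flip_analysis <- function(coef_a, coef_b, ref_coef, band, frequencies) {
  coef_a <- as.matrix(coef_a); coef_b <- as.matrix(coef_b)
  ref_coef <- as.matrix(ref_coef)
  if (!identical(dim(coef_a), dim(coef_b)) ||
      !identical(dim(coef_a), dim(ref_coef))) {
    stop("coefficient matrices are misaligned (differing trial/frequency shape)")
  }
  if (length(frequencies) != ncol(coef_a)) {
    stop("frequencies must match matrix columns")
  }
  sel <- which(frequencies >= band[1] - 1e-9 & frequencies <= band[2] + 1e-9)
  if (length(sel) == 0) stop("band [", band[1], ", ", band[2],
                             "] Hz contains no frequency bins")
  nTr <- nrow(coef_a)
  a <- coef_a[, sel, drop = FALSE]
  b <- coef_b[, sel, drop = FALSE]
  r <- ref_coef[, sel, drop = FALSE]
  A1 <- abs(a); A2 <- abs(b); Ar <- abs(r)
  before <- wrap_angle(Arg(a) - Arg(b))
  after <- wrap_angle(Arg(a - r) - Arg(b - r))
  change <- wrap_angle(after - before)
  big1 <- A1 > Ar
  big2 <- A2 > Ar
  category <- ifelse(big1 & big2, "both",
                     ifelse(xor(big1, big2), "exactly-one", "neither"))
  samples <- data.frame(
    trial = rep(seq_len(nTr), length(sel)),
    frequency = rep(frequencies[sel], each = nTr),
    A1 = as.vector(A1), A2 = as.vector(A2), A_ref = as.vector(Ar),
    category = as.vector(category),
    before = as.vector(before), after = as.vector(after),
    change = as.vector(change), abs_change = abs(as.vector(change)),
    stringsAsFactors = FALSE
  )
  summary <- do.call(rbind, lapply(c("both", "exactly-one", "neither"),
    function(cat) {
      rows <- samples$category == cat
      if (!any(rows)) {
        return(data.frame(category = cat, fraction = 0,
                          mean_abs_change = NA_real_))
      }
      cm <- circular_mean(samples$abs_change[rows])
      data.frame(category = cat, fraction = mean(rows),
                 mean_abs_change = if (cm$defined) abs(cm$mean) else NA_real_)
    }))
  out <- list(samples = samples, summary = summary, band = band)
  class(out) <- "flip_analysis"
  out
}

#' @export
print.flip_analysis <- function(x, ...) {
  cat(sprintf("<flip_analysis> band %g-%g Hz, %d samples\n",
              x$band[1], x$band[2], nrow(x$samples)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Phase-shift surface over signal-minus-reference amplitudes
#'
#' Bins the flip-analysis samples on a 2D grid of (A1 - A_ref, A2 - A_ref)
#' and reports the mean absolute phase-difference change per cell.  With
#' phase-aligned inputs, cells in the first (both larger) and third (neither
#' larger) quadrants sit near 0 while the second and fourth ("exactly one")
#' quadrants sit near pi.
#'
#' @param flip a `flip_analysis`.
#' @param n_bins number of bins per axis (default 10).
#' @return list with `breaks_a`, `breaks_b` and `surface` (n_bins x n_bins
#'   matrix of mean absolute changes; empty cells NA).
#' @export
phase_shift_surface <- function(flip, n_bins = 10) {
  stopifnot(inherits(flip, "flip_analysis"))
  s <- flip$samples
  da <- s$A1 - s$A_ref
  db <- s$A2 - s$A_ref
  lim <- max(abs(c(da, db)))
  breaks <- seq(-lim, lim, length.out = n_bins + 1)
  ia <- cut(da, breaks, include.lowest = TRUE, labels = FALSE)
  ib <- cut(db, breaks, include.lowest = TRUE, labels = FALSE)
  surf <- matrix(NA_real_, n_bins, n_bins)
  for (i in seq_len(n_bins)) {
    for (j in seq_len(n_bins)) {
      rows <- which(ia == i & ib == j)
      if (length(rows) > 0) surf[i, j] <- mean(s$abs_change[rows])
    }
  }
  list(breaks_a = breaks, breaks_b = breaks, surface = surf)
}
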