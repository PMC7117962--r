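---
title: "Reference schemes and the power and phase of multi-electrode LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference schemes and the power and phase of multi-electrode LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpref)
```

## The problem

Local field potentials (LFPs) recorded from a chronically implanted
microelectrode grid are always measured *relative to something*: a distant
wire on the dura (single-wire reference), the mean of all electrodes
(average reference), one neighbouring electrode (bipolar), or the mean of
the four nearest grid neighbours (current source density, CSD).  Because a
large fraction of low-frequency LFP power is a volume-conducted component
common to all electrodes, the choice of reference reshapes two families of
statistics that are routinely given physiological interpretations:

* the slope $\alpha$ of the $1/f^\alpha$ power spectral density, fitted as
  $P(f) = A f^{-\alpha} + B$ over sliding frequency windows, and
* phase statistics between electrode pairs: the phase-locking value
  $C_\mathrm{phase}(f) = \frac{1}{N}\left|\sum_k e^{j(\phi_k - \theta_k)}\right|$
  over $N$ trials, the circular mean phase difference, and the angular
  deviation $\sigma_\mathrm{phase} = \sqrt{2(1 - R)} \in [0, \sqrt 2]$.

`lfpref` implements the full pipeline — grid geometry, re-referencing,
single/multi-taper (Slepian) spectral estimation, roll-off correction and
noise masking, sliding-window slope fits, and pairwise circular statistics —
together with a synthetic generator that reproduces the statistical
structure these effects depend on, so every mechanism can be demonstrated
and tested without access to recordings.

## The generative model

`generate_recording()` draws spectral coefficients directly in the
frequency domain.  For electrode $e$, trial $k$ and positive FFT bin $f$:

$$V_e(f) = \sqrt{c(f)\,P(f)/2}\;\hat G(f) + \sqrt{(1 - c(f))\,P(f)/2}\;\hat N_e(f),$$

with $\hat G$ a circularly symmetric complex Gaussian shared by all
electrodes, $\hat N_e$ independent per electrode, and
$P(f) = A_\mathrm{bg} f^{-\alpha_\mathrm{bg}} + B_\mathrm{floor} + \text{bumps}$.
Consequences, all exercised by the test suite:

* single-taper power at a bin is exponential across trials and amplitude is
  Rayleigh — exactly the estimator variability that drives the
  average-reference phase flip;
* the amplitude-weighted coherence between any two electrodes equals
  $c(f)$; the default $c(f)$ is a logistic decay from 0.6 near DC to 0 with
  midpoint 80 Hz and width 20 Hz, emulating coherence that is high at low
  frequencies and vanishes above ~100 Hz;
* time series are obtained by inverse FFT of the conjugate-symmetric
  spectrum (DC and Nyquist zero), so referencing in the time domain is
  identical to referencing coefficients.

Tunable parameters (with defaults): grid 10×10 at 0.4 mm pitch; 200 trials
of 0.5 s at 2 kHz; background exponent 2 (Brownian-like, within the 1–3
range typical of cortical LFP below 100 Hz) scaled to 1000 µV² per bin at
1 Hz; noise floor $10^{-3}$ µV² per bin; optional alpha/gamma Gaussian
bumps, fixed-amplitude line components, and a `reference_pickup` term added
identically to every electrode to emulate neural activity on the reference
wire itself (its true magnitude is unknowable, hence a free parameter,
default 0).

What the generator does *not* emulate: biophysical forward models,
distance-dependent correlations beyond the single shared source, spikes,
or nonstationarity.  A green test therefore establishes that an effect
follows from the shared-component + Rayleigh-amplitude structure alone —
which is precisely the claim the mechanism analyses make — not that real
tissue behaves this way.

## Why phase-locking value is not the shared fraction

For partially coherent complex-Gaussian signals with coherency $\rho$, the
amplitude-*weighted* coherence estimator converges to $\rho$, but the
amplitude-discarding phase-locking value converges to
$\frac{\pi}{4}\rho\,{}_2F_1(\tfrac12, \tfrac12; 2; \rho^2) < \rho$
(≈ 0.70 at $\rho = 0.8$).  `expected_coherence()` returns $c(f)$ and is
validated against `coherence()`; `phase_coherence()` is validated against
the closed form.  Both estimators are exposed because the phase-locking
value is also positively biased at finite $N$ (≈ $\sqrt{\pi}/(2\sqrt N)$
for independent phases), which is why `pairwise_phase_consistency()` — the
unbiased pair-averaged cosine — is provided as well.

## The mechanisms the pipeline reproduces

**Bipolar power doubling.**  Subtracting an independent equal-power
neighbour doubles expected power (the sum/difference of random-phase
sinusoids has amplitude
$\sqrt{A_1^2 + A_2^2 \pm 2A_1A_2\cos(\theta_1 - \theta_2)}$, RMS
$\sqrt 2 A$), shifting the log₁₀ PSD up by about 0.3 at frequencies where
coherence is gone.

**Shared-component artifacts.**  Bipolar pairs sharing a real electrode,
and CSD pairs at 1, $\sqrt 2$ and 2 pitches (which share subtraction
terms), show spuriously high coherence with deterministic phase offsets:
π for adjacent CSD pairs (each contains the other's centre with weight
−1/4) and 0 for the shared-neighbour geometries.  `flag_shared_components()`
marks these pairs and `pair_profiles()` never pools them with clean pairs.

**The average-reference π flip.**  After average referencing, the shared
component cancels and each electrode retains $N_e - \bar N$, and any two
such residuals are negatively correlated ($-1/n$), so distant-pair circular
mean phase differences sit at 180°.  Trial-wise, the flip happens exactly
when one of the two amplitudes falls below the reference amplitude — which
the Rayleigh amplitude distribution guarantees for a nonzero fraction of
trials at any frequency; `flip_analysis()`, `fraction_below_reference()`
and `phase_shift_surface()` quantify this (quadrants with exactly one
amplitude below the reference show a π shift, the others ≈ 0).

## Numerical choices

* **Slope fit objective**: least squares on log₁₀ power (a config switch
  selects linear space).  Over a $1/f$ range, linear residuals would be
  dominated by the lowest bins; log residuals weight decades evenly and
  make trial-averaged multiplicative noise additive.
* **Optimizer**: Nelder–Mead over $(\log A, \alpha, \log B)$ (the log
  parameterisation enforces $A, B \ge 0$), initialised from a log–log
  straight-line fit with $B_0$ = half the window's minimum power, with
  fminsearch-style restarts at the incumbent until improvement stops.
  Narrow (±15 Hz) windows put the three-parameter family on an almost
  exact $A$–$\alpha$–$B$ ridge, especially at high centre frequencies:
  noiseless slopes are recovered to <0.05 there (far tighter on wide
  windows), and on stochastic PSDs the fitted $\alpha$ on ±15 Hz windows
  scatters substantially — a property of the model family, not the
  optimizer.  Mechanism tests that compare slopes across schemes therefore
  use broad windows.
* **Roll-off correction** divides by the analytic squared magnitudes of a
  first-order 0.3 Hz high-pass and fourth-order 500 Hz low-pass
  Butterworth; DC (zero high-pass gain) is masked rather than divided.
* **Masking** marks bins within ±2 bins (configurable) of each listed
  noise frequency as `NA`, never zero; fits with fewer than 4 usable bins
  return a flagged non-converged result.
* **Ties and degenerate inputs**: amplitude ties count as "not below" the
  reference (measure-zero for continuous data); circular means with
  $R < 10^{-6}$ are reported undefined rather than as an arbitrary angle;
  distance comparisons use a $10^{-6}$ mm absolute tolerance so exact
  lattice distances (subject to one-ulp floating-point error) bin
  unambiguously.
* **Center-out tie-break**: when both electrodes of a bipolar pair are
  equidistant from the grid centre, the minuend is the lower electrode id;
  the restricted ("each electrode used at most once") variant is a greedy
  maximal matching over pairs sorted by (distance, id).  Both are
  deterministic and reproducible.

## Known limitations

* The 27-electrode monkey-1 layout is not published; geometry worked
  examples use a documented compact synthetic 27-site mask (any set of 27
  sites with pairwise distances ≤ 4 mm yields the same 351 unique pairs).
* $\alpha = 0$ (flat spectrum) is structurally unidentifiable in
  $A f^{-\alpha} + B$: the level can be carried by $A$ at $\alpha = 0$ or
  by $B$ with arbitrary $\alpha$.  Tests assert the identifiable contract
  (the fitted model reproduces the level).
* The per-condition (contrast/attention) machinery is limited to bump
  parameter switches in the generator; no behavioural model is implemented.
* CSD is the plain four-neighbour voltage difference of the 2D grid — no
  $1/\text{pitch}^2$ Laplacian scaling, no 3D/laminar variant, no
  irregular arrays.
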