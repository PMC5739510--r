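---
title: "Driven auto-regressive models for phase-amplitude coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driven auto-regressive models for phase-amplitude coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darpac)
```

## The problem

Phase-amplitude coupling (PAC) — the modulation of a fast oscillation's
amplitude by the phase of a slow oscillation — is among the most reported
forms of cross-frequency coupling in neural recordings (theta/gamma in
hippocampus, slow/beta-gamma in cortex). The classical analysis pipeline
band-passes the signal twice, takes Hilbert phases and amplitudes, and
correlates them. It has well-known pitfalls: the result depends strongly on
the fast bandwidth `delta_f_y` (which must exceed `2 f_x` for any modulation
to be observable at all), the Hilbert transform is only meaningful on
narrow-band signals, and none of the resulting indices come with a
goodness-of-fit score, so filtering parameters can only be chosen by how
large they make the effect — a statistically questionable practice.

`darpac` instead fits a **generative signal model**. A driven auto-regressive
(DAR) model is an AR(p) model whose coefficients and innovation variance are
polynomial functions of a slow exogenous *driver* `x`:

    y(t) + sum_{i=1..p} a_i(x(t)) y(t-i) = eps(t),   eps(t) ~ N(0, sigma(x(t))^2)
    a_i(x) = sum_{k+l <= m} a_ikl x1^k x2^l,  log sigma(x) = sum_{k+l <= m} b_kl x1^k x2^l

with `x = x1 + i x2` a complex driver built from quadrature (cosine and sine)
band-pass filters. The model is linear in its regressors
`x1^k x2^l y(t-i)`, so the AR coefficients have a closed-form weighted
least-squares solution; the variance polynomial is maximized by
Newton-Raphson, and the two steps are alternated (twice by default — more
iterations change the likelihood by less than the numerical tolerances).
Because the model is probabilistic, its likelihood scores the *fit to the
data* (explained variance), not the size of the coupling — which is what
makes model and parameter comparison legitimate.

## From model to coupling measures

* **Conditional spectrum.** At any driver value `x0`, the fitted model is a
  locally stationary AR filter, so its power spectral density is
  `sigma(x0)^2 |sum a_i(x0) e^{-2 pi i f i}|^{-2}`. `psd_on_phase_circle()`
  evaluates it at `x0 = rho e^{i phi}` (with `rho` the median driver
  modulus), showing how the whole spectrum deforms with driver phase.
* **Modulation metric.** For each frequency, the conditional PSD values
  across phases are normalized to a distribution and compared with the
  uniform distribution by a Kullback-Leibler divergence, normalized by
  `log(n_phases)` so that `M(f)` lies in `[0, 1]` (`modulation_spectrum()`).
  This is the same KL kernel as the Tort modulation index, applied to model
  spectra instead of binned amplitudes.
* **Comodulogram.** `comodulogram_dar()` repeats preprocessing + fit + M(f)
  over a grid of driver frequencies. The fast-frequency axis defaults to
  `[2.5 * max(driver grid), 0.95 * fs/2]`: below the driver band the spectral
  power reflects the slow components and the gap-filling noise rather than
  fast-amplitude modulation, and the DC/Nyquist bins of an AR spectrum are
  edge-dominated, so including them only admits artifacts.
* **Selection.** `grid_search_driver()` picks the driver band `(f_x,
  delta_f_x)` maximizing the likelihood — computed on the *same* fast signal
  for every candidate, which requires removing all candidate bands at once
  (`prepare_for_gridsearch()`). `select_orders_bic()` picks `(p, m)` by BIC
  with `d = (p+1)(m+1)` degrees of freedom for a real driver and
  `d = (p+1)(m+1)(m+2)/2` for a complex one; all candidates are scored on the
  common support `t > max(p_grid)` so their likelihoods are comparable.
* **Directionality.** `delay_profile()` refits the model with the driver
  shifted by each candidate delay and sums the negative log-likelihoods of
  the forward and time-reversed fits: the non-causal extraction filter
  biases both directions alike, so the bias cancels in the sum. A positive
  best delay means the slow oscillation precedes the amplitude modulation.
  `psi_delay()` implements a phase-slope-index comparator; it assumes
  near-perfect coherence and a small slope, and is biased toward zero for
  large delays — it is kept only for qualitative comparison.
* **Significance.** `surrogate_threshold()` builds the null distribution of
  the comodulogram *maximum* under random circular time shifts of the driver
  pathway (shifts of at least one second or three driver periods). Using
  the max statistic avoids multiple testing across grid cells.

## Preprocessing choices

The driver filter is a Blackman window modulated by a cosine (and its sine
quadrature). The window length is `floor(1.65 fs / delta_f_x)` rounded to an
odd tap count, which places the −3 dB (half-power) points at
`f_x ± delta_f_x / 2` to within 0.05 dB. Taps are normalized to unit gain at
`f_x` so driver amplitudes are comparable across candidate bands. FIR
filtering is zero-phase: the signal is reflect-padded by half the filter
length and the central part of the convolution kept, so all series stay
full-length and aligned.

After subtracting the driver's real part, `y = z - x1` has a spectral notch
that would distort a compact AR model, so it is refilled with white noise
passed through the same filter. The noise energy is matched so the PSD is
continuous across the gap: the target level is the geometric mean of
Welch-estimated levels on the two `2 delta_f_x`-wide flanks of the gap (the
flank width and estimator are this package's choices, recorded in the
pair's metadata). Finally `y` is whitened by the inverse filter of a fitted
AR model — order 10 by default; whitening is not required but lets a small
`p` capture the modulation rather than the spectral slope. For driver grid
searches the whitening is fitted once on the common high-passed `y`, so all
candidates see the identical signal.

Power-line removal projects the signal on a cosine/sine pair over a
0.01 Hz-resolution grid spanning ±0.5 Hz around the nominal frequency and
subtracts the strongest projection (repeated at harmonics on request).

## The simulator

`simulate_pac()` generates the study conditions used throughout the tests:
a coupling between `f_x = 3` Hz (bandwidth 1 Hz, band-passed Gaussian noise
normalized to unit standard deviation — deliberately *not* a sinusoid) and a
`f_y = 50` Hz carrier at `fs = 240` Hz. The fast amplitude is a logistic
function of the driver, `a_y = 1 / (1 + exp(-lambda x1))` with `lambda = 3`;
the modulated carrier is rescaled to standard deviation 0.4, and the driver
plus unit-variance white noise are added. The generator is not a DAR
process, so model validation on it is not circular. A delay `tau` shifts the
modulation pathway in time (realized on an extended driver, no wrap-around);
a preferred phase `phi0` rotates the driver phase at which the amplitude
peaks (`a_y` is driven by `Re(x e^{-i phi0})`). Variants add low-passed
noise at a stated PSD gap at `f_x` (driver-selection experiments) or replace
the oscillators by a 10 Hz jittered spike train with one-sample rise and
10 ms exponential decay (spurious-PAC experiments; the transient shape is an
approximation chosen here, as the original waveform is not reproduced in the
source).

What the simulator does *not* emulate: 1/f background spectra,
non-stationary coupling, asymmetric or wide-band drivers, multi-channel
structure. Tests passing on it show correctness of the estimation machinery
under the stated generative assumptions, not performance on real LFP/ECoG
records.

## Numerical choices and scales

* Newton-Raphson on the variance polynomial: at most 50 iterations,
  gradient-norm tolerance `1e-6` per sample, step halving on any objective
  increase; the first iteration starts from `log sd(residuals)`.
  Ill-conditioned normal equations abort the fit with the reciprocal
  condition number in the message; comodulogram grids mask such columns
  instead of failing.
* The likelihood uses `n = T - p` terms (`t` from `p+1`); when models of
  different `p` are compared, all are evaluated on `t > max(p_grid)`.
* Phase circle: 40 phases and a 256-point FFT by default (16/128 in the
  surrogate-calibration protocol below — the max statistic is insensitive
  to this resolution); `rho = median(|x|)`.
* Comodulogram defaults: driver grid 1–7 Hz in 0.5 Hz steps, bandwidth
  1 Hz, DAR(10, 1), complex driver.
* Tort index: 18 phase bins; empty bins inherit the nearest filled bin's
  mean and are counted. Ozkurt normalization:
  `|sum a e^{i phi}| / sqrt(T sum a^2)`.
* The delay grid defaults to ±1.5 driver periods in 25 points; delays are
  integer-sample shifts, and every grid cell is scored on the common valid
  support so sample counts match.
* The compiled (RcppArmadillo) estimation core is cross-checked against a
  pure-R reference implementation in the tests.

Problem sizes in the test and acceptance protocols are chosen to keep a
full run on one CPU in minutes: 100 s records for single comodulograms and
driver-band selection (nine replicates, modal choice reported, since
cell-level selection is stochastic), 50 replicates of 8 s for the
short-signal study, 200 signals × 200 surrogates of 20 s (driver grid
{3, 4, 5} Hz) for the threshold-calibration study, 2×10⁴ samples for
order-selection replicates, and 4×10⁴ samples for the preferred-phase sweep.

## Design decisions in open territory

* **Amplitude vs phase-only drivers.** The package compares DAR against a
  phase-only variant (PDAR, driver normalized to unit modulus) by held-out
  likelihood. On signals whose coupling genuinely varies with driver
  amplitude (an affine DAR-generated process), DAR wins consistently. On
  the default sigmoid simulator with `lambda = 3` the modulation saturates —
  `a_y` is nearly a step function of the driver's sign — so the amplitude
  carries almost no extra information and the two variants tie within
  ~0.001 nats/sample. The claim "amplitude fluctuations matter" is therefore
  exercised on the amplitude-dependent process, where it is decidable.
* **Preferred-phase invariance.** The real-driver model's improvement over
  the AR baseline collapses near `phi0 = ±pi/2` (to under 20% of its
  maximum); the complex-driver model retains more than half its improvement
  at every phase. These ratios, not a fixed percentage spread, are the
  tested property: the spread of the complex-driver improvement across
  `phi0` contains an irreducible realization-dependent component that does
  not shrink with record length.
* **PDAR's normalized driver** feeds both the coefficient and the variance
  polynomials (a single normalized driver, as the variant's definition
  reads most naturally).
* **Stability.** No stability re-parametrization of the AR coefficients is
  performed; `psd_on_phase_circle(check_stability = TRUE)` warns when the
  per-phase AR polynomial has poles on or outside the unit circle.
* **Surrogates** shift the already-extracted driver pathway circularly
  (preserving both marginal spectra) rather than re-extracting it from a
  shifted raw signal; re-extraction would cost a full preprocessing pass
  per surrogate and differs only at the record edges.

## Worked example

```{r example, eval = FALSE}
sig <- simulate_pac(sim_pac_config(n_seconds = 100, seed = 42))
com <- comodulogram_dar(sig, driver_freqs = seq(1, 7, by = 0.5), rng_seed = 1)
comodulogram_argmax(com)
#> driver_freq signal_freq
#>      3.0000     49.6875

pair <- prepare_pair(sig, f_x = 3, delta_f_x = 1, rng_seed = 1)
fit <- fit_dar(pair, p = 10, m = 1)
fit
#> <dar_model> DAR(p = 10, m = 1) complex driver | dof = 33 | ...
plot(com)
```

## Known limitations

* Univariate records only; no artifact rejection, epoching, or EEG/MEG
  container formats — convert to a plain one-column file first.
* Spurious PAC from sharp non-sinusoidal transients is detected as coupling
  by this method just as by the classical indices (the spike-train
  simulator demonstrates it); the model cannot distinguish nested
  oscillators from harmonics of a sharp waveform.
* Delays are integer-sample; sub-sample delay estimation is out of scope.
* Point estimation by maximum likelihood only — no posterior uncertainty on
  the coefficients; uncertainty on derived scalars (e.g. the delay) comes
  from the block bootstrap.
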