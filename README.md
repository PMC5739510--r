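# darpac

Driven auto-regressive (DAR) models for detecting, quantifying and
characterizing phase-amplitude coupling (PAC) in univariate neural time
series (LFP, ECoG, or any regularly sampled signal).

Classical PAC indices band-pass the signal twice, extract Hilbert phases and
amplitudes, and correlate them. They depend critically on filtering choices,
misbehave on wide-band signals, and provide no goodness-of-fit score, so
there is no legitimate way to compare parameters on real data. `darpac`
instead fits a generative model: an AR(p) process whose coefficients and
innovation variance are degree-m polynomials in a slow, band-limited,
complex-valued driver x = x1 + i·x2,

    y(t) + Σ_{i=1..p} a_i(x(t)) · y(t−i) = ε(t),   ε(t) ~ N(0, σ(x(t))²),
    a_i(x) = Σ_{k+l≤m} a_ikl · x1^k x2^l,          log σ(x) = Σ_{k+l≤m} b_kl · x1^k x2^l.

The fitted model gives

* a **driver-conditional power spectrum** PSD(x₀)(f) = σ(x₀)² |Σ a_i(x₀) e^(−2πi f i)|⁻²,
* a **modulation metric** M(f) ∈ [0, 1] — the normalized KL divergence of
  the phase-conditional spectrum from uniformity — and a **comodulogram**
  over (driver frequency, signal frequency),
* a **likelihood**, used to select the driver band (f_x, Δf_x) by grid
  search, the orders (p, m) by BIC, and the **coupling delay** by profiling
  shifted drivers on forward plus time-reversed fits,
* **surrogate significance** from the null distribution of the comodulogram
  maximum under random time shifts, and classical baselines (Tort KL
  modulation index, Ozkurt normalized vector length, Penny GLM) for
  comparison.

## Quick start

```r
library(darpac)

# 100 s of synthetic PAC: 3 Hz driver modulating a 50 Hz carrier at 240 Hz
sig <- simulate_pac(sim_pac_config(n_seconds = 100, seed = 42))

com <- comodulogram_dar(sig, driver_freqs = seq(1, 7, by = 0.5), rng_seed = 1)
comodulogram_argmax(com)
#> driver_freq signal_freq
#>      3.0000     49.6875
```

The maximum of the comodulogram sits at a driver frequency of 3 Hz and a
fast frequency of 49.7 Hz (the FFT bin nearest 50 Hz): the simulated
coupling pair, recovered from the raw signal alone.

```r
pair <- prepare_pair(sig, f_x = 3, delta_f_x = 1, rng_seed = 1)
fit  <- fit_dar(pair, p = 10, m = 1)
fit
#> <dar_model> DAR(p = 10, m = 1) complex driver | dof = 33 | logL = -35231.21 (-1.4686 / sample, n = 23990)

# significance of the observed comodulogram maximum (p = 0.01)
null <- surrogate_threshold(sig, "dar", driver_freqs = seq(2, 5, 0.5),
                            n_surrogates = 200, percentile = 99, rng_seed = 7)
null
#> <surrogate_null> 200 surrogates | threshold (p = 0.01): 0.002376 | observed max: 0.02316 (significant)

# coupling delay: positive = the slow oscillation precedes the modulation
prof <- delay_profile(pair, p = 10, m = 1)
prof$best_delay
#> [1] -0.04166667
```

The observed coupling (M = 0.023) is an order of magnitude above the
p = 0.01 surrogate threshold, and the estimated delay is one grid step
(0.042 s) from the true value of zero.

A thin command-line front end covering simulation, preprocessing, fitting,
comodulograms (with optional surrogates) and delay profiling is installed at
`inst/cli/darpac`; run it with `Rscript`.

The methods vignette (`vignettes/dar-models-for-pac.Rmd`) documents the
model, the preprocessing pipeline (driver filter design, spectral gap
filling, whitening), all defaults, and the design decisions.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "darpac", load_package = "installed")'
```

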